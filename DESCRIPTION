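Package: ageval
Title: Rule-Based Evidence Evaluation of Aging-Gene Hypotheses over Linked-Data Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A hypothesis-evaluation engine for aging-gene discovery in
    Caenorhabditis elegans. The package stores multi-source gene annotation
    data (gene/phenotype/GO records, curated lifespan annotations, dietary
    restriction gene sets, protein-protein interactions with PSI-MI detection
    methods, protein GO annotations with evidence codes, expression
    fold-change records, and GO term co-occurrence counts) as named RDF-style
    quad graphs with Bio2RDF-convention identifiers, and evaluates the
    hypothesis that a given gene participates in aging by running nine
    boolean data-evaluation functions over gene-centric retrieval queries.
    Event scores (satisfied functions / 9) are propagated bottom-up through
    AND/OR/XOR proposition logic to an overall hypothesis score with a full
    provenance audit trail. Includes a synthetic knowledge-base generator
    with plantable per-gene evidence profiles, batch analytics (score
    distributions, evidence-combination probabilities, candidate
    identification, Kolmogorov-Smirnov distribution comparison, GO
    co-occurrence computation), and Turtle/N-Quads serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
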