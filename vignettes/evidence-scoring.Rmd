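---
title: "Evidence-based scoring of aging-gene hypotheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based scoring of aging-gene hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageval)
```

## The model

`ageval` evaluates the hypothesis that a *C. elegans* gene participates in
aging, by scoring it against a multi-source knowledge base. The hypothesis is
represented as a tree: typed **events** (a biological process — here the GO
process *aging*, `go:0007568` — with an agent gene) combined by
**propositions** carrying a logical operator. The aging use-case always
produces a single-event tree, which we canonicalize by wrapping the event in
an `XOR` proposition so that the propagation engine sees one uniform shape.

Evidence is gathered by pure, gene-centric **retrieval functions** over seven
named graphs — gene/phenotype/GO annotations, curated lifespan effects,
dietary-restriction gene sets, protein–protein interactions with PSI-MI
detection-method codes, protein GO annotations, expression fold changes with
p-values, and GO-term co-occurrence counts. All graphs share
Bio2RDF-convention identifiers (`http://bio2rdf.org/namespace:local`), so a
gene carries one name everywhere; that shared naming, not any inference, is
the integration mechanism. Pattern matching is asserted-triples-only and
deliberately minimal: conjunctive patterns, set filters and numeric
comparisons are exactly what the retrieval layer needs, so nothing more is
implemented (no OPTIONAL/UNION, no OWL reasoning).

Nine boolean **evaluation functions** then each answer one evidence question
(curated lifespan annotation; significant differential expression under
aging-pathway manipulation; multi-study dietary-restriction expression,
directly or via an asserted homolog; DR-essentiality; lifespan phenotype;
experimentally evidenced aging GO annotation; high-confidence protein
interaction with an aging-annotated partner; genetic interaction with
lifespan-phenotype genes; GO co-occurrence with aging terms). The **event
score** is the satisfied count divided by 9, kept as an exact rational
internally and displayed rounded half-away-from-zero to two decimals
(8/9 → 0.89, 7/9 → 0.78, …). Proposition scores propagate bottom-up: `AND`
takes the mean of member scores, `OR` the maximum, `XOR` passes its single
member through; the root score is the hypothesis score. Refuting facts act
through absence: a curated "decrease" effect fails the increase-only curated
check, so the aggregate is strictly lower than for an otherwise identical
gene with "increase".

Every evaluation emits provenance quads — evaluation type, creator, creation
time, the input hypothesis, stable rule identifiers, per-node scores and one
contribution node per evaluation function with the retrieval functions it
called — and the emitted graph is lossless: re-parsing it reconstructs every
score exactly. Timestamps are excluded from equality; a `fixed_clock`
argument pins them when byte-stable output matters.

## Tunable parameters

All rule thresholds live in one config (`default_config()`), overridable
from YAML:

* `aging_go_terms` — the five aging-related GO process terms (`go:0007568`,
  `go:0007569`, `go:0035982`, `go:0010259`, `go:0008340`).
* `lifespan_phenotypes` — phenotype classes meaning lifespan change. The
  underlying databases do not pin specific class codes in any table we
  reproduce, so the package fixes three plausible WormBase-style codes
  (extended / shortened / life-span-variant) as defaults; swap in your own
  ontology's codes via config.
* `high_confidence_methods` — PSI-MI detection-method whitelist. Defaults to
  the four codes exercised by the worked example (0397, 0398, 0676, 0109);
  the full curated whitelist is a config slot precisely because it is
  curation, not code.
* `experimental_evidence` — ECO classes counted as experimental; likewise a
  config choice (defaults cover direct assay, mutant/genetic-interaction
  phenotype evidence and the generic experimental class).
* `expression_p_threshold` (default 0.05) — the significance cutoff for
  differential expression. The sign of the fold change is ignored: the
  question names both under- and over-expression without distinction.
* `cooccurrence_min_count` (default 1) — any observed co-occurrence with an
  aging term counts; no canonical threshold exists, so the default is the
  weakest defensible rule and is exposed.
* `genage_count_decrease` (default `FALSE`) — the curated-annotation check
  follows the increase-only rule; the flag widens it to any curated lifespan
  effect for sensitivity analyses.

## The synthetic generator

The generator (`generate_kb()`) builds all seven graphs from per-gene 9-bit
masks: for each gene it plants exactly the facts that make each evaluation
function return its mask bit, and records the ground truth in a ledger.
Design choices that keep the masks recoverable:

* Interaction partners (and their proteins and annotations) come from a
  dedicated per-gene helper pool that is never scored, so planting evidence
  for one gene cannot flip a verdict for another and per-gene outcomes stay
  independent — which is also what makes the independence combination model
  testable against the generator.
* The multi-study dietary-restriction bit is planted through a minted
  homolog with an asserted homology link, exercising the homolog code path
  that real data rarely reaches.
* Genes whose expression bit is off may still receive a non-significant
  record (p drawn from 0.1–0.9), so the threshold is exercised, not just
  presence of data.
* Co-occurrence terms are unique per gene, so co-occurrence evidence cannot
  leak between genes.

Default mask probabilities are the per-function satisfaction proportions
observed across the full 48,231-gene complement (6.6×10⁻³, 1.3×10⁻¹,
2.1×10⁻⁵, 1.1×10⁻³, 1.4×10⁻², 1.8×10⁻², 2.8×10⁻³, 2.5×10⁻², 1.4×10⁻¹ for
functions 1–9). What the generator does **not** emulate: realistic
(scale-free) interaction topology, correlated evidence between functions,
annotation noise, or any sequence data. Passing the mask-recovery property
therefore shows the rule stack is faithful to its definitions, not that the
rules are biologically optimal on real, messier data.

## Numerical choices

* Scores are exact rationals (integer counts over 9) until display;
  display rounding is half-away-from-zero to two decimals and never reorders
  raw scores.
* Candidate ranking (`identify_candidates()`) filters genes with any
  curated-lifespan or lifespan-phenotype contribution, ranks the rest by raw
  score, and breaks ties by gene identifier so output order is reproducible.
* The evidence-combination probability multiplies the proportions of the
  satisfied functions only, the natural reading of "observing
  this combination by chance"; the exact-mask variant (extra `1 − p`
  factors) is available via `include_unsatisfied = TRUE`.
* The two-sample Kolmogorov–Smirnov comparison computes D as the maximum
  ECDF distance and the asymptotic p-value from the Kolmogorov series
  (100 terms); it operates on raw scores by default because rounding scores
  to the display grid coarsens ties (`rounded = TRUE` switches).
* Typed literals: integers and decimals are compared numerically in
  filters, strings lexically; a non-numeric literal never satisfies a
  numeric comparison.
* Gene-to-curated-record joins are by approved gene symbol, case-sensitive
  exact match — fuzzier matching would silently change verdicts.
* Interaction records are stored directed as published and queried
  symmetrically.

## Problem sizes

The shipped tests evaluate cohorts of up to 500 synthetic genes (the
mask-recovery property, with per-function fractions checked against the
generator probabilities within three binomial standard errors), 100-gene
provenance round-trips, and brute-force join oracles on graphs of ~60 quads
— sizes at which the reference oracles (nested-loop join enumeration,
exhaustive double loops) remain exact and fast. The engine itself is linear
scans over an in-memory quad table; it is comfortable at 10³–10⁵ quads and
is not intended as a database.

## Known limitations

* The quad engine implements only the query fragment the rules need; it is
  not a SPARQL engine and does no reasoning.
* Only the aging event type has a registered domain rule; other event types
  parse and serialize but fail evaluation with an explicit error.
* The curated whitelists (PSI-MI methods, ECO classes, phenotype codes) are
  defaults, not authority; real analyses should configure them from the
  current releases of the underlying vocabularies.
* Scores weight all nine evidence types equally; differential weighting is a
  natural extension the data model already supports (contributions are
  recorded per function in provenance).

## A worked example

```{r worked}
kb <- plant_worked_example_sams1()
gene <- sams1_gene_id()
drf3_genage_lifespan(kb, gene)
head(drf12_gene_ppi(kb, gene), 4)
ev <- evaluate_hypothesis(kb, default_config(),
                          make_gene_aging_hypothesis(gene))
ev
```
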