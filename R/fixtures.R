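#' Worked-example fixture: the sams-1 gene
#'
#' A small knowledge base holding a fully worked reference example around the
#' S-adenosylmethionine synthetase gene sams-1 (wormbase:WBGene00008205).
#' The fixture reconstructs the curated database records for this gene
#' exactly:
#'
#' * one curated lifespan annotation (genage:0584, effect `"increase"`);
#' * the ten protein-interaction records over partners uniprot:O17680,
#'   P48181, P50305, P50306 and Q27522 with detection methods
#'   psi-mi:0397/0398/0676/0109 and one supporting article each;
#' * partner GO process annotations chosen so the interaction-neighborhood
#'   check fails (the partners are annotated with one-carbon metabolism, not
#'   an aging process);
#' * facts satisfying the remaining checks (significant expression change,
#'   multi-study DR expression via an asserted homolog, DR-essential
#'   membership, lifespan phenotype, experimental aging GO annotation, a
#'   genetic interaction with a lifespan-phenotype gene, and a GO term
#'   co-occurring with an aging term),
#'
#' so the full evaluation satisfies functions 1-6, 8 and 9 but not 7,
#' giving 8/9 = 0.89. The UniProt accession of the sams-1 protein itself is
#' not part of the reconstructed records; the fixture mints the synthetic
#' accession `uniprot:SYNSAMS1` for it.
#'
#' @return A knowledge base; the sams-1 gene identifier is attached as
#'   attribute `"gene"` (also exported as [sams1_gene_id()]).
#' @examples
#' kb <- plant_worked_example_sams1()
#' drf3_genage_lifespan(kb, sams1_gene_id())
#' @export
plant_worked_example_sams1 <- function() {
  gene <- sams1_gene_id()
  prot <- "uniprot:SYNSAMS1"  # synthetic accession; see docs
  cfg <- default_config()
  acc <- list()
  add <- function(g, s, p, o, literal = FALSE, datatype = NULL) {
    acc[[length(acc) + 1L]] <<- quads(g, s, p, o, literal, datatype)
  }

  # wormbase: symbol, lifespan phenotype, experimental aging GO annotation,
  # a non-aging GO term for the co-occurrence check, and a genetic
  # interaction with daf-2 (which carries a lifespan phenotype)
  add("wormbase", gene, WB("approved_gene_name"), "sams-1", literal = TRUE)
  add("wormbase", gene, WB("phenotype"), "wbphenotype:0000061")
  ann6 <- "wormbase:sams1_ann_aging"
  add("wormbase", gene, WB("go_annotation"), ann6)
  add("wormbase", ann6, WB("go_term"), "go:0008340")
  add("wormbase", ann6, WB("evidence"), "eco:0000269")
  ann9 <- "wormbase:sams1_ann_onecarbon"
  add("wormbase", gene, WB("go_annotation"), ann9)
  add("wormbase", ann9, WB("go_term"), "go:0006730")  # one-carbon metabolism
  add("wormbase", ann9, WB("evidence"), "eco:0000501")
  daf2 <- "wormbase:WBGene00000898"
  add("wormbase", daf2, WB("approved_gene_name"), "daf-2", literal = TRUE)
  add("wormbase", gene, WB("interacts_with"), daf2)
  add("wormbase", daf2, WB("phenotype"), "wbphenotype:0000061")

  # genage: the curated lifespan record
  add("genage", "genage:0584", GA("gene_symbol"), "sams-1", literal = TRUE)
  add("genage", "genage:0584", GA("lifespan_effect"), "increase",
      literal = TRUE)

  # goa: gene-symbol -> protein link and the partners' process annotations
  add("goa", prot, GO_V("gene_symbol"), "sams-1", literal = TRUE)
  partners <- c("uniprot:O17680", "uniprot:P48181", "uniprot:P50305",
                "uniprot:P50306", "uniprot:Q27522")
  for (p in partners) {
    pann <- mint("goa", paste0("ann_", id_local(p)))
    add("goa", p, GO_V("go_annotation"), pann)
    add("goa", pann, GO_V("go_term"), "go:0006730")
    add("goa", pann, GO_V("aspect"), "process", literal = TRUE)
  }

  # ppi: the ten curated (partner, method) records, one article each
  methods <- list("uniprot:O17680" = c("psi-mi:0397", "psi-mi:0398"),
                  "uniprot:P48181" = c("psi-mi:0676", "psi-mi:0109"),
                  "uniprot:P50305" = c("psi-mi:0397", "psi-mi:0398"),
                  "uniprot:P50306" = c("psi-mi:0397", "psi-mi:0398"),
                  "uniprot:Q27522" = c("psi-mi:0397", "psi-mi:0398"))
  k <- 0L
  for (p in names(methods)) {
    for (m in methods[[p]]) {
      k <- k + 1L
      int <- mint("irefindex", sprintf("sams1_int%02d", k))
      add("ppi", int, IX("interactor_a"), prot)
      add("ppi", int, IX("interactor_b"), p)
      add("ppi", int, IX("method"), m)
      add("ppi", int, IX("article_count"), 1L, literal = TRUE,
          datatype = "integer")
    }
  }

  # expression: one significant fold-change record (sams-1 cosmid C49F5)
  fc <- "expression:sams1_fc1"
  add("expression", fc, EX("gene"), gene)
  add("expression", fc, EX("cosmid"), "C49F5.1", literal = TRUE)
  add("expression", fc, EX("fold_change"), -1.7, literal = TRUE,
      datatype = "decimal")
  add("expression", fc, EX("p_value"), 0.003, literal = TRUE,
      datatype = "decimal")
  add("expression", fc, EX("experiment"), "geo:GSE36041")
  add("expression", fc, EX("derived_from"), "expression:sams1_ev1")
  add("expression", fc, EX("derived_from"), "expression:sams1_ev2")

  # gendr: DR-essential membership; multi-study DR expression via the
  # asserted mammalian homolog (MAT1A)
  add("gendr", gene, GD("member_of"), GENDR_ESSENTIAL_LIST)
  add("gendr", gene, GD("homolog"), "ncbigene:4143")
  add("gendr", "ncbigene:4143", GD("member_of"), GENDR_MULTISTUDY_LIST)

  # go_cooccurrence: one-carbon metabolism co-annotated with adult-lifespan
  # determination
  add("go_cooccurrence", "gocooc:sams1_c1", CO("term_a"), "go:0006730")
  add("go_cooccurrence", "gocooc:sams1_c1", CO("term_b"), "go:0008340")
  add("go_cooccurrence", "gocooc:sams1_c1", CO("count"), 12L,
      literal = TRUE, datatype = "integer")

  kb <- kb_add(kb_new(), do.call(rbind, acc))
  attr(kb, "gene") <- gene
  kb
}

#' @rdname plant_worked_example_sams1
#' @export
sams1_gene_id <- function() "wormbase:WBGene00008205"
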