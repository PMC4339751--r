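#' Gene-centric data-retrieval functions
#'
#' The retrieval layer is a set of pure, side-effect-free queries, each
#' reading one (or, for the composed protein-interaction lookup, three)
#' named graph(s) of the knowledge base. Absence of data is always an empty
#' result, never an error: the evaluation layer interprets absence as lack
#' of evidence. Retrieval and evaluation are deliberately separated so that
#' either can change without touching the other.
#'
#' @param kb A knowledge base.
#' @param gene A `wormbase`-namespace gene identifier.
#' @name retrieval
NULL

#' @describeIn retrieval Approved gene symbol for a gene, from the gene
#'   annotation graph. Returns `NA_character_` when the gene is absent
#'   (an empty result, distinct from an error).
#' @export
drf6_gene_symbol <- function(kb, gene) {
  m <- kb_match(kb, graph_pattern(c(gene, WB("approved_gene_name"), "?sym"),
                                  graph = "wormbase"))
  if (nrow(m) == 0L) NA_character_ else m$sym[[1L]]
}

#' @describeIn retrieval Curated lifespan annotations: joins the gene's
#'   approved symbol (case-sensitive exact match) to curated records keyed by
#'   gene name, returning a data frame with columns `genage_id`, `effect`.
#' @export
drf3_genage_lifespan <- function(kb, gene) {
  sym <- drf6_gene_symbol(kb, gene)
  empty <- data.frame(genage_id = character(), effect = character(),
                      stringsAsFactors = FALSE)
  if (is.na(sym)) return(empty)
  m <- kb_match(kb, graph_pattern(c("?rec", GA("gene_symbol"), "?sym"),
                                  c("?rec", GA("lifespan_effect"), "?eff"),
                                  graph = "genage",
                                  filters = list(value_filter("sym", "==", sym))))
  if (nrow(m) == 0L) return(empty)
  out <- data.frame(genage_id = m$rec, effect = m$eff, stringsAsFactors = FALSE)
  out[order(out$genage_id, out$effect), , drop = FALSE]
}

#' @describeIn retrieval UniProt protein identifiers carrying the given gene
#'   symbol in the protein-annotation graph.
#' @param symbol An approved gene symbol string.
#' @export
drf1_uniprot_ids <- function(kb, symbol) {
  if (is.na(symbol)) return(character())
  m <- kb_match(kb, graph_pattern(c("?prot", GO_V("gene_symbol"), "?sym"),
                                  graph = "goa",
                                  filters = list(value_filter("sym", "==", symbol))))
  sort(unique(m$prot))
}

#' @describeIn retrieval Protein-protein interactions for one protein: one
#'   record per (partner, method) pair with its supporting-article count.
#'   Interaction records are stored directed as published but queried
#'   symmetrically, so partners are found whichever side of the record the
#'   query protein sits on.
#' @param protein A `uniprot`-namespace protein identifier.
#' @export
drf8_ppi <- function(kb, protein) {
  empty <- data.frame(partner = character(), method = character(),
                      articles = integer(), stringsAsFactors = FALSE)
  recs <- list(empty)
  for (side in list(c("interactor_a", "interactor_b"),
                    c("interactor_b", "interactor_a"))) {
    m <- kb_match(kb, graph_pattern(
      c("?i", IX(side[1]), protein),
      c("?i", IX(side[2]), "?partner"),
      c("?i", IX("method"), "?method"),
      c("?i", IX("article_count"), "?n"),
      graph = "ppi"))
    if (nrow(m)) {
      recs[[length(recs) + 1L]] <-
        data.frame(partner = m$partner, method = m$method,
                   articles = as.integer(m$n), stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, recs))
  out <- out[order(out$partner, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn retrieval Composition symbol -> proteins -> interactions:
#'   the union of [drf8_ppi()] over every protein product of the gene. When a
#'   stage returns nothing the result is empty and the attribute
#'   `"empty_stage"` names the stage that emptied (`"symbol"`, `"proteins"`
#'   or `"interactions"`).
#' @export
drf12_gene_ppi <- function(kb, gene) {
  empty <- data.frame(partner = character(), method = character(),
                      articles = integer(), stringsAsFactors = FALSE)
  sym <- drf6_gene_symbol(kb, gene)
  if (is.na(sym)) return(structure(empty, empty_stage = "symbol"))
  prots <- drf1_uniprot_ids(kb, sym)
  if (length(prots) == 0L) return(structure(empty, empty_stage = "proteins"))
  out <- unique(do.call(rbind, c(list(empty), lapply(prots, drf8_ppi, kb = kb))))
  if (nrow(out) == 0L) return(structure(empty, empty_stage = "interactions"))
  out <- out[order(out$partner, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn retrieval GO biological-process annotations of a protein
#'   (other aspects are excluded), as a data frame `entity`, `term`.
#' @export
drf9_go_process <- function(kb, protein) {
  m <- kb_match(kb, graph_pattern(
    c(protein, GO_V("go_annotation"), "?ann"),
    c("?ann", GO_V("go_term"), "?term"),
    c("?ann", GO_V("aspect"), "?aspect"),
    graph = "goa",
    filters = list(value_filter("aspect", "==", "process"))))
  if (nrow(m) == 0L) {
    return(data.frame(entity = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(data.frame(entity = protein, term = m$term,
                           stringsAsFactors = FALSE))
  out[order(out$term), , drop = FALSE]
}

#' @describeIn retrieval Phenotype classes asserted on the gene (direct or
#'   RNAi-knockdown annotations are modelled identically).
#' @export
get_phenotypes <- function(kb, gene) {
  m <- kb_match(kb, graph_pattern(c(gene, WB("phenotype"), "?ph"),
                                  graph = "wormbase"))
  sort(unique(m$ph))
}

#' @describeIn retrieval Expression fold-change records measured for the
#'   gene: columns `record`, `fold_change`, `p_value`, `experiment`,
#'   `cosmid`, `n_derived_from`.
#' @export
get_expression_changes <- function(kb, gene) {
  m <- kb_match(kb, graph_pattern(
    c("?fc", EX("gene"), gene),
    c("?fc", EX("fold_change"), "?fold"),
    c("?fc", EX("p_value"), "?p"),
    c("?fc", EX("experiment"), "?exp"),
    c("?fc", EX("cosmid"), "?cos"),
    graph = "expression"))
  if (nrow(m) == 0L) {
    return(data.frame(record = character(), fold_change = numeric(),
                      p_value = numeric(), experiment = character(),
                      cosmid = character(), n_derived_from = integer(),
                      stringsAsFactors = FALSE))
  }
  nd <- vapply(m$fc, function(node) {
    nrow(kb_match(kb, graph_pattern(c(node, EX("derived_from"), "?v"),
                                    graph = "expression")))
  }, integer(1))
  out <- data.frame(record = m$fc, fold_change = as.numeric(m$fold),
                    p_value = as.numeric(m$p), experiment = m$exp,
                    cosmid = m$cos, n_derived_from = nd,
                    stringsAsFactors = FALSE)
  out <- out[order(out$record), , drop = FALSE]
  rownames(out) <- NULL
  out
}

gendr_member <- function(kb, node, list_node) {
  kb_ask(kb, graph_pattern(c(node, GD("member_of"), list_node),
                           graph = "gendr"))
}

#' @describeIn retrieval Is the gene — or an asserted homolog of it — in the
#'   multi-study dietary-restriction differential-expression set? Homology
#'   must be asserted in the dietary-restriction graph; no homolog inference
#'   is performed.
#' @export
get_gendr_multistudy <- function(kb, gene) {
  if (gendr_member(kb, gene, GENDR_MULTISTUDY_LIST)) return(TRUE)
  hom <- kb_match(kb, graph_pattern(c(gene, GD("homolog"), "?h"),
                                    graph = "gendr"))
  any(vapply(hom$h, gendr_member, logical(1),
             kb = kb, list_node = GENDR_MULTISTUDY_LIST))
}

#' @describeIn retrieval Is the gene in the dietary-restriction-essential
#'   set (its manipulation alters DR-conferred lifespan extension)?
#' @export
get_gendr_dr_essential <- function(kb, gene) {
  gendr_member(kb, gene, GENDR_ESSENTIAL_LIST)
}

#' @describeIn retrieval The gene's own GO annotations with their evidence
#'   class, as a data frame `term`, `evidence`.
#' @export
get_gene_go_with_evidence <- function(kb, gene) {
  m <- kb_match(kb, graph_pattern(
    c(gene, WB("go_annotation"), "?ann"),
    c("?ann", WB("go_term"), "?term"),
    c("?ann", WB("evidence"), "?ev"),
    graph = "wormbase"))
  if (nrow(m) == 0L) {
    return(data.frame(term = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(data.frame(term = m$term, evidence = m$ev,
                           stringsAsFactors = FALSE))
  out[order(out$term, out$evidence), , drop = FALSE]
}

#' @describeIn retrieval Genes the query gene genetically interacts with
#'   (queried symmetrically), each with any phenotype classes asserted on it:
#'   a data frame `partner`, `phenotype` (`NA` when the partner has none).
#' @export
get_gene_interactions <- function(kb, gene) {
  partners <- character()
  for (side in list(c(1L, 3L), c(3L, 1L))) {
    tp <- c(gene, WB("interacts_with"), "?other")
    if (side[1L] == 3L) tp <- c("?other", WB("interacts_with"), gene)
    m <- kb_match(kb, graph_pattern(tp, graph = "wormbase"))
    partners <- c(partners, m$other)
  }
  partners <- sort(unique(partners))
  if (length(partners) == 0L) {
    return(data.frame(partner = character(), phenotype = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(partners, function(p) {
    ph <- get_phenotypes(kb, p)
    if (length(ph) == 0L) ph <- NA_character_
    data.frame(partner = p, phenotype = ph, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn retrieval Co-occurrence count for an unordered pair of GO
#'   terms (symmetric: `get_cooccurrence(a, b) == get_cooccurrence(b, a)`).
#' @param term_a,term_b GO term identifiers.
#' @export
get_cooccurrence <- function(kb, term_a, term_b) {
  total <- 0L
  for (pair in list(c(term_a, term_b), c(term_b, term_a))) {
    m <- kb_match(kb, graph_pattern(
      c("?rec", CO("term_a"), pair[1]),
      c("?rec", CO("term_b"), pair[2]),
      c("?rec", CO("count"), "?n"),
      graph = "go_cooccurrence"))
    if (nrow(m)) total <- total + sum(as.integer(m$n))
  }
  total
}
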