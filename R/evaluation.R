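#' The nine aging-domain evidence evaluation functions
#'
#' Each evaluation function (DEF1..DEF9) answers one boolean evidence
#' question about a gene's involvement in aging, by calling one or more
#' retrieval functions and assessing what comes back. A `TRUE` verdict
#' contributes 1 to the event score, `FALSE` contributes 0; the event score
#' is the number of satisfied functions divided by 9. The questions are:
#'
#' 1. Does the gene have a human-curated aging/longevity annotation
#'    (curated lifespan effect `"increase"`)?
#' 2. Is the gene significantly differentially expressed when genes that
#'    regulate known aging-related pathways are manipulated?
#' 3. Is the gene, or an asserted homolog, differentially expressed under
#'    dietary restriction across multiple studies?
#' 4. Is its effect on DR-conferred lifespan extension altered when its
#'    expression is manipulated (DR-essential set)?
#' 5. Does the gene (or its knockdown) have an extended/shortened-lifespan
#'    phenotype?
#' 6. Does the gene have an aging-related GO annotation backed by
#'    experimental evidence?
#' 7. Does its protein product interact — by a high-confidence detection
#'    method — with a protein annotated with an aging-related process?
#' 8. Does the gene interact with genes that extend or shorten lifespan?
#' 9. Do the gene's GO annotations co-occur with aging-related annotations?
#'
#' @param kb A knowledge base.
#' @param cfg An evaluation config from [default_config()].
#' @param gene A `wormbase`-namespace gene identifier.
#' @return Each `defN_*` function returns an evidence result: a list with
#'   `def_id`, `satisfied`, `score_contribution` (0/1), `supporting_facts`
#'   (the retrieved records backing the verdict) and `drfs_called`.
#' @name evaluation
NULL

evidence_result <- function(def_id, satisfied, supporting_facts, drfs_called) {
  stopifnot(def_id %in% 1:9, is.logical(satisfied), length(satisfied) == 1L)
  structure(list(def_id = as.integer(def_id),
                 satisfied = satisfied,
                 score_contribution = as.integer(satisfied),
                 supporting_facts = supporting_facts,
                 drfs_called = drfs_called),
            class = "evidence_result")
}

#' @describeIn evaluation Curated lifespan annotation (question 1).
#' @export
def1_curated_lifespan <- function(kb, cfg, gene) {
  ann <- drf3_genage_lifespan(kb, gene)
  effects <- cfg$genage_positive_effect
  if (isTRUE(cfg$genage_count_decrease)) effects <- c(effects, "decrease")
  hits <- ann[ann$effect %in% effects, , drop = FALSE]
  evidence_result(1L, nrow(hits) > 0L, hits, c("drf6_gene_symbol",
                                               "drf3_genage_lifespan"))
}

#' @describeIn evaluation Significant differential expression under
#'   aging-pathway manipulation (question 2); only significance matters,
#'   under- and over-expression count alike.
#' @export
def2_expression <- function(kb, cfg, gene) {
  rec <- get_expression_changes(kb, gene)
  hits <- rec[rec$p_value < cfg$expression_p_threshold, , drop = FALSE]
  evidence_result(2L, nrow(hits) > 0L, hits, "get_expression_changes")
}

#' @describeIn evaluation Multi-study dietary-restriction differential
#'   expression, directly or through an asserted homolog (question 3).
#' @export
def3_dr_multistudy <- function(kb, cfg, gene) {
  hit <- get_gendr_multistudy(kb, gene)
  evidence_result(3L, hit,
                  if (hit) data.frame(gene = gene, set = GENDR_MULTISTUDY_LIST,
                                      stringsAsFactors = FALSE)
                  else data.frame(),
                  "get_gendr_multistudy")
}

#' @describeIn evaluation Membership in the DR-essential gene set
#'   (question 4).
#' @export
def4_dr_essential <- function(kb, cfg, gene) {
  hit <- get_gendr_dr_essential(kb, gene)
  evidence_result(4L, hit,
                  if (hit) data.frame(gene = gene, set = GENDR_ESSENTIAL_LIST,
                                      stringsAsFactors = FALSE)
                  else data.frame(),
                  "get_gendr_dr_essential")
}

#' @describeIn evaluation Extended/shortened-lifespan phenotype on the gene
#'   (question 5).
#' @export
def5_lifespan_phenotype <- function(kb, cfg, gene) {
  ph <- get_phenotypes(kb, gene)
  hits <- intersect(ph, cfg$lifespan_phenotypes)
  evidence_result(5L, length(hits) > 0L,
                  data.frame(phenotype = hits, stringsAsFactors = FALSE),
                  "get_phenotypes")
}

#' @describeIn evaluation Aging-related GO annotation with experimental
#'   evidence (question 6).
#' @export
def6_experimental_go <- function(kb, cfg, gene) {
  ann <- get_gene_go_with_evidence(kb, gene)
  hits <- ann[ann$term %in% cfg$aging_go_terms &
                ann$evidence %in% cfg$experimental_evidence, , drop = FALSE]
  evidence_result(6L, nrow(hits) > 0L, hits, "get_gene_go_with_evidence")
}

#' @describeIn evaluation Protein interaction, via a high-confidence
#'   detection method, with a protein annotated with an aging-related
#'   process (question 7). Supporting facts are the witnessing
#'   (partner, method, term) triples.
#' @export
def7_ppi_aging_neighbors <- function(kb, cfg, gene) {
  ppi <- drf12_gene_ppi(kb, gene)
  hc <- ppi[ppi$method %in% cfg$high_confidence_methods, , drop = FALSE]
  witnesses <- list()
  for (partner in unique(hc$partner)) {
    terms <- drf9_go_process(kb, partner)
    aging <- intersect(terms$term, cfg$aging_go_terms)
    if (length(aging)) {
      pm <- hc[hc$partner == partner, , drop = FALSE]
      witnesses[[partner]] <- merge(pm[, c("partner", "method")],
                                    data.frame(partner = partner, term = aging,
                                               stringsAsFactors = FALSE),
                                    by = "partner")
    }
  }
  facts <- if (length(witnesses)) do.call(rbind, unname(witnesses))
           else data.frame(partner = character(), method = character(),
                           term = character(), stringsAsFactors = FALSE)
  rownames(facts) <- NULL
  evidence_result(7L, nrow(facts) > 0L, facts,
                  c("drf12_gene_ppi", "drf6_gene_symbol", "drf1_uniprot_ids",
                    "drf8_ppi", "drf9_go_process"))
}

#' @describeIn evaluation Genetic interaction with lifespan-phenotype genes
#'   (question 8).
#' @export
def8_interacting_lifespan <- function(kb, cfg, gene) {
  gi <- get_gene_interactions(kb, gene)
  hits <- gi[!is.na(gi$phenotype) &
               gi$phenotype %in% cfg$lifespan_phenotypes, , drop = FALSE]
  rownames(hits) <- NULL
  evidence_result(8L, nrow(hits) > 0L, hits, "get_gene_interactions")
}

#' @describeIn evaluation GO annotation co-occurrence with aging terms
#'   (question 9).
#' @export
def9_go_cooccurrence <- function(kb, cfg, gene) {
  ann <- get_gene_go_with_evidence(kb, gene)
  terms <- unique(ann$term)
  witnesses <- list()
  for (t in terms) {
    for (a in cfg$aging_go_terms) {
      n <- get_cooccurrence(kb, t, a)
      if (n >= cfg$cooccurrence_min_count) {
        witnesses[[paste(t, a)]] <- data.frame(term = t, aging_term = a,
                                               count = n,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  facts <- if (length(witnesses)) do.call(rbind, unname(witnesses))
           else data.frame(term = character(), aging_term = character(),
                           count = integer(), stringsAsFactors = FALSE)
  rownames(facts) <- NULL
  evidence_result(9L, nrow(facts) > 0L, facts,
                  c("get_gene_go_with_evidence", "get_cooccurrence"))
}

DEF_FUNCTIONS <- function() {
  list(def1_curated_lifespan, def2_expression, def3_dr_multistudy,
       def4_dr_essential, def5_lifespan_phenotype, def6_experimental_go,
       def7_ppi_aging_neighbors, def8_interacting_lifespan,
       def9_go_cooccurrence)
}

#' @describeIn evaluation Run all nine evaluation functions for one gene,
#'   returning a list of nine evidence results (ids 1..9 in order).
#' @export
evaluate_gene_defs <- function(kb, cfg, gene) {
  lapply(DEF_FUNCTIONS(), function(f) f(kb, cfg, gene))
}

#' Aggregate nine evidence results into an event score
#'
#' The event score is the number of satisfied evaluation functions divided
#' by the maximum possible (9). The exact rational is kept internally;
#' [score_display()] rounds half away from zero to two decimals for
#' reporting, reproducing the familiar 8/9 = 0.89, 7/9 = 0.78, ... grid.
#'
#' @param def_results A list of exactly nine evidence results, one per
#'   function id 1..9.
#' @return An `event_score`: list with `raw` (0..9), `normalized` (raw/9),
#'   `display` (rounded), `def_results`.
#' @examples
#' score_display(6 / 9)  # 0.67
#' @export
score_event <- function(def_results) {
  ids <- vapply(def_results, function(r) r$def_id, integer(1))
  if (length(ids) != 9L || !identical(sort(ids), 1:9)) {
    stop("score_event() needs exactly one result per evaluation function 1..9",
         call. = FALSE)
  }
  def_results <- def_results[order(ids)]
  raw <- sum(vapply(def_results, function(r) r$score_contribution, integer(1)))
  structure(list(raw = raw, normalized = raw / 9,
                 display = score_display(raw / 9),
                 def_results = def_results),
            class = "event_score")
}

#' @rdname score_event
#' @param x Numeric score(s) in \[0, 1\].
#' @export
score_display <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}
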