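#' Batch evaluation and results analytics
#'
#' Everything downstream of single-hypothesis evaluation: evaluating every
#' gene in a list, histogramming the displayed scores, tabulating how often
#' each evidence function is satisfied, the independence model for the
#' probability of an evidence combination arising by chance, ranking
#' candidate genes whose aging involvement is not already curated, comparing
#' two score distributions with a two-sample Kolmogorov-Smirnov test, and
#' computing GO-term co-occurrence counts from an annotation graph.
#'
#' @name analysis
NULL

#' @describeIn analysis Evaluate the aging hypothesis for each gene. Per-gene
#'   failures are caught, logged and reported in the `"failures"` attribute
#'   so a long batch run survives isolated bad records.
#' @param kb A knowledge base.
#' @param cfg An evaluation config.
#' @param genes Character vector of gene identifiers.
#' @param fixed_clock Optional timestamp recorded on every evaluation.
#' @param progress Emit a progress message every `progress` genes (0 = quiet).
#' @export
batch_evaluate <- function(kb, cfg, genes, fixed_clock = NULL, progress = 0L) {
  if (length(genes) == 0L) stop("batch_evaluate() needs at least one gene",
                                call. = FALSE)
  evals <- vector("list", length(genes))
  failures <- character()
  for (i in seq_along(genes)) {
    h <- make_gene_aging_hypothesis(genes[i])
    res <- tryCatch(evaluate_hypothesis(kb, cfg, h, fixed_clock = fixed_clock),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[genes[i]] <- conditionMessage(res)
      message("evaluation failed for ", genes[i], ": ", conditionMessage(res))
    } else {
      evals[[i]] <- res
    }
    if (progress > 0L && i %% progress == 0L) {
      message("evaluated ", i, "/", length(genes), " genes")
    }
  }
  evals <- evals[!vapply(evals, is.null, logical(1))]
  attr(evals, "failures") <- failures
  evals
}

#' @describeIn analysis Flatten evaluations into a per-gene table:
#'   `gene`, `def1`..`def9` (0/1), `raw`, `normalized`, `score` (displayed).
#' @param evals A list of hypothesis evaluations.
#' @export
evaluation_table <- function(evals) {
  rows <- lapply(evals, function(ev) {
    out <- lapply(names(ev$events), function(path) {
      e <- ev$events[[path]]
      row <- data.frame(gene = e$gene, stringsAsFactors = FALSE)
      for (r in e$score$def_results) {
        row[[paste0("def", r$def_id)]] <- r$score_contribution
      }
      row$raw <- e$score$raw
      row$normalized <- e$score$normalized
      row$score <- e$score$display
      row
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn analysis Histogram of displayed scores, highest first:
#'   columns `score`, `n_genes`. Counts sum to the number of evaluated
#'   genes.
#' @export
score_distribution <- function(evals) {
  if (length(evals) == 0L) {
    return(data.frame(score = numeric(), n_genes = integer()))
  }
  tab <- evaluation_table(evals)
  agg <- as.data.frame(table(tab$score), stringsAsFactors = FALSE)
  names(agg) <- c("score", "n_genes")
  agg$score <- as.numeric(agg$score)
  agg <- agg[order(-agg$score), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @describeIn analysis Per-function satisfaction counts and proportions
#'   over the evaluated genes: columns `def`, `satisfied`, `proportion`.
#' @export
def_frequencies <- function(evals) {
  tab <- evaluation_table(evals)
  n <- nrow(tab)
  counts <- vapply(1:9, function(k) sum(tab[[paste0("def", k)]]), numeric(1))
  data.frame(def = 1:9, satisfied = as.integer(counts),
             proportion = counts / n)
}

#' @describeIn analysis Frequency table from externally reported counts
#'   (e.g. a previously reported satisfaction table), for use with
#'   [combination_probability()].
#' @param satisfied_counts Nine satisfaction counts (DEF1..DEF9).
#' @param n_genes Number of genes the counts were measured over.
#' @export
def_frequency_table <- function(satisfied_counts, n_genes) {
  stopifnot(length(satisfied_counts) == 9L)
  data.frame(def = 1:9, satisfied = as.integer(satisfied_counts),
             proportion = satisfied_counts / n_genes)
}

#' @describeIn analysis Probability, under per-function independence, of a
#'   gene showing a given satisfied-function combination by chance. The
#'   default multiplies the proportions of the satisfied functions only;
#'   `include_unsatisfied = TRUE` additionally multiplies `(1 - p)` for the
#'   functions outside the combination (the probability of exactly that
#'   mask).
#' @param freq A frequency table from [def_frequencies()] or
#'   [def_frequency_table()].
#' @param combo Integer vector of satisfied function ids.
#' @param include_unsatisfied Multiply `(1 - p)` factors for the rest?
#' @export
combination_probability <- function(freq, combo, include_unsatisfied = FALSE) {
  combo <- as.integer(combo)
  if (length(combo) == 0L || !all(combo %in% 1:9)) {
    stop("combo must name evaluation functions in 1..9", call. = FALSE)
  }
  p <- freq$proportion[match(combo, freq$def)]
  out <- prod(p)
  if (include_unsatisfied) {
    rest <- setdiff(1:9, combo)
    out <- out * prod(1 - freq$proportion[match(rest, freq$def)])
  }
  out
}

#' @describeIn analysis Expected number of genes showing the combination by
#'   chance in a gene set of size `n_genes`.
#' @param p A combination probability.
#' @export
expected_count <- function(p, n_genes) p * n_genes

#' @describeIn analysis Candidate aging-related genes: the highest-scoring
#'   genes with no existing curated aging annotation — no contribution from
#'   the curated-lifespan check (function 1) or the lifespan-phenotype check
#'   (function 5). Ranking uses the exact raw score; ties within a tier are
#'   ordered by gene identifier for reproducibility. Columns: `gene`, `raw`,
#'   `score` (displayed tier), `defs` (satisfied-function set, e.g.
#'   `"2,7,8,9"`), `top_tier`.
#' @param tiers `"top"` returns only the maximum remaining tier; `"all"`
#'   every non-zero tier in rank order.
#' @export
identify_candidates <- function(evals, tiers = c("all", "top")) {
  tiers <- match.arg(tiers)
  tab <- evaluation_table(evals)
  cand <- tab[tab$def1 == 0 & tab$def5 == 0 & tab$raw > 0, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(gene = character(), raw = integer(), score = numeric(),
                      defs = character(), top_tier = logical(),
                      stringsAsFactors = FALSE))
  }
  cand <- cand[order(-cand$raw, cand$gene), , drop = FALSE]
  defs <- apply(cand[paste0("def", 1:9)], 1L, function(m) {
    paste(which(m == 1), collapse = ",")
  })
  out <- data.frame(gene = cand$gene, raw = cand$raw,
                    score = score_display(cand$raw / 9), defs = defs,
                    top_tier = cand$raw == max(cand$raw),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (tiers == "top") out[out$top_tier, , drop = FALSE] else out
}

#' @describeIn analysis Two-sample Kolmogorov-Smirnov comparison of score
#'   samples: the statistic `D` (maximum ECDF distance) and the asymptotic
#'   p-value. Computed on raw scores by default; `rounded = TRUE` compares
#'   displayed (two-decimal) scores instead.
#' @param scores_a,scores_b Numeric score samples.
#' @param rounded Compare displayed scores?
#' @export
compare_distributions <- function(scores_a, scores_b, rounded = FALSE) {
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    stop("both score samples must be non-empty", call. = FALSE)
  }
  if (rounded) {
    scores_a <- score_display(scores_a)
    scores_b <- score_display(scores_b)
  }
  D <- ks_statistic(scores_a, scores_b)
  n1 <- length(scores_a); n2 <- length(scores_b)
  n_eff <- n1 * n2 / (n1 + n2)
  p <- ks_asymptotic_p(sqrt(n_eff) * D)  # standard asymptotic approximation
  list(statistic = D, p_value = p, n = c(n1, n2))
}

ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# Kolmogorov asymptotic survival function Q(lambda)
ks_asymptotic_p <- function(lambda) {
  if (lambda < 1e-12) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @describeIn analysis GO-term co-occurrence counts from the
#'   protein-annotation graph: for every annotated entity, each unordered
#'   pair of its distinct terms counts once (duplicate annotation rows are
#'   deduplicated first, so counts are over entities, not annotation rows).
#'   Returns columns `term_a`, `term_b` (`term_a < term_b`), `count`.
#' @param graph Graph role holding the annotations (default `"goa"`).
#' @export
go_cooccurrence <- function(kb, graph = "goa") {
  m <- kb_match(kb, graph_pattern(
    c("?ent", GO_V("go_annotation"), "?ann"),
    c("?ann", GO_V("go_term"), "?term"),
    graph = graph))
  if (nrow(m) == 0L) {
    return(data.frame(term_a = character(), term_b = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  per_entity <- split(m$term, m$ent)
  pair_rows <- lapply(per_entity, function(terms) {
    terms <- sort(unique(terms))
    if (length(terms) < 2L) return(NULL)
    idx <- utils::combn(length(terms), 2L)
    data.frame(term_a = terms[idx[1L, ]], term_b = terms[idx[2L, ]],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs)) {
    return(data.frame(term_a = character(), term_b = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(pairs))),
                          by = pairs[c("term_a", "term_b")], FUN = sum)
  agg <- agg[order(agg$term_a, agg$term_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @describeIn analysis Serialize a co-occurrence table into quads for the
#'   `go_cooccurrence` graph role consumed by the co-occurrence evaluation
#'   function.
#' @param cooc A co-occurrence table from [go_cooccurrence()].
#' @export
cooccurrence_quads <- function(cooc, graph = "go_cooccurrence") {
  if (nrow(cooc) == 0L) return(empty_quads())
  nodes <- mint("gocooc", sprintf("pair%05d", seq_len(nrow(cooc))))
  rbind(quads(graph, nodes, CO("term_a"), cooc$term_a),
        quads(graph, nodes, CO("term_b"), cooc$term_b),
        quads(graph, nodes, CO("count"), as.integer(cooc$count),
              literal = TRUE, datatype = "integer"))
}
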