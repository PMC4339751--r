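#' Conjunctive graph-pattern matching
#'
#' A graph pattern is an ordered list of (subject, predicate, object) triple
#' templates in which any position may be a variable (a string starting with
#' `"?"`), optionally restricted to one graph and refined by value filters
#' (set membership, or numeric comparison on typed literals). [kb_match()]
#' returns exactly the variable bindings a naive nested-loop join over the
#' quad multiset would return (deduplicated; order unspecified). This is the
#' query surface every data-retrieval function is built on; it deliberately
#' covers conjunctive patterns only — no OPTIONAL/UNION.
#'
#' @param ... Triple templates, each a character vector `c(s, p, o)`.
#' @param graph Optional graph name restriction; a reference to a graph not
#'   present in the store yields an empty result, not an error.
#' @param filters Optional list of filters from [value_filter()].
#' @return For `graph_pattern()`, a pattern object. For `kb_match()`, a data
#'   frame with one column per variable (names without the `?`) and one row
#'   per solution.
#' @examples
#' kb <- kb_add(kb_new(), quads("wormbase", "wormbase:WBGene00000898",
#'                              "wormbase_vocabulary:approved_gene_name",
#'                              "daf-2", literal = TRUE))
#' pat <- graph_pattern(c("?g", "wormbase_vocabulary:approved_gene_name", "?sym"),
#'                      graph = "wormbase")
#' kb_match(kb, pat)
#' @export
graph_pattern <- function(..., graph = NULL, filters = list()) {
  triples <- list(...)
  if (length(triples) == 0L) stop("a graph pattern needs at least one triple",
                                  call. = FALSE)
  for (tp in triples) {
    if (!is.character(tp) || length(tp) != 3L) {
      stop("each triple template must be a character vector c(s, p, o)",
           call. = FALSE)
    }
  }
  for (f in filters) {
    if (!inherits(f, "value_filter")) {
      stop("filters must be built with value_filter()", call. = FALSE)
    }
  }
  structure(list(triples = triples, graph = graph, filters = filters),
            class = "graph_pattern")
}

#' @rdname graph_pattern
#' @param var Variable name the filter applies to (with or without `?`).
#' @param op One of `"in"`, `"=="`, `"!="`, `"<"`, `"<="`, `">"`, `">="`.
#'   Comparison operators coerce the bound literal to numeric; non-numeric
#'   bindings never satisfy a numeric comparison.
#' @param value The comparison value, or the membership set for `"in"`.
#' @export
value_filter <- function(var, op, value) {
  op <- match.arg(op, c("in", "==", "!=", "<", "<=", ">", ">="))
  if (op != "in" && length(value) != 1L) {
    stop("comparison filters take a single value", call. = FALSE)
  }
  structure(list(var = sub("^\\?", "", var), op = op, value = value),
            class = "value_filter")
}

is_pat_var <- function(x) startsWith(x, "?")

#' @rdname graph_pattern
#' @param kb A knowledge base.
#' @param pattern A [graph_pattern()].
#' @export
kb_match <- function(kb, pattern) {
  stopifnot(inherits(pattern, "graph_pattern"))
  qd <- kb_quads(kb, pattern$graph)
  # one universal binding row; real variable columns accrete as we join
  bindings <- data.frame(.k = 1L)
  for (tp in pattern$triples) {
    cand <- qd
    cols <- list()
    for (pos in 1:3) {
      term <- tp[pos]
      col <- c("s", "p", "o")[pos]
      if (is_pat_var(term)) {
        vname <- sub("^\\?", "", term)
        if (vname %in% names(cols)) {
          cand <- cand[cand[[cols[[vname]]]] == cand[[col]], , drop = FALSE]
        } else {
          cols[[vname]] <- col
        }
      } else {
        cand <- cand[cand[[col]] == term, , drop = FALSE]
      }
    }
    sol <- data.frame(.k = rep(1L, nrow(cand)))
    for (vname in names(cols)) sol[[vname]] <- cand[[cols[[vname]]]]
    shared <- intersect(names(bindings), names(sol))
    bindings <- merge(bindings, sol, by = shared)
    if (nrow(bindings) == 0L) break
  }
  pattern_vars <- sub("^\\?", "", unlist(lapply(pattern$triples, function(tp) {
    tp[startsWith(tp, "?")]
  })))
  for (f in pattern$filters) {
    if (!f$var %in% pattern_vars) {
      stop("filter references unbound variable '?", f$var, "'", call. = FALSE)
    }
    if (!f$var %in% names(bindings)) next  # join already empty
    v <- bindings[[f$var]]
    keep <- switch(f$op,
      "in" = v %in% f$value,
      "==" = v == as.character(f$value),
      "!=" = v != as.character(f$value),
      {
        num <- suppressWarnings(as.numeric(v))
        ok <- !is.na(num) & do.call(f$op, list(num, as.numeric(f$value)))
        ok
      })
    bindings <- bindings[keep, , drop = FALSE]
  }
  n_sol <- nrow(bindings)
  bindings$.k <- NULL
  if (ncol(bindings) == 0L) {
    # ask-style pattern (no variables): one empty binding when satisfied
    return(data.frame(row.names = seq_len(min(n_sol, 1L))))
  }
  bindings <- unique(bindings)
  rownames(bindings) <- NULL
  bindings
}

#' @rdname graph_pattern
#' @return `kb_ask()` returns `TRUE` when the pattern has at least one
#'   solution.
#' @export
kb_ask <- function(kb, pattern) {
  nrow(kb_match(kb, pattern)) > 0L
}
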