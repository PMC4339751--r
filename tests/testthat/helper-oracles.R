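# Independent reference implementations used to cross-check the package's
# optimized code paths. These deliberately share no code with the package
# internals: the join oracle enumerates every combination of quads, the
# proposition oracle is a plain recursive fold, the co-occurrence oracle a
# double loop.

# Brute-force nested-loop join over the quad multiset.
oracle_match <- function(kb, pattern) {
  qd <- kb_quads(kb, pattern$graph)
  k <- length(pattern$triples)
  vars <- unique(unlist(lapply(pattern$triples, function(tp) {
    sub("^\\?", "", tp[startsWith(tp, "?")])
  })))
  empty <- as.data.frame(setNames(rep(list(character()), length(vars)), vars),
                         stringsAsFactors = FALSE)
  if (nrow(qd) == 0L) return(empty)
  idx <- do.call(expand.grid, rep(list(seq_len(nrow(qd))), k))
  sols <- list()
  for (r in seq_len(nrow(idx))) {
    env <- list()
    ok <- TRUE
    for (j in seq_len(k)) {
      row <- qd[idx[r, j], ]
      vals <- c(row$s, row$p, row$o)
      tp <- pattern$triples[[j]]
      for (pos in 1:3) {
        t <- tp[pos]
        if (startsWith(t, "?")) {
          v <- sub("^\\?", "", t)
          if (!is.null(env[[v]]) && env[[v]] != vals[pos]) { ok <- FALSE; break }
          env[[v]] <- vals[pos]
        } else if (t != vals[pos]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) sols[[length(sols) + 1L]] <- env
  }
  if (length(sols) == 0L) return(empty)
  out <- do.call(rbind, lapply(sols, function(e) {
    as.data.frame(e[vars], stringsAsFactors = FALSE)
  }))
  for (f in pattern$filters) {
    v <- out[[f$var]]
    keep <- switch(f$op,
      "in" = v %in% f$value,
      "==" = v == as.character(f$value),
      "!=" = v != as.character(f$value),
      { num <- suppressWarnings(as.numeric(v))
        !is.na(num) & do.call(f$op, list(num, as.numeric(f$value))) })
    out <- out[keep, , drop = FALSE]
  }
  unique(out)
}

# Canonicalize a bindings frame for set comparison.
canon_bindings <- function(df) {
  df <- df[, sort(names(df)), drop = FALSE]
  df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_bindings <- function(a, b) {
  expect_equal(canon_bindings(a), canon_bindings(b))
}

# Plain recursive fold computing a hypothesis score from per-gene event
# scores, independent of the propagation engine.
oracle_tree_score <- function(node, event_score_of) {
  if (inherits(node, "ho_event")) return(event_score_of(node$agent))
  vals <- vapply(node$members, oracle_tree_score, numeric(1),
                 event_score_of = event_score_of)
  switch(node$operator,
         AND = sum(vals) / length(vals),
         OR = max(vals),
         XOR = vals[[1L]])
}

# Double loop over entity annotation lists.
oracle_cooccurrence <- function(entity_terms) {
  counts <- list()
  for (terms in entity_terms) {
    terms <- sort(unique(terms))
    if (length(terms) < 2L) next
    for (i in seq_len(length(terms) - 1L)) {
      for (j in seq(i + 1L, length(terms))) {
        key <- paste(terms[i], terms[j])
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(counts) == 0L) {
    return(data.frame(term_a = character(), term_b = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(counts), " ", fixed = TRUE)
  out <- data.frame(term_a = vapply(parts, `[`, "", 1L),
                    term_b = vapply(parts, `[`, "", 2L),
                    count = as.integer(unlist(counts)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$term_a, out$term_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small random graph with a deliberately tiny vocabulary so that join
# patterns have many accidental matches.
random_dense_graph <- function(n_quads, graph = "test", seed = 1) {
  set.seed(seed)
  subjects <- paste0("ex:s", 1:5)
  preds <- paste0("exv:p", 1:3)
  objects <- c(paste0("ex:s", 1:5), paste0("ex:o", 1:3))
  quads(graph,
        sample(subjects, n_quads, replace = TRUE),
        sample(preds, n_quads, replace = TRUE),
        sample(objects, n_quads, replace = TRUE))
}

# Random proposition tree over a pool of genes.
random_tree <- function(genes, depth = 2) {
  make <- function(d) {
    if (d == 0L || runif(1) < 0.4) {
      return(event("go:0007568", sample(genes, 1)))
    }
    op <- sample(c("AND", "OR", "XOR"), 1)
    n <- if (op == "XOR") 1L else sample(2:3, 1)
    proposition(op, lapply(seq_len(n), function(i) make(d - 1L)))
  }
  root <- make(depth)
  if (inherits(root, "ho_event")) root <- proposition("XOR", list(root))
  hypothesis("hypothesis:random", root)
}

# One gene per evaluation-function id, each satisfying exactly that check.
single_def_cohort <- function(seed = 42) {
  profiles <- lapply(1:9, function(k) synthetic_profile(k))
  generate_kb(generator_spec(n_genes = 0, explicit_profiles = profiles,
                             seed = seed))
}
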