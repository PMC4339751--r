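#' Bottom-up score propagation and provenance
#'
#' System rules turn event scores into an overall hypothesis score: event
#' scores are computed first, then proposition scores, then the hypothesis
#' score. An `AND` proposition scores the arithmetic mean of its members, an
#' `OR` the maximum, and an `XOR` (single member) passes the member score
#' through. Every evaluation carries a provenance record — evaluation type,
#' creator, creation time, the input hypothesis, the rule identifiers used,
#' and one node per evidence function with its 0/1 contribution and the
#' retrieval functions it called — and the emitted provenance graph is
#' lossless: re-loading it reconstructs all scores exactly.
#'
#' @name propagation
NULL

RULE_IDS <- c(aging = "rules:aging_event_rule-v1",
              system = "rules:score_propagation_rule-v1")

#' @describeIn propagation Combine member scores under a proposition
#'   operator (`AND` mean, `OR` max, `XOR` passthrough).
#' @param operator `"AND"`, `"OR"` or `"XOR"`.
#' @param member_scores Numeric member scores.
#' @export
score_proposition <- function(operator, member_scores) {
  operator <- match.arg(operator, c("AND", "OR", "XOR"))
  n <- length(member_scores)
  if (operator == "XOR" && n != 1L) {
    stop("XOR propositions score exactly one member", call. = FALSE)
  }
  if (operator %in% c("AND", "OR") && n < 2L) {
    stop(operator, " propositions need at least two member scores",
         call. = FALSE)
  }
  switch(operator,
         AND = mean(member_scores),
         OR = max(member_scores),
         XOR = member_scores[[1L]])
}

#' @describeIn propagation Evaluate a hypothesis against the knowledge base.
#'   Every event must carry a registered event type (only the aging process,
#'   `go:0007568`, has a rule in this package); an unregistered type is an
#'   error naming the GO term. The result is deterministic given
#'   `(kb, cfg, h)` apart from the creation timestamp, which `fixed_clock`
#'   pins for byte-stable output.
#' @param kb A knowledge base.
#' @param cfg An evaluation config.
#' @param h A hypothesis.
#' @param fixed_clock Optional timestamp string recorded as creation time in
#'   place of the current time.
#' @export
evaluate_hypothesis <- function(kb, cfg, h, fixed_clock = NULL) {
  stopifnot(inherits(h, "ho_hypothesis"))
  events <- list()
  node_scores <- numeric()
  walk <- function(x, path) {
    if (inherits(x, "ho_event")) {
      if (x$event_type != AGING_EVENT_TYPE) {
        stop("unsupported event type: no domain rule registered for ",
             x$event_type, call. = FALSE)
      }
      es <- score_event(evaluate_gene_defs(kb, cfg, x$agent))
      events[[path]] <<- list(gene = x$agent, score = es)
      node_scores[[path]] <<- es$normalized
      es$normalized
    } else {
      member_scores <- vapply(seq_along(x$members), function(k) {
        walk(x$members[[k]], paste0(path, ".", k))
      }, numeric(1))
      s <- score_proposition(x$operator, member_scores)
      node_scores[[path]] <<- s
      s
    }
  }
  overall <- walk(h$root, "root")
  structure(list(hypothesis = h$id,
                 overall_score = overall,
                 display = score_display(overall),
                 node_scores = node_scores,
                 events = events,
                 rules = RULE_IDS,
                 creator = paste0("ageval ",
                                  as.character(utils::packageVersion("ageval"))),
                 created = if (is.null(fixed_clock))
                   format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
                 else fixed_clock),
            class = "hypothesis_evaluation")
}

#' @export
print.hypothesis_evaluation <- function(x, ...) {
  cat("<evaluation of ", x$hypothesis, ">\n", sep = "")
  cat("  overall score: ", format(x$display, nsmall = 2), "\n", sep = "")
  for (p in names(x$events)) {
    ev <- x$events[[p]]
    sat <- vapply(ev$score$def_results, function(r) r$satisfied, logical(1))
    cat("  ", ev$gene, ": ", ev$score$raw, "/9 satisfied {",
        paste(which(sat), collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

eval_node_id <- function(ev) {
  mint("evaluation", paste0(id_local(ev$hypothesis), "-eval"))
}

#' @describeIn propagation Emit an evaluation's provenance as quads. The
#'   graph holds the typed evaluation node with creator/creation time, a link
#'   to the hypothesis, the rule identifiers, per-node scores, and one
#'   contribution node per evidence function with its 0/1 value and the
#'   retrieval functions called.
#' @param ev A hypothesis evaluation.
#' @param graph Graph name for the provenance quads.
#' @export
emit_provenance <- function(ev, graph = "provenance") {
  stopifnot(inherits(ev, "hypothesis_evaluation"))
  en <- eval_node_id(ev)
  acc <- list(
    quads(graph, en, PV("type"), "hypothesis_evaluation", literal = TRUE),
    quads(graph, en, PV("creator"), ev$creator, literal = TRUE),
    quads(graph, en, PV("created"), ev$created, literal = TRUE),
    quads(graph, en, PV("hypothesis"), ev$hypothesis),
    quads(graph, en, PV("rule_used"), unname(RULE_IDS)),
    quads(graph, en, PV("overall_score"), ev$overall_score,
          literal = TRUE, datatype = "decimal")
  )
  for (path in names(ev$node_scores)) {
    nn <- mint("evaluation", paste0(id_local(ev$hypothesis), "-", path))
    acc[[length(acc) + 1L]] <-
      rbind(quads(graph, en, PV("node_score"), nn),
            quads(graph, nn, PV("node_path"), path, literal = TRUE),
            quads(graph, nn, PV("score"), ev$node_scores[[path]],
                  literal = TRUE, datatype = "decimal"))
  }
  for (path in names(ev$events)) {
    e <- ev$events[[path]]
    for (r in e$score$def_results) {
      dn <- mint("evaluation",
                 paste0(id_local(ev$hypothesis), "-", path, "-def", r$def_id))
      acc[[length(acc) + 1L]] <-
        rbind(quads(graph, en, PV("def_result"), dn),
              quads(graph, dn, PV("event_path"), path, literal = TRUE),
              quads(graph, dn, PV("gene"), e$gene),
              quads(graph, dn, PV("def_id"), r$def_id,
                    literal = TRUE, datatype = "integer"),
              quads(graph, dn, PV("contribution"), r$score_contribution,
                    literal = TRUE, datatype = "integer"),
              quads(graph, dn, PV("drf_called"), r$drfs_called,
                    literal = TRUE))
    }
  }
  do.call(rbind, acc)
}

#' @describeIn propagation Reconstruct scores from a provenance quad graph.
#'   Returns a data frame with one row per (evaluation, event) pair: columns
#'   `evaluation`, `hypothesis`, `gene`, `def1`..`def9`, `raw`, `normalized`,
#'   `overall`.
#' @param quads A quad data frame as produced by [emit_provenance()].
#' @export
parse_provenance <- function(quads) {
  q <- quads
  evals <- unique(q$s[q$p == PV("type") & q$o == "hypothesis_evaluation"])
  rows <- list()
  for (en in evals) {
    hyp <- q$o[q$s == en & q$p == PV("hypothesis")]
    overall <- as.numeric(q$o[q$s == en & q$p == PV("overall_score")])
    dns <- q$o[q$s == en & q$p == PV("def_result")]
    if (length(dns) == 0L) next
    info <- data.frame(
      dn = dns,
      path = vapply(dns, function(d) q$o[q$s == d & q$p == PV("event_path")][1L],
                    character(1)),
      gene = vapply(dns, function(d) q$o[q$s == d & q$p == PV("gene")][1L],
                    character(1)),
      def_id = vapply(dns, function(d)
        as.integer(q$o[q$s == d & q$p == PV("def_id")][1L]), integer(1)),
      value = vapply(dns, function(d)
        as.integer(q$o[q$s == d & q$p == PV("contribution")][1L]), integer(1)),
      stringsAsFactors = FALSE)
    for (path in unique(info$path)) {
      sub <- info[info$path == path, , drop = FALSE]
      mask <- integer(9)
      mask[sub$def_id] <- sub$value
      row <- data.frame(evaluation = en, hypothesis = hyp,
                        gene = sub$gene[1L], stringsAsFactors = FALSE)
      for (k in 1:9) row[[paste0("def", k)]] <- mask[k]
      row$raw <- sum(mask)
      row$normalized <- sum(mask) / 9
      row$overall <- overall
      rows[[paste(en, path)]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Write a flat per-gene evaluation table
#'
#' Tab-separated output (gene, def1..def9, raw, normalized) for spreadsheet
#' use.
#'
#' @param evals A list of hypothesis evaluations.
#' @param path Output path.
#' @export
write_eval_tsv <- function(evals, path) {
  tab <- evaluation_table(evals)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
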