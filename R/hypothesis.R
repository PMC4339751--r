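#' Hypotheses, propositions and events
#'
#' A hypothesis is a finite tree: typed events (a biological process with an
#' agent gene and optional target participants) combined by propositions
#' whose logical operator is `AND`, `OR` or `XOR`. `XOR` propositions hold
#' exactly one member (the single-event case), `AND`/`OR` hold two or more.
#' The aging use-case builds single-event hypotheses — "gene G is the agent
#' of an aging process (go:0007568)" — wrapped in an `XOR` proposition so
#' every hypothesis presents a uniform tree to the scoring engine.
#'
#' @param event_type GO term identifier typing the process (for the aging
#'   rule, `go:0007568`).
#' @param agent Gene identifier acting as agent.
#' @param targets Optional additional participant identifiers.
#' @return `event()` returns an object of class `ho_event`;
#'   `proposition()` of class `ho_proposition`; `hypothesis()` of class
#'   `ho_hypothesis`.
#' @examples
#' h <- make_gene_aging_hypothesis("wormbase:WBGene00000898")
#' h$root$operator
#' @export
event <- function(event_type, agent, targets = character()) {
  if (!nzchar(event_type) || !nzchar(agent)) {
    stop("an event needs a non-empty event_type and agent", call. = FALSE)
  }
  structure(list(event_type = event_type, agent = agent, targets = targets),
            class = "ho_event")
}

#' @rdname event
#' @param operator `"AND"`, `"OR"` or `"XOR"`.
#' @param members List of events and/or nested propositions.
#' @export
proposition <- function(operator, members) {
  operator <- match.arg(operator, c("AND", "OR", "XOR"))
  if (operator == "XOR" && length(members) != 1L) {
    stop("an XOR proposition holds exactly one member", call. = FALSE)
  }
  if (operator %in% c("AND", "OR") && length(members) < 2L) {
    stop(operator, " propositions need at least two members", call. = FALSE)
  }
  ok <- vapply(members, function(m)
    inherits(m, "ho_event") || inherits(m, "ho_proposition"), logical(1))
  if (!all(ok)) stop("members must be events or propositions", call. = FALSE)
  structure(list(operator = operator, members = members),
            class = "ho_proposition")
}

#' @rdname event
#' @param id Hypothesis identifier.
#' @param root Root proposition (a bare event is wrapped in an XOR
#'   proposition).
#' @export
hypothesis <- function(id, root) {
  if (inherits(root, "ho_event")) root <- proposition("XOR", list(root))
  stopifnot(inherits(root, "ho_proposition"))
  structure(list(id = id, root = root), class = "ho_hypothesis")
}

#' @rdname event
#' @param gene A gene identifier; hypotheses for batch runs get identifiers
#'   minted deterministically from it, so re-runs are reproducible.
#' @export
make_gene_aging_hypothesis <- function(gene) {
  if (!is_identifier(gene)) stop("gene must be a namespace:local identifier",
                                 call. = FALSE)
  if (id_namespace(gene) != "wormbase") {
    warning("gene '", gene, "' is not in the wormbase namespace; ",
            "the aging rule set was designed for C. elegans genes",
            call. = FALSE)
  }
  hypothesis(mint("hypothesis", paste0("aging-", id_local(gene))),
             event(AGING_EVENT_TYPE, gene))
}

# --- serialization ----------------------------------------------------------

#' Read and write hypotheses as quads
#'
#' Hypotheses round-trip through a small fixed vocabulary
#' (`hypothesis_vocabulary:` type / root / operator / member / member_index /
#' event_type / agent / target). `parse_hypothesis(serialize_hypothesis(h))`
#' is structurally equal to `h` up to node renaming.
#'
#' @param h A hypothesis.
#' @param graph Graph name the quads are written under.
#' @return `serialize_hypothesis()` returns a quad data frame;
#'   `parse_hypothesis()` a hypothesis.
#' @export
serialize_hypothesis <- function(h, graph = "hypotheses") {
  stopifnot(inherits(h, "ho_hypothesis"))
  counter <- new.env(); counter$n <- 0L
  acc <- list()
  add <- function(s, p, o, literal = FALSE, datatype = NULL) {
    acc[[length(acc) + 1L]] <<- quads(graph, s, p, o, literal, datatype)
  }
  node_for <- function() {
    counter$n <- counter$n + 1L
    mint("hypothesis", paste0(id_local(h$id), "-n", counter$n))
  }
  walk <- function(x) {
    node <- node_for()
    if (inherits(x, "ho_event")) {
      add(node, HV("type"), "event", literal = TRUE)
      add(node, HV("event_type"), x$event_type)
      add(node, HV("agent"), x$agent)
      for (t in x$targets) add(node, HV("target"), t)
    } else {
      add(node, HV("type"), "proposition", literal = TRUE)
      add(node, HV("operator"), x$operator, literal = TRUE)
      for (k in seq_along(x$members)) {
        child <- walk(x$members[[k]])
        add(node, HV("member"), child)
        add(child, HV("member_index"), k, literal = TRUE,
            datatype = "integer")
      }
    }
    node
  }
  add(h$id, HV("type"), "hypothesis", literal = TRUE)
  root <- walk(h$root)
  add(h$id, HV("root"), root)
  do.call(rbind, acc)
}

#' @rdname serialize_hypothesis
#' @param quads A quad data frame containing exactly one hypothesis node.
#' @export
parse_hypothesis <- function(quads) {
  q <- quads
  typed <- q[q$p == HV("type"), , drop = FALSE]
  roots <- unique(typed$s[typed$o == "hypothesis"])
  if (length(roots) == 0L) {
    stop("validation error: graph contains no hypothesis node", call. = FALSE)
  }
  if (length(roots) > 1L) {
    stop("ambiguity error: graph contains ", length(roots),
         " hypothesis nodes", call. = FALSE)
  }
  hyp_id <- roots
  root_node <- q$o[q$s == hyp_id & q$p == HV("root")]
  if (length(root_node) != 1L) {
    stop("validation error: hypothesis ", hyp_id,
         " must have exactly one root proposition", call. = FALSE)
  }
  node_type <- function(node) {
    t <- typed$o[typed$s == node]
    if (length(t) != 1L) stop("validation error: node ", node,
                              " has no single type", call. = FALSE)
    t
  }
  build <- function(node) {
    if (node_type(node) == "event") {
      et <- q$o[q$s == node & q$p == HV("event_type")]
      ag <- q$o[q$s == node & q$p == HV("agent")]
      if (length(et) != 1L || length(ag) != 1L) {
        stop("validation error: event node ", node,
             " is missing its event type or agent", call. = FALSE)
      }
      event(et, ag, targets = sort(q$o[q$s == node & q$p == HV("target")]))
    } else {
      op <- q$o[q$s == node & q$p == HV("operator")]
      kids <- q$o[q$s == node & q$p == HV("member")]
      idx <- vapply(kids, function(k) {
        v <- q$o[q$s == k & q$p == HV("member_index")]
        if (length(v) == 1L) as.integer(v) else NA_integer_
      }, integer(1))
      kids <- kids[order(idx)]
      proposition(op, lapply(kids, build))
    }
  }
  hypothesis(hyp_id, build(root_node))
}

#' Structural equality of hypotheses up to node renaming
#'
#' @param a,b Hypotheses.
#' @export
hypotheses_equal <- function(a, b) {
  canon <- function(x) {
    if (inherits(x, "ho_event")) {
      list(type = "event", event_type = x$event_type, agent = x$agent,
           targets = sort(x$targets))
    } else {
      list(type = "proposition", operator = x$operator,
           members = lapply(x$members, canon))
    }
  }
  identical(canon(a$root), canon(b$root))
}
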