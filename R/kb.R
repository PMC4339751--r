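#' Named-graph quad store
#'
#' A `kb` object holds RDF-style statements as quads
#' (subject, predicate, object, graph). Subjects and predicates are compact
#' Bio2RDF-convention identifiers ([mint()]); objects are either identifiers
#' or typed literals (string, integer or decimal). The graph name partitions
#' the store into the seven evidence-source roles (`wormbase`, `genage`,
#' `gendr`, `ppi`, `goa`, `expression`, `go_cooccurrence`) plus any number of
#' hypothesis or provenance graphs. The same identifier may appear in many
#' graphs; that shared naming is the data-integration mechanism every
#' retrieval function relies on.
#'
#' Internally the store is a single data frame with columns `graph`, `s`, `p`,
#' `o`, `ot` (object type: `"iri"` or `"literal"`) and `dt` (literal datatype:
#' `"string"`, `"integer"`, `"decimal"`, or `NA` for IRIs). Duplicate quads
#' are kept (the store is a multiset), matching standard quad-store
#' semantics under serialization round-trips.
#'
#' @return `kb_new()` returns an empty knowledge base of class `"kb"`.
#' @examples
#' kb <- kb_new()
#' kb <- kb_add(kb, quads("wormbase", "wormbase:WBGene00000898",
#'                        "wormbase_vocabulary:approved_gene_name",
#'                        "daf-2", literal = TRUE))
#' kb_size(kb)
#' @export
kb_new <- function() {
  structure(list(quads = empty_quads()), class = "kb")
}

empty_quads <- function() {
  data.frame(graph = character(), s = character(), p = character(),
             o = character(), ot = character(), dt = character(),
             stringsAsFactors = FALSE)
}

#' Build a block of quads
#'
#' Vectorized constructor for quad data frames, recycling arguments the usual
#' way. Literal datatypes are inferred from the R type of `o` (integer ->
#' integer, double -> decimal, otherwise string) unless `datatype` is given.
#'
#' @param graph Graph name the quads belong to.
#' @param s,p Subject and predicate identifiers.
#' @param o Objects: identifiers (default) or literal values.
#' @param literal Logical; are the objects literals?
#' @param datatype Optional literal datatype override
#'   (`"string"`, `"integer"`, `"decimal"`).
#' @return A quad data frame suitable for [kb_add()].
#' @export
quads <- function(graph, s, p, o, literal = FALSE, datatype = NULL) {
  n <- max(length(graph), length(s), length(p), length(o))
  if (n == 0L) return(empty_quads())
  literal <- rep_len(literal, n)
  if (is.null(datatype)) {
    dt <- if (is.integer(o)) "integer"
          else if (is.double(o)) "decimal"
          else "string"
    datatype <- rep_len(dt, n)
  } else {
    datatype <- rep_len(datatype, n)
  }
  o_chr <- as.character(o)
  data.frame(graph = rep_len(as.character(graph), n),
             s = rep_len(as.character(s), n),
             p = rep_len(as.character(p), n),
             o = o_chr,
             ot = ifelse(literal, "literal", "iri"),
             dt = ifelse(literal, datatype, NA_character_),
             stringsAsFactors = FALSE)
}

#' @rdname kb_new
#' @param kb A knowledge base.
#' @param quads A quad data frame from [quads()] (or several rbound together).
#' @export
kb_add <- function(kb, quads) {
  stopifnot(inherits(kb, "kb"))
  if (nrow(quads) == 0L) return(kb)
  bad <- quads$ot == "iri" & !is_identifier(quads$o) & !grepl("^https?://", quads$o)
  if (any(is.na(quads$s)) || any(is.na(quads$p))) {
    stop("quad subjects and predicates must be identifiers, not NA", call. = FALSE)
  }
  if (any(bad)) {
    stop("IRI objects must be identifiers or full URIs: ",
         paste(utils::head(quads$o[bad], 3), collapse = ", "), call. = FALSE)
  }
  kb$quads <- rbind(kb$quads, quads[, names(empty_quads())])
  kb
}

#' @rdname kb_new
#' @param graph Optional graph name; `NULL` means the whole store.
#' @export
kb_quads <- function(kb, graph = NULL) {
  q <- kb$quads
  if (!is.null(graph)) q <- q[q$graph %in% graph, , drop = FALSE]
  q
}

#' @rdname kb_new
#' @export
kb_size <- function(kb, graph = NULL) {
  nrow(kb_quads(kb, graph))
}

#' @rdname kb_new
#' @export
kb_graphs <- function(kb) {
  sort(unique(kb$quads$graph))
}

#' @export
print.kb <- function(x, ...) {
  gs <- table(x$quads$graph)
  cat("<knowledge base: ", nrow(x$quads), " quads in ", length(gs),
      " graphs>\n", sep = "")
  for (g in names(sort(gs, decreasing = TRUE))) {
    cat("  ", g, ": ", gs[[g]], " quads\n", sep = "")
  }
  invisible(x)
}

# Canonical one-line rendering of each quad, used for multiset comparison
# in round-trip checks. Literal decimals compare by numeric value so that
# "0.050" and "0.05" are one quad.
quad_keys <- function(quads) {
  o <- quads$o
  num <- !is.na(quads$dt) & quads$dt %in% c("integer", "decimal")
  o[num] <- formatC(as.numeric(o[num]), format = "g", digits = 15)
  paste(quads$graph, quads$s, quads$p, quads$ot, quads$dt, o, sep = "\r")
}

#' Compare two quad sets as multisets
#'
#' @param a,b Quad data frames.
#' @return `TRUE` when the two hold exactly the same quads with the same
#'   multiplicities.
#' @export
quads_equal <- function(a, b) {
  identical(sort(quad_keys(a)), sort(quad_keys(b)))
}
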