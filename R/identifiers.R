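#' Bio2RDF-convention identifiers
#'
#' Entities across all knowledge-base graphs are named with compact
#' `namespace:local_id` identifiers (CURIEs) that expand deterministically to
#' `http://bio2rdf.org/namespace:local_id`. Using one identifier per entity in
#' every graph is what makes cross-graph joins possible: the same gene URI
#' appears in the gene-annotation graph, the dietary-restriction graph, the
#' expression graph, and so on.
#'
#' @param namespace Short dataset or vocabulary namespace, e.g. `"wormbase"`,
#'   `"ncbigene"`, `"go"`, `"psi-mi"`, `"wormbase_vocabulary"`.
#' @param local_id Local identifier within the namespace.
#' @return `mint()` returns the compact identifier string
#'   `"namespace:local_id"`.
#' @examples
#' mint("ncbigene", "181370")
#' expand_uri("wormbase:WBGene00000898")
#' contract_uri("http://bio2rdf.org/go:0007568")
#' @export
mint <- function(namespace, local_id) {
  if (any(!nzchar(namespace))) {
    stop("identifier namespace must be non-empty", call. = FALSE)
  }
  if (any(grepl(":", namespace, fixed = TRUE))) {
    stop("identifier namespace must not contain ':'", call. = FALSE)
  }
  paste0(namespace, ":", local_id)
}

BIO2RDF_BASE <- "http://bio2rdf.org/"

#' @rdname mint
#' @param id A compact identifier, as returned by [mint()].
#' @export
expand_uri <- function(id) {
  if (any(!is_identifier(id))) {
    bad <- id[!is_identifier(id)]
    stop("not a namespace:local identifier: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste0(BIO2RDF_BASE, id)
}

#' @rdname mint
#' @param uri A full `http://bio2rdf.org/...` URI string.
#' @export
contract_uri <- function(uri) {
  ok <- startsWith(uri, BIO2RDF_BASE)
  id <- substr(uri, nchar(BIO2RDF_BASE) + 1L, nchar(uri))
  ok <- ok & is_identifier(id)
  if (any(!ok)) {
    stop("URI does not follow the http://bio2rdf.org/namespace:id convention: ",
         paste(uri[!ok], collapse = ", "), call. = FALSE)
  }
  id
}

#' @rdname mint
#' @param x Character vector to test.
#' @export
is_identifier <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9_.-]*:\\S*$", x)
}

id_namespace <- function(id) sub(":.*$", "", id)

id_local <- function(id) sub("^[^:]*:", "", id)
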