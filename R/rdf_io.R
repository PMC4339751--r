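#' Turtle and N-Quads readers and writers
#'
#' The knowledge base reads and writes the two standard serializations the
#' run configs use: Turtle (`.ttl`, one graph per file) and N-Quads (`.nq`,
#' whole store, graph name carried per statement). The reader covers the
#' Turtle subset these knowledge bases use plus the usual conveniences of
#' externally produced files: `@prefix`/`@base` directives, `a`, predicate
#' lists (`;`), object lists (`,`), comments, quoted strings with escapes and
#' `^^` datatypes or language tags, bare numeric literals, and blank nodes
#' (skolemized into the `bnode` namespace). Serialize-then-reload returns an
#' identical quad multiset.
#'
#' @name rdf_io
NULL

XSD_BASE <- "http://www.w3.org/2001/XMLSchema#"

TOKEN_RE <- paste0(
  "@prefix|@base",
  "|<[^>]*>",
  "|\"(?:\\\\.|[^\"\\\\\n])*\"",
  "|\\^\\^",
  "|@[A-Za-z][A-Za-z0-9-]*",
  "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",
  "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.%#/-]*",
  "|[A-Za-z][A-Za-z0-9_.-]*(?=[\\s;,.])",
  "|[+-]?(?:[0-9]+\\.[0-9]*|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?",
  "|\\.(?=\\s|$)|[;,]",
  "|#[^\n]*"
)

tokenize_rdf <- function(text) {
  m <- gregexpr(TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(),
                      stringsAsFactors = FALSE))
  }
  toks <- regmatches(text, list(m))[[1]]
  starts <- as.integer(m)
  keep <- !startsWith(toks, "#")
  toks <- toks[keep]
  starts <- starts[keep]
  # a prefixed name can swallow the statement-terminating dot when written
  # without a preceding space; split it back out
  swallowed <- grepl("^[A-Za-z].*:.*[^.]\\.$", toks)
  if (any(swallowed)) {
    out_t <- character(0); out_s <- integer(0)
    for (i in seq_along(toks)) {
      if (swallowed[i]) {
        out_t <- c(out_t, sub("\\.$", "", toks[i]), ".")
        out_s <- c(out_s, starts[i], starts[i] + nchar(toks[i]) - 1L)
      } else {
        out_t <- c(out_t, toks[i]); out_s <- c(out_s, starts[i])
      }
    }
    toks <- out_t; starts <- out_s
  }
  data.frame(text = toks, start = starts, stringsAsFactors = FALSE)
}

line_of <- function(text, offset) {
  1L + lengths(regmatches(substr(text, 1L, offset),
                          gregexpr("\n", substr(text, 1L, offset), fixed = TRUE)))
}

unescape_literal <- function(s) {
  if (!grepl("\\", s, fixed = TRUE)) return(s)
  parts <- regmatches(s, gregexpr("\\\\u[0-9a-fA-F]{4}|\\\\.|[^\\\\]+", s,
                                  perl = TRUE))[[1]]
  mapped <- vapply(parts, function(p) {
    if (startsWith(p, "\\")) {
      code <- substr(p, 2L, 2L)
      switch(code,
             "n" = "\n", "t" = "\t", "r" = "\r",
             "\"" = "\"", "\\" = "\\",
             "u" = intToUtf8(strtoi(substr(p, 3L, 6L), 16L)),
             substr(p, 2L, nchar(p)))
    } else p
  }, character(1))
  paste(mapped, collapse = "")
}

escape_literal <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}

# Resolve a full URI to the internal compact form where it follows the
# Bio2RDF convention; otherwise keep the full URI string.
uri_to_term <- function(uri) {
  if (startsWith(uri, BIO2RDF_BASE)) {
    id <- substr(uri, nchar(BIO2RDF_BASE) + 1L, nchar(uri))
    if (is_identifier(id)) return(id)
  }
  uri
}

xsd_datatype_class <- function(dt_uri) {
  local <- sub("^.*#", "", dt_uri)
  if (local %in% c("integer", "int", "long", "short", "nonNegativeInteger",
                   "positiveInteger")) "integer"
  else if (local %in% c("decimal", "double", "float")) "decimal"
  else "string"
}

# --- Turtle parsing ---------------------------------------------------------

parse_turtle_text <- function(text, graph_name, source = "<text>") {
  toks <- tokenize_rdf(text)
  n <- nrow(toks)
  i <- 1L
  prefixes <- list()
  acc <- vector("list", 256L); nacc <- 0L

  fail <- function(msg, at = i) {
    off <- if (at <= n) toks$start[at] else nchar(text)
    stop("Turtle parse error in ", source, " near line ",
         line_of(text, off), " (byte ", off, "): ", msg, call. = FALSE)
  }
  peek <- function() if (i <= n) toks$text[i] else NA_character_
  advance <- function() { t <- peek(); i <<- i + 1L; t }
  expect <- function(what) {
    t <- advance()
    if (is.na(t) || t != what) fail(paste0("expected '", what, "'"), i - 1L)
    t
  }

  resolve_pname <- function(tok) {
    ns <- sub(":.*$", "", tok)
    local <- sub("^[^:]*:", "", tok)
    base <- prefixes[[ns]]
    if (is.null(base)) fail(paste0("undeclared prefix '", ns, ":'"), i - 1L)
    uri_to_term(paste0(base, local))
  }

  # returns list(value, ot, dt); consumes tokens
  read_term <- function(role) {
    t <- advance()
    if (is.na(t)) fail("unexpected end of input")
    if (startsWith(t, "<")) {
      return(list(v = uri_to_term(substr(t, 2L, nchar(t) - 1L)),
                  ot = "iri", dt = NA_character_))
    }
    if (startsWith(t, "\"")) {
      if (role != "object") fail("literal not allowed as subject/predicate")
      val <- unescape_literal(substr(t, 2L, nchar(t) - 1L))
      dt <- "string"
      if (!is.na(peek()) && peek() == "^^") {
        advance()
        dtok <- advance()
        dt_uri <- if (startsWith(dtok, "<")) substr(dtok, 2L, nchar(dtok) - 1L)
                  else { ns <- sub(":.*$", "", dtok)
                         base <- prefixes[[ns]]
                         if (is.null(base)) fail(paste0("undeclared prefix '", ns, ":'"))
                         paste0(base, sub("^[^:]*:", "", dtok)) }
        dt <- xsd_datatype_class(dt_uri)
      } else if (!is.na(peek()) && grepl("^@", peek()) &&
                 !peek() %in% c("@prefix", "@base")) {
        advance()  # language tag; kept as plain string
      }
      return(list(v = val, ot = "literal", dt = dt))
    }
    if (startsWith(t, "_:")) {
      return(list(v = mint("bnode", substr(t, 3L, nchar(t))),
                  ot = "iri", dt = NA_character_))
    }
    if (t == "a") {
      if (role != "predicate") fail("'a' is only a predicate")
      return(list(v = "rdf:type", ot = "iri", dt = NA_character_))
    }
    if (grepl("^[+-]?[0-9.]", t)) {
      if (role != "object") fail("numeric literal not allowed here")
      dt <- if (grepl("^[+-]?[0-9]+$", t)) "integer" else "decimal"
      return(list(v = t, ot = "literal", dt = dt))
    }
    if (grepl(":", t, fixed = TRUE)) {
      return(list(v = resolve_pname(t), ot = "iri", dt = NA_character_))
    }
    fail(paste0("unexpected token '", t, "'"), i - 1L)
  }

  emit <- function(s, p, obj) {
    nacc <<- nacc + 1L
    if (nacc > length(acc)) length(acc) <<- 2L * nacc
    acc[[nacc]] <<- data.frame(graph = graph_name, s = s, p = p,
                               o = obj$v, ot = obj$ot, dt = obj$dt,
                               stringsAsFactors = FALSE)
  }

  while (i <= n) {
    t <- peek()
    if (t == "@prefix") {
      advance()
      ns_tok <- advance()
      if (!grepl(":$", ns_tok)) fail("expected 'ns:' after @prefix", i - 1L)
      iri_tok <- advance()
      if (!startsWith(iri_tok, "<")) fail("expected IRI in @prefix", i - 1L)
      prefixes[[sub(":$", "", ns_tok)]] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      expect(".")
    } else if (t == "@base") {
      advance(); advance(); expect(".")
    } else {
      subj <- read_term("subject")
      repeat {
        pred <- read_term("predicate")
        repeat {
          obj <- read_term("object")
          emit(subj$v, pred$v, obj)
          if (!is.na(peek()) && peek() == ",") { advance() } else break
        }
        if (!is.na(peek()) && peek() == ";") {
          advance()
          # tolerate trailing ';' before '.'
          if (!is.na(peek()) && peek() == ".") break
        } else break
      }
      expect(".")
    }
  }
  if (nacc == 0L) return(empty_quads())
  do.call(rbind, acc[seq_len(nacc)])
}

# --- Turtle writing ---------------------------------------------------------

render_term <- function(v, ot, dt) {
  if (ot == "iri") {
    if (is_identifier(v) && grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", id_local(v))) {
      return(v)  # prefixed name
    }
    return(paste0("<", if (is_identifier(v)) expand_uri(v) else v, ">"))
  }
  if (dt == "integer" && grepl("^[+-]?[0-9]+$", v)) return(v)
  if (dt == "decimal") {
    if (grepl("^[+-]?[0-9]+$", v)) return(paste0(v, ".0"))
    if (grepl("^[+-]?(?:[0-9]+\\.[0-9]*|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?$", v)) {
      return(v)
    }
  }
  q <- paste0("\"", escape_literal(v), "\"")
  if (dt %in% c("integer", "decimal")) {
    paste0(q, "^^xsd:", if (dt == "integer") "integer" else "decimal")
  } else q
}

turtle_lines <- function(quads) {
  iri_vals <- c(quads$s, quads$p, quads$o[quads$ot == "iri"])
  iri_vals <- iri_vals[is_identifier(iri_vals)]
  nss <- sort(unique(id_namespace(iri_vals)))
  header <- c(paste0("@prefix ", nss, ": <", BIO2RDF_BASE, nss, ":> ."),
              paste0("@prefix xsd: <", XSD_BASE, "> ."),
              "")
  if (nrow(quads) == 0L) return(header)
  body <- vapply(seq_len(nrow(quads)), function(k) {
    paste(render_term(quads$s[k], "iri", NA),
          render_term(quads$p[k], "iri", NA),
          render_term(quads$o[k], quads$ot[k], quads$dt[k]),
          ".")
  }, character(1))
  c(header, body)
}

#' @rdname rdf_io
#' @param kb A knowledge base.
#' @param graph Graph name to serialize.
#' @param path Output (or input) file path.
#' @export
kb_write_turtle <- function(kb, graph, path) {
  writeLines(turtle_lines(kb_quads(kb, graph)), path)
  invisible(path)
}

#' Load a serialized graph into the knowledge base
#'
#' @param kb A knowledge base.
#' @param path File to read.
#' @param format `"turtle"` or `"nquads"`.
#' @param graph_name Graph the statements are loaded under (Turtle only;
#'   N-Quads files carry their own graph names).
#' @return The updated knowledge base; the number of quads added is attached
#'   as attribute `"quads_added"` and reported with a message.
#' @export
kb_load_graph <- function(kb, path, format = c("turtle", "nquads"),
                          graph_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (format == "turtle") {
    if (is.null(graph_name)) stop("graph_name is required for Turtle input",
                                  call. = FALSE)
    q <- parse_turtle_text(text, graph_name, source = path)
  } else {
    q <- parse_nquads_text(text, source = path)
  }
  kb <- kb_add(kb, q)
  message("loaded ", nrow(q), " quads from ", path)
  attr(kb, "quads_added") <- nrow(q)
  kb
}

# --- N-Quads ----------------------------------------------------------------

nquads_term <- function(v, ot, dt) {
  if (ot == "iri") {
    return(paste0("<", if (is_identifier(v)) expand_uri(v) else v, ">"))
  }
  q <- paste0("\"", escape_literal(v), "\"")
  if (dt == "integer") paste0(q, "^^<", XSD_BASE, "integer>")
  else if (dt == "decimal") paste0(q, "^^<", XSD_BASE, "decimal>")
  else q
}

#' @rdname rdf_io
#' @export
kb_write_nquads <- function(kb, path) {
  q <- kb$quads
  lines <- vapply(seq_len(nrow(q)), function(k) {
    paste(nquads_term(q$s[k], "iri", NA),
          nquads_term(q$p[k], "iri", NA),
          nquads_term(q$o[k], q$ot[k], q$dt[k]),
          paste0("<", expand_uri(mint("graph", q$graph[k])), ">"),
          ".")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

parse_nquads_text <- function(text, source = "<text>") {
  toks <- tokenize_rdf(text)
  i <- 1L; n <- nrow(toks)
  acc <- list(); nacc <- 0L
  term <- function(role) {
    t <- toks$text[i]; i <<- i + 1L
    if (startsWith(t, "<")) {
      list(v = uri_to_term(substr(t, 2L, nchar(t) - 1L)), ot = "iri",
           dt = NA_character_)
    } else if (startsWith(t, "\"")) {
      val <- unescape_literal(substr(t, 2L, nchar(t) - 1L))
      dt <- "string"
      if (i <= n && toks$text[i] == "^^") {
        i <<- i + 1L
        dtok <- toks$text[i]; i <<- i + 1L
        dt <- xsd_datatype_class(substr(dtok, 2L, nchar(dtok) - 1L))
      }
      list(v = val, ot = "literal", dt = dt)
    } else if (startsWith(t, "_:")) {
      list(v = mint("bnode", substr(t, 3L, nchar(t))), ot = "iri",
           dt = NA_character_)
    } else {
      stop("N-Quads parse error in ", source, " near line ",
           line_of(text, toks$start[i - 1L]), ": unexpected token '", t, "'",
           call. = FALSE)
    }
  }
  while (i <= n) {
    s <- term("subject"); p <- term("predicate"); o <- term("object")
    g <- term("graph")
    if (i > n || toks$text[i] != ".") {
      stop("N-Quads parse error in ", source, ": statement not terminated by '.'",
           call. = FALSE)
    }
    i <- i + 1L
    gname <- g$v
    if (is_identifier(gname) && id_namespace(gname) == "graph") {
      gname <- id_local(gname)
    }
    nacc <- nacc + 1L
    acc[[nacc]] <- data.frame(graph = gname, s = s$v, p = p$v, o = o$v,
                              ot = o$ot, dt = o$dt, stringsAsFactors = FALSE)
  }
  if (nacc == 0L) return(empty_quads()) else do.call(rbind, acc)
}

#' @rdname rdf_io
#' @export
kb_read_nquads <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  kb_add(kb_new(), parse_nquads_text(text, source = path))
}
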