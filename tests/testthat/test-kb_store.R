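# Quad store: identifier minting, standard-format I/O, pattern matching.

test_that("identifier minting expands and contracts by the shared convention", {
  expect_equal(expand_uri(mint("ncbigene", "181370")),
               "http://bio2rdf.org/ncbigene:181370")
  expect_equal(expand_uri(mint("wormbase", "WBGene00000898")),
               "http://bio2rdf.org/wormbase:WBGene00000898")
  expect_error(mint("", "x"), "non-empty")
  expect_error(contract_uri("http://example.org/other"), "convention")
  expect_error(contract_uri("http://bio2rdf.org/nocolonhere"), "convention")
})

test_that("expansion round-trips and is injective over random identifiers", {
  set.seed(1)
  ns <- sample(c("wormbase", "genage", "go", "psi-mi", "uniprot"), 50,
               replace = TRUE)
  loc <- replicate(50, paste(sample(c(LETTERS, 0:9), 8, replace = TRUE),
                             collapse = ""))
  ids <- mint(ns, loc)
  expect_equal(contract_uri(expand_uri(ids)), ids)
  # distinct (namespace, local) pairs give distinct URIs
  expect_equal(anyDuplicated(expand_uri(unique(ids))), 0L)
})

test_that("graph loading counts quads and empty input adds nothing", {
  empty <- withr::local_tempfile(fileext = ".ttl")
  writeLines(character(), empty)
  kb <- suppressMessages(kb_load_graph(kb_new(), empty, "turtle", "wormbase"))
  expect_equal(attr(kb, "quads_added"), 0L)
  expect_equal(kb_size(kb), 0L)

  three <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix wormbase: <http://bio2rdf.org/wormbase:> .",
    "@prefix wormbase_vocabulary: <http://bio2rdf.org/wormbase_vocabulary:> .",
    "wormbase:WBGene00000898 wormbase_vocabulary:approved_gene_name \"daf-2\" .",
    "wormbase:WBGene00000898 wormbase_vocabulary:phenotype wormbase:ph1 ;",
    "  wormbase_vocabulary:phenotype wormbase:ph2 ."), three)
  kb <- suppressMessages(kb_load_graph(kb_new(), three, "turtle", "wormbase"))
  expect_equal(attr(kb, "quads_added"), 3L)
  expect_setequal(kb_quads(kb)$graph, "wormbase")
})

test_that("parse failures name the offending position and bad formats error", {
  bad <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c("@prefix ex: <http://bio2rdf.org/ex:> .",
               "ex:a ex:b"), bad)  # statement never terminated
  expect_error(suppressMessages(kb_load_graph(kb_new(), bad, "turtle", "g")),
               "line")
  expect_error(kb_load_graph(kb_new(), bad, "trig", "g"), "arg")
  expect_error(suppressMessages(kb_load_graph(kb_new(), "/no/such/file.ttl",
                                              "turtle", "g")), "no such file")
})

test_that("serialize-then-reload preserves the quad multiset exactly", {
  gen <- generate_kb(generator_spec(n_genes = 15, seed = 3,
                                    satisfaction_probs = rep(0.4, 9)))
  # whole store through N-Quads
  nq <- withr::local_tempfile(fileext = ".nq")
  kb_write_nquads(gen$kb, nq)
  back <- kb_read_nquads(nq)
  expect_true(quads_equal(kb_quads(gen$kb), kb_quads(back)))
  # each named graph through Turtle
  for (g in kb_graphs(gen$kb)) {
    f <- withr::local_tempfile(fileext = ".ttl")
    kb_write_turtle(gen$kb, g, f)
    one <- suppressMessages(kb_load_graph(kb_new(), f, "turtle", g))
    expect_true(quads_equal(kb_quads(gen$kb, g), kb_quads(one)))
  }
})

test_that("escaped literals and typed numbers survive the Turtle round-trip", {
  kb <- kb_add(kb_new(), rbind(
    quads("g", "ex:a", "exv:note", "line1\nline\t2 \"quoted\" \\slash",
          literal = TRUE),
    quads("g", "ex:a", "exv:p", 0.003, literal = TRUE, datatype = "decimal"),
    quads("g", "ex:a", "exv:tiny", 1e-7, literal = TRUE, datatype = "decimal"),
    quads("g", "ex:a", "exv:whole", 2, literal = TRUE, datatype = "decimal"),
    quads("g", "ex:a", "exv:n", 42L, literal = TRUE, datatype = "integer")))
  f <- withr::local_tempfile(fileext = ".ttl")
  kb_write_turtle(kb, "g", f)
  back <- suppressMessages(kb_load_graph(kb_new(), f, "turtle", "g"))
  expect_true(quads_equal(kb_quads(kb), kb_quads(back)))
})

test_that("an independent RDF parser reads our Turtle with the same statements", {
  py <- Sys.which("python")
  kb <- plant_worked_example_sams1()
  f <- withr::local_tempfile(fileext = ".ttl")
  kb_write_turtle(kb, "ppi", f)
  script <- paste(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle')",
    "print(len(g))",
    "print(sum(1 for s,p,o in g if str(o)=='http://bio2rdf.org/psi-mi:0397'))",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2(py, c(sf, f), stdout = TRUE)
  expect_equal(as.integer(out[1]), kb_size(kb, "ppi"))
  expect_equal(as.integer(out[2]),
               sum(kb_quads(kb, "ppi")$o == "psi-mi:0397"))
})

test_that("pattern matching over empty and single-quad stores behaves", {
  pat <- graph_pattern(c("?s", "exv:p1", "?o"), graph = "test")
  expect_equal(nrow(kb_match(kb_new(), pat)), 0L)
  kb <- kb_add(kb_new(), quads("test", "ex:s1", "exv:p1", "ex:o1"))
  m <- kb_match(kb, pat)
  expect_equal(nrow(m), 1L)
  expect_equal(m$s, "ex:s1")
  expect_equal(m$o, "ex:o1")
  # graph restriction to a nonexistent graph is empty, not an error
  expect_equal(nrow(kb_match(kb, graph_pattern(c("?s", "?p", "?o"),
                                               graph = "nope"))), 0L)
})

test_that("joins equal the brute-force nested-loop oracle on dense graphs", {
  for (seed in 1:3) {
    kb <- kb_add(kb_new(), random_dense_graph(50, seed = seed))
    pats <- list(
      graph_pattern(c("?a", "exv:p1", "?b"), c("?b", "exv:p2", "?c"),
                    graph = "test"),
      graph_pattern(c("?a", "?p", "?b"), c("?b", "?p", "?c"), graph = "test"),
      graph_pattern(c("?a", "exv:p1", "?b"), c("?a", "exv:p2", "?c"),
                    c("?c", "exv:p3", "?d"), graph = "test"),
      graph_pattern(c("?a", "exv:p1", "?a"), graph = "test"))
    for (pat in pats) {
      expect_same_bindings(kb_match(kb, pat), oracle_match(kb, pat))
    }
  }
})

test_that("value filters follow typed-literal semantics and reject bad refs", {
  kb <- kb_add(kb_new(), rbind(
    quads("g", "ex:r1", "exv:p_value", 0.003, literal = TRUE,
          datatype = "decimal"),
    quads("g", "ex:r2", "exv:p_value", 0.8, literal = TRUE,
          datatype = "decimal"),
    quads("g", "ex:r3", "exv:p_value", "not-a-number", literal = TRUE)))
  pat <- graph_pattern(c("?r", "exv:p_value", "?p"), graph = "g",
                       filters = list(value_filter("p", "<", 0.05)))
  m <- kb_match(kb, pat)
  expect_equal(m$r, "ex:r1")  # non-numeric literal never passes a comparison
  expect_same_bindings(kb_match(kb, pat), oracle_match(kb, pat))
  pat_in <- graph_pattern(c("?r", "exv:p_value", "?p"), graph = "g",
                          filters = list(value_filter("r", "in",
                                                      c("ex:r2", "ex:r3"))))
  expect_setequal(kb_match(kb, pat_in)$r, c("ex:r2", "ex:r3"))
  expect_error(kb_match(kb, graph_pattern(c("?r", "exv:p_value", "?p"),
                                          graph = "g",
                                          filters = list(value_filter("zz", "<", 1)))),
               "unbound")
  expect_error(value_filter("p", "almost", 1), "arg")
})
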