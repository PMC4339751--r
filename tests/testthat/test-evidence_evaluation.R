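# The nine evidence evaluation functions and the event scorer.

test_that("the curated-lifespan check follows the increase-only rule", {
  kb <- plant_worked_example_sams1()
  cfg <- default_config()
  r <- def1_curated_lifespan(kb, cfg, sams1_gene_id())
  expect_true(r$satisfied)
  expect_equal(r$score_contribution, 1L)
  expect_false(def1_curated_lifespan(kb, cfg, "wormbase:NOBODY")$satisfied)
  # a planted "decrease" effect does not satisfy the check ...
  prof <- synthetic_profile(rep(FALSE, 9), refuting_decrease = TRUE)
  gen <- generate_kb(generator_spec(0, explicit_profiles = list(prof), seed = 2))
  expect_false(def1_curated_lifespan(gen$kb, cfg, gen$ledger$gene[1])$satisfied)
  # ... unless the config widens the rule
  wide <- default_config(genage_count_decrease = TRUE)
  expect_true(def1_curated_lifespan(gen$kb, wide, gen$ledger$gene[1])$satisfied)
})

test_that("a refuting fact yields a strictly lower score than a supporting one", {
  cfg <- default_config()
  base_mask <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE)
  with_support <- synthetic_profile(c(TRUE, base_mask[-1]))
  with_refute <- synthetic_profile(base_mask, refuting_decrease = TRUE)
  gen <- generate_kb(generator_spec(0, seed = 3,
    explicit_profiles = list(with_support, with_refute)))
  scores <- vapply(gen$ledger$gene, function(g) {
    score_event(evaluate_gene_defs(gen$kb, cfg, g))$normalized
  }, numeric(1))
  expect_lt(scores[2], scores[1])
})

test_that("the interaction-neighborhood check needs both the method and the term", {
  kb <- plant_worked_example_sams1()
  cfg <- default_config()
  # worked example: high-confidence methods but no aging-annotated partner
  expect_false(def7_ppi_aging_neighbors(kb, cfg, sams1_gene_id())$satisfied)
  expect_false(def7_ppi_aging_neighbors(kb, cfg, "wormbase:LONER")$satisfied)

  plant7 <- function(method, term, aspect) {
    kb_add(kb_new(), rbind(
      quads("wormbase", "wormbase:G7", "wormbase_vocabulary:approved_gene_name",
            "gene-7", literal = TRUE),
      quads("goa", "uniprot:GP7", "goa_vocabulary:gene_symbol", "gene-7",
            literal = TRUE),
      quads("ppi", "irefindex:j1", "irefindex_vocabulary:interactor_a",
            "uniprot:GP7"),
      quads("ppi", "irefindex:j1", "irefindex_vocabulary:interactor_b",
            "uniprot:HP7"),
      quads("ppi", "irefindex:j1", "irefindex_vocabulary:method", method),
      quads("ppi", "irefindex:j1", "irefindex_vocabulary:article_count", 1L,
            literal = TRUE, datatype = "integer"),
      quads("goa", "uniprot:HP7", "goa_vocabulary:go_annotation", "goa:ha"),
      quads("goa", "goa:ha", "goa_vocabulary:go_term", term),
      quads("goa", "goa:ha", "goa_vocabulary:aspect", aspect, literal = TRUE)))
  }
  hit <- def7_ppi_aging_neighbors(plant7("psi-mi:0397", "go:0008340", "process"),
                                  cfg, "wormbase:G7")
  expect_true(hit$satisfied)
  expect_equal(hit$supporting_facts$partner, "uniprot:HP7")
  expect_equal(hit$supporting_facts$term, "go:0008340")
  # low-confidence method: refused
  expect_false(def7_ppi_aging_neighbors(plant7("psi-mi:9999", "go:0008340",
                                               "process"),
                                        cfg, "wormbase:G7")$satisfied)
  # non-aging partner annotation: refused
  expect_false(def7_ppi_aging_neighbors(plant7("psi-mi:0397", "go:0006730",
                                               "process"),
                                        cfg, "wormbase:G7")$satisfied)
  # aging term outside the biological-process aspect: refused
  expect_false(def7_ppi_aging_neighbors(plant7("psi-mi:0397", "go:0008340",
                                               "function"),
                                        cfg, "wormbase:G7")$satisfied)
})

test_that("each check fires exactly for its own planted evidence", {
  gen <- single_def_cohort()
  cfg <- default_config()
  for (i in 1:9) {
    results <- evaluate_gene_defs(gen$kb, cfg, gen$ledger$gene[i])
    sat <- vapply(results, `[[`, logical(1), "satisfied")
    expect_equal(which(sat), i)
    expect_equal(vapply(results, `[[`, integer(1), "def_id"), 1:9)
  }
  # and a gene with no facts in any graph satisfies nothing
  none <- evaluate_gene_defs(gen$kb, cfg, "wormbase:EMPTY")
  expect_false(any(vapply(none, `[[`, logical(1), "satisfied")))
})

test_that("the sams-1 fixture shows its expected satisfaction pattern", {
  kb <- plant_worked_example_sams1()
  results <- evaluate_gene_defs(kb, default_config(), sams1_gene_id())
  sat <- vapply(results, `[[`, logical(1), "satisfied")
  expect_equal(which(sat), c(1:6, 8:9))
  expect_equal(score_event(results)$display, 0.89)
})

test_that("config thresholds steer the expression and co-occurrence checks", {
  gen <- single_def_cohort()
  g2 <- gen$ledger$gene[2]  # carries only a significant expression record
  expect_true(def2_expression(gen$kb, default_config(), g2)$satisfied)
  strict <- default_config(expression_p_threshold = 1e-8)
  expect_false(def2_expression(gen$kb, strict, g2)$satisfied)
  g9 <- gen$ledger$gene[9]  # co-occurrence planted with count 3
  expect_true(def9_go_cooccurrence(gen$kb, default_config(), g9)$satisfied)
  high <- default_config(cooccurrence_min_count = 10L)
  expect_false(def9_go_cooccurrence(gen$kb, high, g9)$satisfied)
  expect_error(default_config(expression_p_threshold = 1.2), "0, 1")
  expect_error(default_config(nonsense = 1), "unknown")
})

test_that("event scores normalize by nine and display on the k/9 grid", {
  mk <- function(mask) {
    lapply(1:9, function(k) {
      ageval:::evidence_result(k, mask[k], data.frame(), "none")
    })
  }
  grid <- c(0, 0.11, 0.22, 0.33, 0.44, 0.56, 0.67, 0.78, 0.89, 1)
  for (k in 0:9) {
    es <- score_event(mk(seq_len(9) <= k))
    expect_equal(es$raw, k)
    expect_equal(es$normalized, k / 9)
    expect_equal(es$display, grid[k + 1])
  }
  # rounding never reorders raw scores
  expect_true(all(diff(score_display((0:9) / 9)) > 0))
  # monotonicity: flipping any single verdict moves the score by exactly 1/9
  for (k in 1:9) {
    lo <- rep(FALSE, 9)
    hi <- lo; hi[k] <- TRUE
    expect_equal(score_event(mk(hi))$normalized -
                   score_event(mk(lo))$normalized, 1 / 9)
  }
})

test_that("the scorer rejects missing or duplicated function results", {
  ok <- lapply(1:9, function(k) {
    ageval:::evidence_result(k, TRUE, data.frame(), "none")
  })
  expect_error(score_event(ok[-3]), "exactly one")
  expect_error(score_event(c(ok[-3], ok[4])), "exactly one")
})
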