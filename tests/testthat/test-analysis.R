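# Batch evaluation and the downstream analytics.

test_that("batch evaluation equals gene-by-gene evaluation", {
  gen <- generate_kb(generator_spec(n_genes = 40, seed = 37,
                                    satisfaction_probs = rep(0.3, 9)))
  cfg <- default_config()
  evals <- batch_evaluate(gen$kb, cfg, gen$ledger$gene,
                          fixed_clock = "2026-01-01T00:00:00Z")
  expect_length(evals, 40L)
  for (i in c(1, 7, 40)) {
    single <- evaluate_hypothesis(gen$kb, cfg,
                                  make_gene_aging_hypothesis(gen$ledger$gene[i]),
                                  fixed_clock = "2026-01-01T00:00:00Z")
    expect_identical(evals[[i]], single)
  }
  one <- batch_evaluate(gen$kb, cfg, gen$ledger$gene[1])
  expect_length(one, 1L)
  expect_error(batch_evaluate(gen$kb, cfg, character()), "at least one")
})

test_that("the score histogram equals the ledger and sums to n", {
  gen <- generate_kb(generator_spec(n_genes = 30, seed = 41,
                                    satisfaction_probs = rep(0.4, 9)))
  evals <- batch_evaluate(gen$kb, default_config(), gen$ledger$gene)
  dist <- score_distribution(evals)
  expect_equal(sum(dist$n_genes), 30L)
  raw <- rowSums(gen$ledger[paste0("def", 1:9)])
  expected <- table(score_display(raw / 9))
  got <- setNames(dist$n_genes, format(dist$score))
  for (s in names(expected)) {
    expect_equal(unname(got[[format(as.numeric(s))]]),
                 unname(as.integer(expected[[s]])))
  }
  expect_equal(nrow(score_distribution(list())), 0L)
  # an all-zero-evidence batch lands in a single bin at 0
  zero <- generate_kb(generator_spec(0, seed = 1, explicit_profiles =
    lapply(1:5, function(i) synthetic_profile(rep(FALSE, 9)))))
  zd <- score_distribution(batch_evaluate(zero$kb, default_config(),
                                          zero$ledger$gene))
  expect_equal(zd, data.frame(score = 0, n_genes = 5L))
})

test_that("satisfaction frequencies equal the planted proportions", {
  gen <- generate_kb(generator_spec(n_genes = 50, seed = 43,
                                    satisfaction_probs = rep(0.3, 9)))
  evals <- batch_evaluate(gen$kb, default_config(), gen$ledger$gene)
  freq <- def_frequencies(evals)
  for (k in 1:9) {
    expect_equal(freq$satisfied[k], sum(gen$ledger[[paste0("def", k)]]))
  }
  expect_equal(freq$proportion, freq$satisfied / 50)
  one <- generate_kb(generator_spec(0, seed = 1,
    explicit_profiles = list(synthetic_profile(2L))))
  f1 <- def_frequencies(batch_evaluate(one$kb, default_config(),
                                       one$ledger$gene))
  expect_equal(f1$proportion, as.numeric(1:9 == 2))
})

test_that("the independence model gives a tiny chance for the candidate combination", {
  # satisfaction counts over the 48,231-gene complement
  freq <- def_frequency_table(c(317, 6406, 1, 55, 699, 876, 135, 1216, 6899),
                              48231)
  expect_equal(signif(freq$proportion[1], 2), 6.6e-3)
  expect_equal(signif(freq$proportion[7], 2), 2.8e-3)
  p <- combination_probability(freq, c(2, 7, 8, 9))
  expect_equal(signif(p, 2), 1.3e-6)
  expect_lt(expected_count(p, 48231), 1)
  # single-function combination is that function's proportion
  expect_equal(combination_probability(freq, 5), freq$proportion[5])
  # monotone non-increasing as the combination grows, bounded by the minimum
  combos <- list(2, c(2, 9), c(2, 9, 8), c(2, 9, 8, 7), c(2, 9, 8, 7, 5))
  ps <- vapply(combos, combination_probability, numeric(1), freq = freq)
  expect_true(all(diff(ps) <= 0))
  for (i in seq_along(combos)) {
    expect_lte(ps[i], min(freq$proportion[combos[[i]]]))
  }
  expect_error(combination_probability(freq, c(2, 10)), "1..9")
  # the exact-mask variant is smaller (extra (1-p) factors)
  expect_lt(combination_probability(freq, c(2, 7, 8, 9),
                                    include_unsatisfied = TRUE), p)
})

test_that("the independence product matches Monte-Carlo mask sampling", {
  freq <- def_frequency_table(c(317, 6406, 1, 55, 699, 876, 135, 1216, 6899),
                              48231)
  combo <- c(2, 9)
  p <- combination_probability(freq, combo)
  set.seed(47)
  n <- 1e5
  draws <- vapply(combo, function(k) {
    stats::rbinom(n, 1L, freq$proportion[k])
  }, integer(n))
  obs <- mean(rowSums(draws) == length(combo))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(obs - p), 3 * se)
})

test_that("candidate identification applies the no-curation filter and tiers", {
  profiles <- c(
    lapply(1:31, function(i) synthetic_profile(c(2, 7, 8, 9))),
    # decoys: curated or phenotype evidence disqualifies even high scorers
    list(synthetic_profile(c(1, 2, 3, 4, 6, 7, 8, 9)),
         synthetic_profile(c(2, 5, 7, 8, 9)),
         synthetic_profile(rep(FALSE, 9)),
         synthetic_profile(c(2, 9))))
  gen <- generate_kb(generator_spec(0, explicit_profiles = profiles, seed = 53))
  evals <- batch_evaluate(gen$kb, default_config(), gen$ledger$gene)
  cand <- identify_candidates(evals)
  top <- cand[cand$top_tier, ]
  expect_equal(nrow(top), 31L)
  expect_equal(unique(top$score), 0.44)
  expect_equal(unique(top$defs), "2,7,8,9")
  # no returned gene has curated-lifespan or phenotype contributions
  tab <- evaluation_table(evals)
  expect_true(all(tab$def1[match(cand$gene, tab$gene)] == 0))
  expect_true(all(tab$def5[match(cand$gene, tab$gene)] == 0))
  # lower tier follows, ordered by identifier within a tier
  expect_equal(cand$raw, sort(cand$raw, decreasing = TRUE))
  expect_false(any(gen$ledger$gene[32:33] %in% cand$gene))
  expect_equal(identify_candidates(evals, tiers = "top")$gene, top$gene)
})

test_that("candidate ranking equals a brute-force filter-and-sort", {
  gen <- generate_kb(generator_spec(n_genes = 60, seed = 59,
                                    satisfaction_probs = rep(0.35, 9)))
  evals <- batch_evaluate(gen$kb, default_config(), gen$ledger$gene)
  cand <- identify_candidates(evals)
  led <- gen$ledger
  keep <- !led$def1 & !led$def5 &
    rowSums(led[paste0("def", 1:9)]) > 0
  brute <- led[keep, ]
  brute$raw <- rowSums(brute[paste0("def", 1:9)])
  brute <- brute[order(-brute$raw, brute$gene), ]
  expect_equal(cand$gene, brute$gene)
  expect_equal(cand$raw, unname(brute$raw))
})

test_that("the KS comparison agrees with the reference implementation", {
  expect_equal(compare_distributions(c(0, 0.11, 0.44), c(0, 0.11, 0.44))$statistic, 0)
  expect_equal(compare_distributions(rep(0, 5), rep(1, 4))$statistic, 1)
  set.seed(61)
  for (i in 1:5) {
    a <- rnorm(80)
    b <- rnorm(120, mean = runif(1, 0, 1))
    got <- compare_distributions(a, b)
    ref <- stats::ks.test(a, b, exact = FALSE)
    expect_lt(abs(got$statistic - unname(ref$statistic)), 1e-10)
    # both sides evaluate the same asymptotic null distribution but truncate
    # its series differently; agreement far below any decision threshold
    expect_lt(abs(got$p_value - ref$p.value), 1e-4)
  }
  expect_error(compare_distributions(numeric(), 1), "non-empty")
  # rounded mode compares displayed scores
  a <- c(0.666666, 0.444444)
  b <- c(0.67, 0.44)
  expect_equal(compare_distributions(a, b, rounded = TRUE)$statistic, 0)
})

test_that("GO co-occurrence counts entities, not annotation rows", {
  mk <- function(entity, terms) {
    anns <- mint("goa", paste0("a", entity, seq_along(terms)))
    rbind(quads("goa", mint("uniprot", entity), "goa_vocabulary:go_annotation",
                anns),
          quads("goa", anns, "goa_vocabulary:go_term", terms))
  }
  kb <- kb_add(kb_new(), rbind(
    mk("E1", c("go:a", "go:b", "go:c")),
    mk("E2", c("go:a", "go:a", "go:b")),  # duplicate annotation deduplicated
    mk("E3", "go:a")))                    # single term: no pairs
  tab <- go_cooccurrence(kb)
  expect_equal(tab$count[tab$term_a == "go:a" & tab$term_b == "go:b"], 2L)
  expect_equal(sum(tab$count), choose(3, 2) + 1L)
  expect_true(all(tab$term_a < tab$term_b))
  # serialized back, the counts feed the co-occurrence lookup
  kb2 <- kb_add(kb_new(), cooccurrence_quads(tab))
  expect_equal(get_cooccurrence(kb2, "go:b", "go:a"), 2L)
})

test_that("co-occurrence equals the double-loop oracle on random graphs", {
  set.seed(67)
  for (rep in 1:3) {
    entity_terms <- lapply(1:12, function(i) {
      sample(paste0("go:t", 1:6), sample(1:5, 1), replace = TRUE)
    })
    blocks <- lapply(seq_along(entity_terms), function(i) {
      terms <- entity_terms[[i]]
      anns <- mint("goa", paste0("r", rep, "e", i, "a", seq_along(terms)))
      rbind(quads("goa", mint("uniprot", paste0("P", i)),
                  "goa_vocabulary:go_annotation", anns),
            quads("goa", anns, "goa_vocabulary:go_term", terms))
    })
    kb <- kb_add(kb_new(), do.call(rbind, blocks))
    got <- go_cooccurrence(kb)
    ref <- oracle_cooccurrence(entity_terms)
    expect_equal(got, ref)
    # invariant: total pair mass is the sum over entities of C(k, 2)
    ks <- vapply(entity_terms, function(t) length(unique(t)), integer(1))
    expect_equal(sum(got$count), sum(choose(ks, 2)))
  }
})
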