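test_that("expected pool frequencies encode the recessive selfing model", {
  expect_equal(expected_pool_frequency("mutant"), 1)
  expect_equal(expected_pool_frequency("wt"), 0)
  expect_equal(expected_pool_frequency("sibling"), 1 / 3)
  expect_error(expected_pool_frequency("father"))
})

test_that("exact binomial sibling test matches its pinned examples", {
  expect_equal(sibling_ratio_test(33, 99, 1 / 3, pool_size = Inf)$p_value, 1)
  expect_true(sibling_ratio_test(33, 99, 1 / 3, pool_size = Inf)$consistent)
  hi <- sibling_ratio_test(99, 99, 1 / 3, pool_size = Inf)
  expect_lt(hi$p_value, 1e-15)
  expect_false(hi$consistent)
  obs38 <- sibling_ratio_test(38, 100, 1 / 3, alpha = 0.05,
                              pool_size = Inf)
  expect_true(obs38$consistent)
  zero <- sibling_ratio_test(0, 0)
  expect_true(zero$low_depth)
  expect_true(is.na(zero$p_value))
  expect_error(sibling_ratio_test(10, 5), "exceed")
})

test_that("binomial p-values agree with the enumeration oracle at several depths", {
  for (d in c(1L, 7L, 23L, 50L)) {
    for (k in 0:d) {
      expect_equal(sibling_ratio_test(k, d, 1 / 3, pool_size = Inf)$p_value,
                   binom_p_oracle(k, d, 1 / 3), tolerance = 1e-12)
    }
  }
})

test_that("pool-aware null absorbs embryo-sampling overdispersion", {
  # infinite pool reduces to the plain binomial
  expect_equal(sibling_ratio_test(40, 120, 1 / 3, pool_size = Inf)$p_value,
               binom.test(40, 120, 1 / 3)$p.value)
  # a sibling pool fixed for the variant is decisively inconsistent
  expect_lt(sibling_ratio_test(100, 100, 1 / 3, pool_size = 12)$p_value,
            1e-20)
  expect_lt(sibling_ratio_test(95, 100, 1 / 3, pool_size = 12)$p_value,
            1e-20)
  # Monte-Carlo under the true generative null: the pool-aware test holds
  # its level where the binomial test, blind to pool composition, does not
  set.seed(31)
  m <- 12
  draws <- t(replicate(1500, {
    f <- mean(sample(c(0, 0.5), m, TRUE, c(1 / 3, 2 / 3)))
    d <- 80L
    c(k = rbinom(1, d, f), d = d)
  }))
  p_pool <- apply(draws, 1, function(x)
    sibling_ratio_test(x[["k"]], x[["d"]], 1 / 3, pool_size = m)$p_value)
  p_binom <- apply(draws, 1, function(x)
    sibling_ratio_test(x[["k"]], x[["d"]], 1 / 3, pool_size = Inf)$p_value)
  expect_lte(mean(p_pool < 0.05), 0.05 + 0.02)
  expect_gt(mean(p_binom < 0.05), 0.15)
})

test_that("classification reproduces the published three-pool signature", {
  cand <- classify_segregation(variant_row("v1", 100, 38, 0))
  expect_equal(cand$classification, "candidate")
  expect_equal(unname(cand$observed_frequencies),
               c(1, 0.38, 0))

  fixed <- classify_segregation(variant_row("v2", 100, 100, 100))
  expect_equal(fixed$classification, "strain_fixed")

  # sibling pool near-fixed for the variant: wrong Mendelian ratio
  bad <- classify_segregation(variant_row("v3", 100, 95, 0))
  expect_equal(bad$classification, "sibling_ratio_inconsistent")
  # same call under the plain binomial convention at alpha 0.05
  bad2 <- classify_segregation(
    variant_row("v3", 100, 95, 0),
    filter_thresholds(sibling_alpha = 0.05, sibling_pool_size = Inf))
  expect_equal(bad2$classification, "sibling_ratio_inconsistent")

  shallow <- variant_row("v4", 100, 38, 0)
  shallow$wt_depth <- 5L
  shallow$wt_alt <- 0L
  expect_equal(classify_segregation(shallow)$classification, "low_depth")

  wt <- classify_segregation(variant_row("v5", 100, 38, 20))
  expect_equal(wt$classification, "wt_contaminated")
  ns <- classify_segregation(variant_row("v6", 55, 38, 0))
  expect_equal(ns$classification, "non_segregating")

  expect_error(classify_segregation(list(variant_id = "x", mut_alt = 1)),
               "missing field")
})

test_that("every variant receives exactly one class and candidates satisfy the gates", {
  sim <- simulate_dataset(pedigree_config(n_background_variants = 300,
                                          seed = 14))
  t <- filter_thresholds()
  res <- filter_candidates(sim$variants, t)
  expect_equal(nrow(res$calls), nrow(sim$variants))
  expect_true(all(res$calls$classification %in%
                    c("candidate", "strain_fixed", "wt_contaminated",
                      "non_segregating", "sibling_ratio_inconsistent",
                      "low_depth")))
  expect_equal(sum(res$funnel[c("candidate", "strain_fixed",
                                "wt_contaminated", "non_segregating",
                                "sibling_ratio_inconsistent",
                                "low_depth")]),
               res$funnel[["total"]])
  cand <- res$candidates
  expect_true(all(cand$freq_mut >= t$min_mutant_freq))
  expect_true(all(cand$freq_wt <= t$max_wt_freq))
  expect_true(all(cand$sibling_p >= t$sibling_alpha))
  expect_true(all(cand[, c("mut_depth", "sib_depth", "wt_depth")] >=
                    t$min_depth))
})

test_that("stricter thresholds never admit more candidates", {
  sim <- simulate_dataset(pedigree_config(n_background_variants = 250,
                                          seed = 15))
  n_cand <- function(t) filter_candidates(sim$variants, t)$funnel[["candidate"]]
  base <- n_cand(filter_thresholds(min_mutant_freq = 0.9,
                                   max_wt_freq = 0.1))
  expect_lte(n_cand(filter_thresholds(min_mutant_freq = 0.97,
                                      max_wt_freq = 0.1)), base)
  expect_lte(n_cand(filter_thresholds(min_mutant_freq = 0.9,
                                      max_wt_freq = 0.02)), base)
})

test_that("swapping the mutant and wild-type pools flips candidates to wt_contaminated", {
  sim <- simulate_dataset(pedigree_config(n_background_variants = 120,
                                          seed = 16))
  res <- filter_candidates(sim$variants)
  cand <- res$candidates
  expect_gt(nrow(cand), 0)
  swapped <- cand
  swapped[, c("mut_alt", "mut_depth")] <- cand[, c("wt_alt", "wt_depth")]
  swapped[, c("wt_alt", "wt_depth")] <- cand[, c("mut_alt", "mut_depth")]
  out <- filter_candidates(swapped)
  expect_true(all(out$calls$classification == "wt_contaminated"))
})

test_that("filter handles empty and degenerate tables", {
  empty <- variant_row("v0", 1, 1, 1)[0, ]
  expect_warning(res <- filter_candidates(empty), "empty")
  expect_equal(res$funnel[["total"]], 0L)
  expect_equal(res$funnel[["candidate"]], 0L)

  allwt <- do.call(rbind, lapply(1:4, function(i)
    variant_row(paste0("w", i), 100, 100, 100)))
  expect_equal(filter_candidates(allwt)$funnel[["candidate"]], 0L)
})

test_that("threshold invariants are enforced", {
  expect_error(filter_thresholds(min_mutant_freq = 0.04),
               "must exceed")
  expect_error(filter_thresholds(sibling_expected_freq = 0.97),
               "strictly between")
  expect_error(filter_thresholds(min_depth = 0), "min_depth")
})
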