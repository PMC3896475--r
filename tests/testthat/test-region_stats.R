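test_that("rectum sites split into anterior and posterior halves", {
  est10 <- data.frame(preparation_id = "p", region_hint = rep("rectum", 10),
                      ordinal = sample(1:10))
  r10 <- assign_regions(est10)
  expect_equal(sum(r10$region == "anterior_rectum"), 5)
  expect_equal(sum(r10$region == "posterior_rectum"), 5)
  # anterior = lowest ordinals
  expect_setequal(r10$ordinal[r10$region == "anterior_rectum"], 1:5)
  # odd count: extra site goes anterior
  est7 <- data.frame(preparation_id = "p", region_hint = rep("rectum", 7),
                     ordinal = 1:7)
  r7 <- assign_regions(est7)
  expect_equal(sum(r7$region == "anterior_rectum"), 4)
  expect_equal(sum(r7$region == "posterior_rectum"), 3)
  # ileum sites pass through unchanged
  est_i <- data.frame(preparation_id = "p", region_hint = rep("ileum", 5),
                      ordinal = 1:5)
  expect_equal(assign_regions(est_i)$region, rep("ileum", 5))
  # partition is exhaustive and exclusive, split is per preparation
  est2 <- data.frame(preparation_id = rep(c("a", "b"), c(6, 7)),
                     region_hint = "rectum", ordinal = c(1:6, 1:7))
  r2 <- assign_regions(est2)
  expect_false(any(is.na(r2$region)))
  counts <- table(r2$preparation_id, r2$region)
  expect_true(all(abs(counts[, "anterior_rectum"] -
                        counts[, "posterior_rectum"]) <= 1))
  # errors
  expect_error(assign_regions(
    data.frame(preparation_id = "p", region_hint = "rectum",
               ordinal = NA_integer_)), "ordinal")
  expect_error(assign_regions(
    data.frame(preparation_id = "p", region_hint = "colon", ordinal = 1)),
    "unknown region_hint")
})

test_that("region summaries use the preparation as the replication unit", {
  s <- summarize_region(c(1, 2, 3))
  expect_equal(s$mean_flux, 2)
  expect_equal(s$sem_flux, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(s$sem_flux, 0.577, tolerance = 1e-3)
  s1 <- summarize_region(5)
  expect_equal(s1$mean_flux, 5)
  expect_true(is.na(s1$sem_flux))
  expect_error(summarize_region(numeric()), "no flux")
})

test_that("percent change works on magnitudes and flags sign reversals", {
  expect_equal(percent_change(-53.2, -13.3)$percent, -75)
  expect_equal(percent_change(26.7, 26.7)$percent, 0)
  expect_equal(percent_change(26.7, 8.544)$percent, -68)
  expect_false(percent_change(-53.2, -13.3)$sign_reversal)
  rev <- percent_change(-5, 3)
  expect_true(rev$sign_reversal)
  expect_equal(rev$percent, -40)
  expect_error(percent_change(0, 5), "zero")
})

test_that("one-way ANOVA and Bonferroni adjustment match hand computation", {
  # oracle: groups {1,2,3} vs {11,12,13}: SSB = 150, SSW = 4 on 1/4 df
  ab <- anova_bonferroni(list(a = c(1, 2, 3), b = c(11, 12, 13)))
  expect_equal(ab$f, 150)
  expect_lt(ab$p, 0.001)
  # identical groups: no between-group variance
  ab0 <- anova_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ab0$f, 0)
  expect_equal(ab0$p, 1)
  expect_false(any(ab0$pairwise$significant))
  # Bonferroni is exactly min(1, m p) and monotone in m
  ab3 <- anova_bonferroni(list(a = c(1, 2, 3), b = c(11, 12, 13)),
                          n_comparisons = 3)
  expect_equal(ab3$pairwise$p_adjusted, pmin(1, ab3$pairwise$p_raw * 3))
  ab50 <- anova_bonferroni(list(a = c(1, 2), b = c(1.5, 2.5)),
                           n_comparisons = 50)
  expect_lte(ab50$pairwise$p_adjusted, 1)
  expect_gte(ab50$pairwise$p_adjusted, ab50$pairwise$p_raw)
  # cross-check raw pairwise p against the pooled-SD t test
  g <- list(a = c(1, 2, 3), b = c(11, 12, 13), c = c(5, 6, 9))
  ab <- anova_bonferroni(g, n_comparisons = 3)
  pt <- stats::pairwise.t.test(unlist(g), rep(names(g), lengths(g)),
                               p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(sort(ab$pairwise$p_raw),
               sort(as.vector(pt$p.value[!is.na(pt$p.value)])))
  expect_error(anova_bonferroni(list(a = 1:3)), ">= 2 groups")
  expect_error(anova_bonferroni(list(a = 1:3, b = 2)),
               "insufficient replication")
})

test_that("false-positive rate is controlled on null simulations", {
  # equal true fluxes in both arms: per-preparation means are exchangeable,
  # so 500 replicate two-group comparisons at adjusted p < 0.05 (single
  # comparison) should reject at most 5% + 2 binomial SE of the time
  set.seed(202)
  n_rep <- 500L
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    g1 <- rnorm(10, 26.7, 6.7)
    g2 <- rnorm(10, 26.7, 6.7)
    ab <- anova_bonferroni(list(control = g1, treatment = g2),
                           n_comparisons = 1)
    if (ab$pairwise$significant[1]) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("the ileal Na+ effect is detected in most replicate batches", {
  # full-pipeline power check at the study conditions (N = 10, 5 ileum
  # sites, 15 uV sample noise): the 75% reduction of ileal Na+ secretion
  # should reach Bonferroni-adjusted significance in >= 80% of batches
  n_batches <- 12L
  detected <- 0L
  for (b in seq_len(n_batches)) {
    cmp <- simulate_comparison("Na", c(ileum = 5, rectum = 0),
                               seed = 300 + b)
    if (cmp$significant[cmp$region == "ileum"]) detected <- detected + 1L
  }
  expect_gte(detected, ceiling(0.8 * n_batches))
})

test_that("treatment comparison table assembles all per-region statistics", {
  ctrl <- data.frame(preparation_id = rep(paste0("c", 1:4), each = 2),
                     treatment = "control",
                     region = rep(c("ileum", "anterior_rectum"), 4),
                     mean_flux = c(-50, 5, -55, 6, -52, 4, -49, 5))
  trt <- data.frame(preparation_id = rep(paste0("t", 1:4), each = 2),
                    treatment = "GPA2/GPB5",
                    region = rep(c("ileum", "anterior_rectum"), 4),
                    mean_flux = c(-12, 5, -14, 6, -13, 4, -15, 5))
  cmp <- compare_treatments(ctrl, trt)
  expect_setequal(cmp$region, c("ileum", "anterior_rectum"))
  ile <- cmp[cmp$region == "ileum", ]
  expect_equal(ile$n_control, 4)
  expect_lt(ile$percent_change, -70)
  expect_true(ile$significant)
  expect_gte(ile$bonferroni_p, ile$anova_p)  # m = 2 regions here
  ant <- cmp[cmp$region == "anterior_rectum", ]
  expect_false(ant$significant)
  expect_equal(ant$percent_change, 0)
})
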