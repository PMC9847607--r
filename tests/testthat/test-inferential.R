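test_that("signed-rank statistic matches closed-form rank arithmetic", {
  # all differences positive with ranks 1..10: W = 55, z = 27.5/sqrt(96.25)
  x <- 1:10 + (1:10) / 10
  y <- rep(0, 10)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$W, 55)
  expect_equal(w$z, 27.5 / sqrt(96.25), tolerance = 1e-12)
  expect_equal(w$z, 2.803, tolerance = 1e-3)
  expect_equal(w$n_nonzero, 10)

  # antisymmetric differences: signed ranks cancel, z = 0
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  wa <- wilcoxon_signed_rank(d, rep(0, 8))
  expect_equal(wa$z, 0)
  expect_equal(wa$p_two_sided, 1)

  expect_error(wilcoxon_signed_rank(rep(1, 6), rep(1, 6)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, c(0, 0, 0)), ">= 5")
  expect_error(wilcoxon_signed_rank(1:4, 1:5), "equal length")
})

test_that("the exact enumeration matches the reference distribution", {
  # seeded continuous differences: the package's conditional enumeration must
  # agree with stats::wilcox.test's exact p to machine precision
  for (n in c(5, 8, 11, 15)) {
    for (seed in 1:10) {
      set.seed(n * 100 + seed)
      d <- rnorm(n, mean = 0.4)
      w <- wilcoxon_signed_rank(d, rep(0, n))
      expect_false(is.na(w$p_exact))
      ref <- suppressWarnings(wilcox.test(d, exact = TRUE))
      expect_equal(w$p_exact, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("normal-approximation p tracks the exact enumeration for small n", {
  # exhaustive over every achievable statistic (untied ranks): in the
  # decision-relevant region the uncorrected normal p stays close to the
  # exact p; the discreteness of the exact distribution widens the band
  # below n = 10
  for (n in 5:15) {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    for (W in 0:(n * (n + 1) / 2)) {
      p_exact <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
      if (p_exact > 0.25) next
      p_norm <- 2 * pnorm(-abs(W - mu) / sigma)
      expect_lt(abs(p_norm - p_exact), if (n >= 10) 0.03 else 0.05)
    }
  }
})

test_that("exact enumeration handles ties via the conditional distribution", {
  d <- c(1, 1, -1, 2, 3, 3, -2, 4)
  w <- wilcoxon_signed_rank(d, rep(0, 8))
  # brute force over all 2^8 sign assignments of the observed tied ranks
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  Wdist <- signs %*% r
  p_le <- mean(Wdist <= w$W)
  p_ge <- mean(Wdist >= w$W)
  expect_equal(w$p_exact, min(1, 2 * min(p_le, p_ge)), tolerance = 1e-12)
})

test_that("effect size r follows the participants-x-conditions convention", {
  expect_equal(round(effect_size_r(2.29, 20), 2), 0.51)
  expect_equal(round(effect_size_r(2.52, 20), 2), 0.56)
  expect_equal(effect_size_r(0, 20), 0)
  expect_equal(effect_size_r(-2.29, 20), effect_size_r(2.29, 20)) # absolute
})

test_that("d_z reproduces the published paired effect sizes", {
  # congruency with saltiness
  expect_equal(round(cohens_dz(mean_1 = 2.92, mean_2 = 0.98,
                               sd_1 = 1.97, sd_2 = 1.10, rho = 0.44), 2), 1.09)
  # edibility
  expect_equal(round(cohens_dz(mean_1 = 5.52, mean_2 = 2.96,
                               sd_1 = 0.67, sd_2 = 1.69, rho = 0.54), 2), 1.77)
  # familiarity and liking
  expect_equal(round(cohens_dz(mean_1 = 4.48, mean_2 = 3.35,
                               sd_1 = 1.26, sd_2 = 1.13, rho = 0.10), 2), 0.70)
  expect_equal(round(cohens_dz(mean_1 = 3.01, mean_2 = 3.00,
                               sd_1 = 1.00, sd_2 = 1.18, rho = -0.43), 2), 0.01)
  # null effect and degenerate denominator
  expect_equal(cohens_dz(mean_1 = 1, mean_2 = 1, sd_1 = 1, sd_2 = 1, rho = 0), 0)
  expect_error(cohens_dz(mean_1 = 1, mean_2 = 2, sd_1 = 1, sd_2 = 1, rho = 1),
               "non-positive")
})

test_that("d_z reduces to the expected closed forms", {
  # rho = 0: independent-variance denominator
  expect_equal(cohens_dz(mean_1 = 3, mean_2 = 1, sd_1 = 1.5, sd_2 = 2, rho = 0),
               2 / sqrt(1.5^2 + 2^2), tolerance = 1e-12)
  # equal sds: |dm| / (sigma * sqrt(2 - 2 rho))
  expect_equal(cohens_dz(mean_1 = 2, mean_2 = 1, sd_1 = 0.8, sd_2 = 0.8,
                         rho = 0.5),
               1 / (0.8 * sqrt(2 - 2 * 0.5)), tolerance = 1e-12)
  # consistent with a paired_summary built from data
  set.seed(4)
  x <- rnorm(12, 1)
  y <- rnorm(12)
  ps <- paired_summary(x, y)
  expect_equal(cohens_dz(ps),
               abs(mean(x) - mean(y)) /
                 sqrt(sd(x)^2 + sd(y)^2 - 2 * ps$rho * sd(x) * sd(y)),
               tolerance = 1e-12)
})

test_that("pooled d uses n-weighted variances and is symmetric", {
  g_wide <- group_summary(0.29, 0.08, 10)
  g_narrow <- group_summary(0.39, 0.11, 10)
  expect_equal(round(cohens_d_pooled(g_wide, g_narrow), 2), 1.04)
  expect_equal(cohens_d_pooled(g_wide, g_narrow),
               cohens_d_pooled(g_narrow, g_wide))
  # hand arithmetic with unequal n
  expect_equal(cohens_d_pooled(group_summary(0, 1, 4), group_summary(1, 2, 12)),
               1 / sqrt((4 + 48) / 16), tolerance = 1e-12)
  expect_equal(cohens_d_pooled(group_summary(2, 1, 5), group_summary(2, 3, 7)), 0)
  expect_error(cohens_d_pooled(group_summary(1, 0, 5), group_summary(2, 0, 5)),
               "zero pooled variance")
})

test_that("Spearman rho is the Pearson correlation of average ranks", {
  expect_equal(spearman_rho(1:8, exp(1:8)), 1)
  expect_equal(spearman_rho(1:8, -(1:8)^3), -1)
  # tie-heavy fixture against an independent average-rank computation
  x <- c(1, 2, 2, 2, 5, 6, 6, 9)
  y <- c(3, 3, 1, 5, 5, 5, 8, 8)
  expect_equal(spearman_rho(x, y), pearson_by_formula(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_warning(r0 <- spearman_rho(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.na(r0))
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
})

test_that("the no-correlation t test matches the published statistic", {
  res <- no_correlation_test(0.52, 20)
  expect_equal(res$df, 18)
  expect_equal(round(res$t, 2), 2.58)
  expect_lt(res$p_two_sided, 0.05)

  null <- no_correlation_test(0, 20)
  expect_equal(null$t, 0)
  expect_equal(null$p_two_sided, 1)
  expect_error(no_correlation_test(1, 20), "infinite")
})

test_that("correlation strength labels follow the conventional bounds", {
  expect_equal(no_correlation_test(0, 10)$strength_label, "none")
  expect_equal(no_correlation_test(0.39, 10)$strength_label, "weak")
  expect_equal(no_correlation_test(0.48, 10)$strength_label, "moderate")
  expect_equal(no_correlation_test(0.4, 10)$strength_label, "moderate")
  expect_equal(no_correlation_test(0.71, 10)$strength_label, "strong")
  expect_equal(no_correlation_test(-0.8, 10)$strength_label, "strong")
})

test_that("the no-correlation p-value decreases in |rho| at fixed n", {
  rhos <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(rhos, function(r) no_correlation_test(r, 15)$p_two_sided,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_equal(ps, vapply(-rhos, function(r) no_correlation_test(r, 15)$p_two_sided,
                          numeric(1)))
})
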