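test_that("noncentral-t kernel behaves at its boundaries", {
  expect_equal(noncentral_t_power(0, 18, alpha = 0.05, tails = 2), 0.05,
               tolerance = 1e-9)
  expect_equal(noncentral_t_power(0, 18, alpha = 0.01, tails = 1), 0.01,
               tolerance = 1e-9)
  expect_gt(noncentral_t_power(8, 18), 0.999)
  expect_error(noncentral_t_power(Inf, 18), "finite")
  expect_error(noncentral_t_power(1, 0), "> 0")
  expect_error(noncentral_t_power(1, 10, tails = 3), "tails")
})

test_that("noncentral-t power agrees with a Monte-Carlo draw", {
  set.seed(99)
  n_draw <- 4e5
  draws <- rnorm(n_draw, 3.0) / sqrt(rchisq(n_draw, 19) / 19)
  crit <- qt(0.975, 19)
  mc <- mean(abs(draws) > crit)
  expect_lt(abs(noncentral_t_power(3.0, 19) - mc),
            0.002 + 3 * sqrt(mc * (1 - mc) / n_draw))
})

test_that("matched-pairs Wilcoxon power reproduces the published values", {
  expect_equal(round(power_wilcoxon_matched(0.81, 20)$power, 2), 0.92)
  expect_equal(round(power_wilcoxon_matched(1.09, 20)$power, 2), 0.99)
  expect_equal(round(power_wilcoxon_matched(0.70, 20)$power, 2), 0.82)
  expect_equal(round(power_wilcoxon_matched(1.77, 20)$power, 2), 1.00)
  expect_equal(power_wilcoxon_matched(0, 20)$power, 0.05, tolerance = 1e-9)
  # effective n is ARE-shrunk and df fractional
  res <- power_wilcoxon_matched(0.81, 20)
  expect_equal(res$effective_n, 20 * 3 / pi, tolerance = 1e-12)
  expect_equal(res$df, 20 * 3 / pi - 1, tolerance = 1e-12)
  expect_error(power_wilcoxon_matched(0.5, 20, parent = "cauchy"))
})

test_that("A.R.E.-adjusted power is below the unadjusted t-test power", {
  for (d in c(0.3, 0.6, 1.0)) {
    for (n in c(10, 20, 40)) {
      w <- power_wilcoxon_matched(d, n)$power
      t_unadj <- noncentral_t_power(d * sqrt(n), n - 1)
      expect_lt(w, t_unadj)
    }
  }
})

test_that("matched-pairs power tracks a simulation of the actual test", {
  # paired normal data with standardized effect 0.5, n = 15 pairs entered;
  # reduced replicate count here, full 1e5 in the acceptance suite
  set.seed(7)
  n_rep <- 20000
  rejects <- vapply(seq_len(n_rep), function(i) {
    signed_rank_reject(rnorm(15, 0.5))
  }, logical(1))
  sim <- mean(rejects)
  expect_lt(abs(power_wilcoxon_matched(0.5, 15)$power - sim), 0.03)
})

test_that("exact correlation power reproduces the published values", {
  expect_equal(round(power_correlation_exact(0.52, 20)$power, 2), 0.68)
  expect_equal(round(power_correlation_exact(0.48, 20)$power, 2), 0.60)
  expect_equal(power_correlation_exact(0, 20)$power, 0.05, tolerance = 1e-6)
  expect_equal(power_correlation_exact(-0.52, 20)$power,
               power_correlation_exact(0.52, 20)$power, tolerance = 1e-9)
  expect_error(power_correlation_exact(1, 20), "< 1")
  expect_error(power_correlation_exact(0.5, 20, rho_null = 0.2), "zero null")
})

test_that("the exact sampling density of r integrates to one", {
  for (rho in c(0, 0.3, 0.7)) {
    total <- integrate(function(r) tbwsj:::sample_correlation_density(r, rho, 20),
                       -1, 1, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("exact correlation power tracks a bivariate-normal simulation", {
  set.seed(12)
  n <- 30
  rho <- 0.4
  n_rep <- 20000
  x <- matrix(rnorm(n * n_rep), n_rep, n)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * n_rep), n_rep, n)
  r <- vapply(seq_len(n_rep), function(i) cor(x[i, ], y[i, ]), numeric(1))
  t_crit <- qt(0.975, n - 2)
  r_crit <- t_crit / sqrt(n - 2 + t_crit^2)
  sim <- mean(abs(r) > r_crit)
  expect_lt(abs(power_correlation_exact(rho, n)$power - sim), 0.02)
})

test_that("the Fisher-z route is available as a labeled approximation", {
  ex <- power_correlation_exact(0.52, 20)
  fz <- power_correlation_exact(0.52, 20, method = "fisher_z")
  expect_equal(ex$method, "exact")
  expect_equal(fz$method, "fisher_z")
  expect_lt(abs(ex$power - fz$power), 0.06)
})

test_that("WMW sample size reproduces the published a-priori result", {
  res <- sample_size_wmw(d = 1.04, alpha = 0.05, power_target = 0.80)
  expect_equal(res$n_total, 34)
  expect_equal(res$n_1, 17)
  expect_equal(res$n_2, 17)
  expect_gte(res$achieved_power, 0.80)
})

test_that("WMW sample size is minimal and saturates for huge effects", {
  res <- sample_size_wmw(d = 0.8)
  below <- tbwsj:::power_wmw_two_groups(0.8, res$n_1 - 1, res$n_2 - 1)
  expect_gte(res$achieved_power, 0.80)
  expect_lt(below$power, 0.80)

  big <- sample_size_wmw(d = 10)
  expect_equal(big$n_1, 2) # minimum feasible group size
  expect_gt(big$achieved_power, 0.95)

  expect_error(sample_size_wmw(d = 0), "unreachable")
  # allocation ratio 2: n_2 = 2 n_1
  unequal <- sample_size_wmw(d = 1.04, allocation_ratio = 2)
  expect_equal(unequal$n_2, 2 * unequal$n_1)
})

test_that("power functions are monotone in effect size, n and alpha", {
  d_grid <- seq(0.2, 1.4, by = 0.2)
  p_d <- vapply(d_grid, function(d) power_wilcoxon_matched(d, 20)$power,
                numeric(1))
  expect_true(all(diff(p_d) > 0))
  n_grid <- seq(6, 60, by = 6)
  p_n <- vapply(n_grid, function(n) power_wilcoxon_matched(0.5, n)$power,
                numeric(1))
  expect_true(all(diff(p_n) > 0))
  a_grid <- c(0.01, 0.05, 0.1, 0.2)
  p_a <- vapply(a_grid, function(a) power_wilcoxon_matched(0.5, 20, alpha = a)$power,
                numeric(1))
  expect_true(all(diff(p_a) > 0))
  r_grid <- seq(0.1, 0.9, by = 0.1)
  p_r <- vapply(r_grid, function(r) power_correlation_exact(r, 20)$power,
                numeric(1))
  expect_true(all(diff(p_r) > 0))
})
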