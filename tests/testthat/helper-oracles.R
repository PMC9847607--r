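# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Noiseless binned rates from a Gaussian curve at the default window centers.
make_noiseless_binned <- function(a, b_s, c_s, n_per_window = 12,
                                  centers_ms = seq(-1000, 1000, by = 100)) {
  rate <- a * exp(-(centers_ms / 1000 - b_s)^2 / (2 * c_s^2))
  structure(
    list(window_centers_ms = centers_ms,
         window_edges_ms = c(centers_ms - 50, centers_ms[length(centers_ms)] + 50),
         n_trials = rep(n_per_window, length(centers_ms)),
         n_simultaneous = round(rate * n_per_window),
         rate = rate),
    class = "sj_binned"
  )
}

# Zooming dense grid search for the Gaussian least-squares minimum: an
# independent route to the optimum that never calls the package optimizer.
grid_search_sse <- function(t_s, y, zooms = 6, n_grid = 21) {
  lims <- list(a = c(1e-3, 1.2), b = c(-1, 1), c = c(0.01, 2))
  best <- NULL
  for (z in seq_len(zooms)) {
    ag <- seq(lims$a[1], lims$a[2], length.out = n_grid)
    bg <- seq(lims$b[1], lims$b[2], length.out = n_grid)
    cg <- seq(lims$c[1], lims$c[2], length.out = n_grid)
    for (a in ag) for (b in bg) for (cc in cg) {
      sse <- sum((y - a * exp(-(t_s - b)^2 / (2 * cc^2)))^2)
      if (is.null(best) || sse < best$sse) best <- list(a = a, b = b, c = cc, sse = sse)
    }
    shrink <- function(lim, center) {
      w <- diff(lim) / (n_grid - 1) * 2
      c(max(lim[1], center - w), min(lim[2], center + w))
    }
    lims <- list(a = shrink(lims$a, best$a), b = shrink(lims$b, best$b),
                 c = shrink(lims$c, best$c))
  }
  best
}

# Textbook sum-based Pearson correlation (no stats::cor).
pearson_by_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Signed-rank z statistic and normal-approximation p for a vector of paired
# differences; standalone re-derivation used by the power simulation oracle.
signed_rank_reject <- function(d, alpha = 0.05) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  z <- (W - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  2 * pnorm(-abs(z)) < alpha
}
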