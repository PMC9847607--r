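# Inferential module: paired nonparametric comparison, effect sizes and
# correlation tests on per-participant index values and ratings.

#' Wilcoxon signed-rank test (normal approximation, exact for small n)
#'
#' Paired two-sided test. Zero differences are dropped; absolute differences
#' are ranked with average ranks for ties; `W` is the positive-rank sum. The
#' standardized statistic uses the tie-corrected variance and no continuity
#' correction:
#' \deqn{z = \frac{W - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum(t^3-t)/48}}.}
#' For `n <= 25` nonzero differences the exact two-sided p-value is also
#' computed by enumerating the null distribution of `W` conditional on the
#' observed (tied) ranks.
#'
#' @param values_1,values_2 Paired numeric vectors of equal length.
#' @return An object of class `wilcoxon_result`: list with `W`, `z`,
#'   `p_two_sided` (normal approximation), `p_exact` (`NA` when `n > 25`),
#'   `n_nonzero`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
wilcoxon_signed_rank <- function(values_1, values_2) {
  if (length(values_1) != length(values_2)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- values_1 - values_2
  if (anyNA(d)) stop("paired values must not contain NA", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero", call. = FALSE)
  if (n < 5L) {
    stop(sprintf("need >= 5 nonzero differences; have %d", n), call. = FALSE)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_sizes <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  z <- (W - mu) / sqrt(sigma2)
  p_norm <- 2 * stats::pnorm(-abs(z))
  p_exact <- if (n <= 25L) exact_signed_rank_p(r, W) else NA_real_
  structure(
    list(W = W, z = z, p_two_sided = p_norm, p_exact = p_exact, n_nonzero = n),
    class = "wilcoxon_result"
  )
}

# Exact two-sided p for the positive-rank sum, conditional on the observed
# ranks (handles average ranks for ties: ranks are multiples of 1/2, so the
# distribution is built over doubled ranks by polynomial convolution).
exact_signed_rank_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), f[seq_len(total + 1L - rr)])
    f <- f + shifted
  }
  f <- f / 2^length(r2)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %.1f, z = %.3f, p = %.4f (n = %d)\n",
              x$W, x$z, x$p_two_sided, x$n_nonzero))
  if (!is.na(x$p_exact)) cat(sprintf("  exact p = %.4f\n", x$p_exact))
  invisible(x)
}

#' Effect size r for the Wilcoxon signed-rank test
#'
#' \eqn{r = |z| / \sqrt{n}} where `n_total` is the total sample size counted
#' as participants times conditions (the reporting convention followed here:
#' 10 participants x 2 conditions gives n = 20), not the number of pairs.
#' Benchmarks: 0.1 small, 0.3 medium, 0.5 large.
#'
#' @param z Standardized Wilcoxon statistic.
#' @param n_total Total sample size (participants x conditions).
#' @return Effect size r (nonnegative).
#' @export
effect_size_r <- function(z, n_total) {
  assert_number(z, "z")
  if (!is.numeric(n_total) || n_total < 1) {
    stop("`n_total` must be >= 1", call. = FALSE)
  }
  abs(z) / sqrt(n_total)
}

#' Summaries of a paired comparison
#'
#' Means, SDs and the Spearman correlation between two paired condition
#' vectors — the ingredients of the paired effect size \eqn{d_z}.
#'
#' @param values_1,values_2 Paired numeric vectors.
#' @return An object of class `paired_summary`.
#' @export
paired_summary <- function(values_1, values_2) {
  if (length(values_1) != length(values_2) || length(values_1) < 2L) {
    stop("need paired vectors of equal length >= 2", call. = FALSE)
  }
  structure(
    list(mean_1 = mean(values_1), mean_2 = mean(values_2),
         sd_1 = stats::sd(values_1), sd_2 = stats::sd(values_2),
         rho = spearman_rho(values_1, values_2),
         n_pairs = length(values_1)),
    class = "paired_summary"
  )
}

#' Paired effect size d_z with correlated SDs
#'
#' \deqn{d_z = \frac{|m_1 - m_2|}{\sqrt{\sigma_1^2 + \sigma_2^2 -
#'   2\rho\sigma_1\sigma_2}},}
#' where \eqn{\rho} is the Spearman correlation between the two conditions.
#' Reported as an absolute value.
#'
#' @param summary A [paired_summary()]; alternatively pass the five numbers
#'   explicitly.
#' @param mean_1,mean_2,sd_1,sd_2,rho Explicit components (used when
#'   `summary` is missing).
#' @return Effect size d_z.
#' @export
#' @examples
#' cohens_dz(mean_1 = 2.92, mean_2 = 0.98, sd_1 = 1.97, sd_2 = 1.10, rho = 0.44)
cohens_dz <- function(summary = NULL, mean_1, mean_2, sd_1, sd_2, rho) {
  if (!is.null(summary)) {
    if (!inherits(summary, "paired_summary")) {
      stop("`summary` must be a paired_summary", call. = FALSE)
    }
    mean_1 <- summary$mean_1; mean_2 <- summary$mean_2
    sd_1 <- summary$sd_1; sd_2 <- summary$sd_2; rho <- summary$rho
  }
  denom2 <- sd_1^2 + sd_2^2 - 2 * rho * sd_1 * sd_2
  if (!is.finite(denom2) || denom2 <= 0) {
    stop("non-positive variance of the paired difference (rho too close to 1?)",
         call. = FALSE)
  }
  abs(mean_1 - mean_2) / sqrt(denom2)
}

#' Two-group summary
#'
#' @param mean,sd,n Group mean, SD and sample size (`n >= 1`, `sd >= 0`).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  assert_number(mean, "mean"); assert_number(sd, "sd")
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Pooled two-group effect size d (n-weighted)
#'
#' \deqn{d = \frac{|m_1 - m_2|}{\sqrt{(n_1\sigma_1^2 + n_2\sigma_2^2)/
#'   (n_1 + n_2)}}.}
#' Note the n-weighted (not n-1) pooling of the variances.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return Effect size d.
#' @export
#' @examples
#' cohens_d_pooled(group_summary(0.29, 0.08, 10), group_summary(0.39, 0.11, 10))
cohens_d_pooled <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  denom2 <- (g1$n * g1$sd^2 + g2$n * g2$sd^2) / (g1$n + g2$n)
  if (denom2 <= 0) stop("zero pooled variance", call. = FALSE)
  abs(g1$mean - g2$mean) / sqrt(denom2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive average ranks).
#' Returns `NA` with a warning when either variable has zero rank variance.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need vectors of equal length >= 3", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

correlation_strength <- function(rho) {
  a <- abs(rho)
  if (a == 0) "none"
  else if (a < 0.4) "weak"
  else if (a < 0.7) "moderate"
  else if (a < 1) "strong"
  else "perfect"
}

#' Test of no correlation
#'
#' t-test of \eqn{H_0: \rho = 0} for a correlation coefficient:
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on `n - 2` degrees of freedom,
#' two-sided. The strength label follows the conventional bounds: none (0),
#' weak (<0.4), moderate (<0.7), strong (<1), perfect (1), on \eqn{|\rho|}.
#'
#' @param rho Observed correlation, `|rho| < 1`.
#' @param n Number of paired observations, `>= 3`.
#' @return An object of class `correlation_result`: list with `rho`, `t`,
#'   `df`, `p_two_sided`, `strength_label`.
#' @export
#' @examples
#' no_correlation_test(0.52, 20)
no_correlation_test <- function(rho, n) {
  assert_number(rho, "rho")
  if (!is.numeric(n) || n < 3) stop("`n` must be >= 3", call. = FALSE)
  if (abs(rho) >= 1) {
    stop("|rho| = 1 gives an infinite test statistic", call. = FALSE)
  }
  df <- n - 2
  t <- rho * sqrt(df / (1 - rho^2))
  structure(
    list(rho = rho, t = t, df = df,
         p_two_sided = 2 * stats::pt(-abs(t), df),
         strength_label = correlation_strength(rho)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Correlation: rho = %.3f (%s), t(%d) = %.3f, p = %.4f\n",
              x$rho, x$strength_label, x$df, x$t, x$p_two_sided))
  invisible(x)
}
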