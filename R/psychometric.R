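# Psychometric module: Gaussian simultaneity-curve fitting and the derived
# temporal-binding-window indices.

gauss_curve <- function(t_s, a, b, c) a * exp(-(t_s - b)^2 / (2 * c^2))

#' Fit the Gaussian simultaneity curve
#'
#' Least-squares fit of \eqn{y = a \exp\{-(t-b)^2/(2c^2)\}} to the
#' per-window simultaneous-response rates, with `t` in seconds. Only occupied
#' windows enter the (unweighted) loss. Optimization is bounded
#' Levenberg-Marquardt with multiple starts: `a` initialized at the maximum
#' rate, `b` at the corresponding window center (ties broken toward 0 ms),
#' and `c` over several plausible scales. Bounds keep the peak interpretable
#' (`a` in (0, 1.2], `|b| <= 1` s, `c` in (0.01, 5] s) while tolerating
#' sampling noise slightly above 1.
#'
#' @param binned An `sj_binned` object from [bin_trials()].
#' @param c_starts Starting values for `c` in seconds.
#' @param max_amplitude Upper bound for `a`.
#' @return An object of class `gaussian_fit`: list with `a`, `b`, `c` (seconds),
#'   `sse`, `converged`, `n_windows_used`.
#' @export
#' @examples
#' obs <- observer_model(amplitude = 0.8, center_s = -0.1, width_s = 0.35,
#'                       lapse_rate = 0, jitter_sd_ms = 0)
#' trials <- simulate_trials(obs, rep(soa_steps_ms(), 12), seed = 1)
#' fit <- fit_gaussian(bin_trials(select_trials(trials)))
fit_gaussian <- function(binned, c_starts = c(0.2, 0.4, 0.8),
                         max_amplitude = 1.2) {
  if (!inherits(binned, "sj_binned")) {
    stop("`binned` must be an sj_binned object", call. = FALSE)
  }
  occ <- which(binned$n_trials > 0 & !is.na(binned$rate))
  if (length(occ) < 4L) {
    stop(sprintf("need >= 4 occupied windows to fit 3 parameters; have %d",
                 length(occ)), call. = FALSE)
  }
  y <- binned$rate[occ]
  t_s <- binned$window_centers_ms[occ] / 1000
  if (all(y == 0)) {
    stop("all simultaneous-response rates are zero: no peak to fit",
         call. = FALSE)
  }
  peak <- which(y == max(y))
  b0 <- t_s[peak[which.min(abs(t_s[peak]))]]  # tie -> center closest to 0
  a0 <- min(max(max(y), 1e-3), max_amplitude)
  lower <- c(a = 1e-8, b = -1, c = 0.01)
  upper <- c(a = max_amplitude, b = 1, c = 5)
  resid_fn <- function(par) y - gauss_curve(t_s, par[1], par[2], par[3])
  best <- NULL
  for (c0 in c_starts) {
    start <- pmin(pmax(c(a = a0, b = b0, c = c0), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse, info = fit$info)
    }
  }
  if (is.null(best)) stop("Gaussian fit failed for all starts", call. = FALSE)
  structure(
    list(a = unname(best$par[1]), b = unname(best$par[2]),
         c = unname(best$par[3]), sse = best$sse,
         converged = best$info %in% 1:3,
         n_windows_used = length(occ)),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("Gaussian simultaneity curve  y = a*exp{-(t-b)^2/(2c^2)}\n")
  cat(sprintf("  a = %.4f, b = %+.4f s, c = %.4f s  (SSE %.3g, %d windows%s)\n",
              x$a, x$b, x$c, x$sse, x$n_windows_used,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Goodness of fit of the Gaussian approximation
#'
#' The Pearson product-moment correlation between the observed
#' simultaneous-response rates and the fitted values at the occupied window
#' centers. Returns `NA` (with a warning) when either side has zero variance.
#'
#' @param binned An `sj_binned` object.
#' @param fit A `gaussian_fit` for the same data.
#' @return A single correlation coefficient.
#' @export
goodness_of_fit <- function(binned, fit) {
  stopifnot(inherits(binned, "sj_binned"), inherits(fit, "gaussian_fit"))
  occ <- which(binned$n_trials > 0 & !is.na(binned$rate))
  if (length(occ) < 3L) {
    stop("need >= 3 occupied windows for a correlation", call. = FALSE)
  }
  y <- binned$rate[occ]
  yhat <- gauss_curve(binned$window_centers_ms[occ] / 1000, fit$a, fit$b, fit$c)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warning("zero variance in observed or fitted rates; goodness of fit undefined")
    return(NA_real_)
  }
  stats::cor(y, yhat)
}

#' Temporal-binding-window indices from a Gaussian fit
#'
#' The headline index is the half width at half height,
#' HWHH \eqn{= c\sqrt{2\ln 2} \approx 1.18\,c}; FWHH is twice that, and
#' \eqn{\sigma} is `c` itself. Absolute-threshold indices exist only when the
#' curve actually crosses the threshold: the 75% interval and JND require
#' `a > 0.75`, the 50%-crossing half-interval (`delta50`) requires `a > 0.5`;
#' otherwise they are `NA` with the reason recorded in attribute
#' `"undefined_reason"`.
#'
#' @param fit A converged `gaussian_fit`.
#' @param goodness Optional goodness-of-fit correlation to carry along.
#' @return An object of class `tbw_indices`: list with `hwhh_s`, `fwhh_s`,
#'   `sigma_s`, `width75_s`, `jnd75_s`, `delta50_s`, `goodness_of_fit`
#'   (all widths in seconds).
#' @export
#' @examples
#' tbw_indices(structure(list(a = 0.8, b = 0, c = 0.44, sse = 0,
#'                            converged = TRUE, n_windows_used = 21),
#'                       class = "gaussian_fit"))
tbw_indices <- function(fit, goodness = NA_real_) {
  if (!inherits(fit, "gaussian_fit")) {
    stop("`fit` must be a gaussian_fit", call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    stop("indices require a converged fit", call. = FALSE)
  }
  a <- fit$a
  c_s <- fit$c
  hwhh <- c_s * sqrt(2 * log(2))
  reasons <- character(0)
  if (a > 0.75) {
    jnd75 <- c_s * sqrt(2 * log(a / 0.75))
    width75 <- 2 * jnd75
  } else {
    jnd75 <- width75 <- NA_real_
    reasons <- c(reasons, "peak rate a <= 0.75: curve never reaches 75%")
  }
  if (a > 0.5) {
    delta50 <- c_s * sqrt(2 * log(a / 0.5))
  } else {
    delta50 <- NA_real_
    reasons <- c(reasons, "peak rate a <= 0.5: curve never reaches 50%")
  }
  structure(
    list(hwhh_s = hwhh, fwhh_s = 2 * hwhh, sigma_s = c_s,
         width75_s = width75, jnd75_s = jnd75, delta50_s = delta50,
         goodness_of_fit = goodness),
    class = "tbw_indices",
    undefined_reason = if (length(reasons)) reasons else NULL
  )
}

#' @export
print.tbw_indices <- function(x, ...) {
  cat("Temporal binding window indices (s)\n")
  cat(sprintf("  HWHH %.4f | FWHH %.4f | sigma %.4f\n",
              x$hwhh_s, x$fwhh_s, x$sigma_s))
  cat(sprintf("  width75 %s | JND75 %s | delta50 %s\n",
              formatC(x$width75_s, digits = 4, format = "f"),
              formatC(x$jnd75_s, digits = 4, format = "f"),
              formatC(x$delta50_s, digits = 4, format = "f")))
  if (!is.na(x$goodness_of_fit)) {
    cat(sprintf("  goodness of fit r = %.3f\n", x$goodness_of_fit))
  }
  invisible(x)
}
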