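# Synthetic-observer module: trial sequences and simulated SJ responses with
# the statistical structure the analysis assumes (Gaussian simultaneity
# probability over actual SOA, onset jitter, occasional missing responses).

#' Define a synthetic SJ observer
#'
#' An observer answers "simultaneous" on a trial with probability
#' \eqn{a \exp\{-(t - b)^2 / (2 c^2)\}}, where \eqn{t} is the actual SOA in
#' seconds, \eqn{a} is the peak simultaneous-response probability, \eqn{b} the
#' point of subjective simultaneity (PSS) and \eqn{c} the Gaussian scale that
#' sets the temporal binding window. On a fraction `lapse_rate` of trials the
#' observer gives no response at all (the missing-response mechanism of the
#' finger-report task, not a random guess). Actual SOA deviates from nominal
#' SOA by Gaussian onset jitter with SD `jitter_sd_ms`.
#'
#' @param amplitude Peak simultaneous-response probability `a`, in `[0, 1]`.
#' @param center_s PSS `b` in seconds (negative: odor-first side).
#' @param width_s Gaussian scale `c` in seconds, strictly positive.
#' @param lapse_rate Per-trial probability of no response, in `[0, 1)`.
#' @param jitter_sd_ms SD of (actual - nominal) SOA noise in ms, `>= 0`.
#' @return An object of class `observer_model`.
#' @export
#' @examples
#' obs <- observer_model(amplitude = 0.75, center_s = -0.15, width_s = 0.4)
observer_model <- function(amplitude = 0.75, center_s = -0.15, width_s = 0.4,
                           lapse_rate = 0.01, jitter_sd_ms = 30) {
  assert_number(amplitude, "amplitude")
  assert_number(center_s, "center_s")
  assert_number(width_s, "width_s")
  assert_number(lapse_rate, "lapse_rate")
  assert_number(jitter_sd_ms, "jitter_sd_ms")
  if (amplitude < 0 || amplitude > 1) {
    stop("`amplitude` must lie in [0, 1]", call. = FALSE)
  }
  if (width_s <= 0) stop("`width_s` must be > 0", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate >= 1) {
    stop("`lapse_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (jitter_sd_ms < 0) stop("`jitter_sd_ms` must be >= 0", call. = FALSE)
  structure(
    list(amplitude = amplitude, center_s = center_s, width_s = width_s,
         lapse_rate = lapse_rate, jitter_sd_ms = jitter_sd_ms),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat("Synthetic SJ observer\n")
  cat(sprintf("  amplitude a      : %.3f\n", x$amplitude))
  cat(sprintf("  PSS b (s)        : %+.3f\n", x$center_s))
  cat(sprintf("  width c (s)      : %.3f  (HWHH %.3f s)\n",
              x$width_s, x$width_s * sqrt(2 * log(2))))
  cat(sprintf("  lapse rate       : %.3f\n", x$lapse_rate))
  cat(sprintf("  jitter SD (ms)   : %.1f\n", x$jitter_sd_ms))
  invisible(x)
}

#' Hyperpriors for one experimental condition
#'
#' Per-participant observer parameters are drawn from these distributions:
#' the Gaussian scale `c` from a lognormal (positivity), the amplitude `a`
#' from a normal truncated to `[0, 1]`, and the PSS `b` from a normal.
#' Defaults reproduce the group-level curve shapes of the congruent
#' (soy-sauce odor + saline) condition; see [cohort_config()] for both
#' conditions.
#'
#' @param amplitude_mean,amplitude_sd Truncated-normal hyperprior for `a`.
#' @param pss_mean_s,pss_sd_s Normal hyperprior for `b` (seconds).
#' @param width_mean_s,width_sd_s Mean and SD of the lognormal for `c`
#'   (seconds), parameterized on the natural scale.
#' @param lapse_rate,jitter_sd_ms Shared (non-random) nuisance parameters.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(amplitude_mean = 0.73, amplitude_sd = 0.10,
                           pss_mean_s = -0.16, pss_sd_s = 0.10,
                           width_mean_s = 0.44, width_sd_s = 0.195,
                           lapse_rate = 0.01, jitter_sd_ms = 30) {
  if (width_mean_s <= 0 || width_sd_s <= 0) {
    stop("width hyperprior must have positive mean and SD", call. = FALSE)
  }
  if (amplitude_sd <= 0 || pss_sd_s <= 0) {
    stop("amplitude and PSS hyperpriors must have positive SD", call. = FALSE)
  }
  structure(
    list(amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
         pss_mean_s = pss_mean_s, pss_sd_s = pss_sd_s,
         width_mean_s = width_mean_s, width_sd_s = width_sd_s,
         lapse_rate = lapse_rate, jitter_sd_ms = jitter_sd_ms),
    class = "condition_spec"
  )
}

#' Configure a synthetic cohort
#'
#' Emulates the SJ study design: each participant completes both conditions,
#' three sessions per condition, 92 test trials per session. Per-participant
#' widths are correlated across conditions through a Gaussian copula so that
#' the paired effect size \eqn{d_z} has a controllable correlation term.
#' Default hyperpriors follow the group summaries of the two conditions
#' (congruent: HWHH 0.52 +/- 0.23 s; incongruent: 0.38 +/- 0.12 s; width
#' correlation 0.71).
#'
#' @param n_participants Number of participants (`>= 1`).
#' @param n_sessions_per_condition Sessions per condition (design: 3).
#' @param condition_specs Named list of two [condition_spec()] objects.
#' @param between_condition_correlation Copula correlation of `width_s`
#'   across the two conditions, in `[-1, 1]`.
#' @param seed Integer master seed; all per-participant streams are derived
#'   from it deterministically.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 10,
                          n_sessions_per_condition = 3,
                          condition_specs = list(
                            congruent = condition_spec(),
                            incongruent = condition_spec(
                              amplitude_mean = 0.76, pss_mean_s = -0.11,
                              width_mean_s = 0.32, width_sd_s = 0.102)
                          ),
                          between_condition_correlation = 0.71,
                          seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("`n_participants` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_sessions_per_condition) || n_sessions_per_condition < 1) {
    stop("`n_sessions_per_condition` must be >= 1", call. = FALSE)
  }
  if (!is.list(condition_specs) || length(condition_specs) != 2L ||
      is.null(names(condition_specs)) || any(names(condition_specs) == "")) {
    stop("`condition_specs` must be a named list of two condition_spec objects",
         call. = FALSE)
  }
  if (!all(vapply(condition_specs, inherits, logical(1), "condition_spec"))) {
    stop("each element of `condition_specs` must be a condition_spec",
         call. = FALSE)
  }
  rho <- between_condition_correlation
  assert_number(rho, "between_condition_correlation")
  if (rho < -1 || rho > 1) {
    stop("`between_condition_correlation` must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_sessions_per_condition = as.integer(n_sessions_per_condition),
         condition_specs = condition_specs,
         between_condition_correlation = rho,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a 92-trial SJ test sequence
#'
#' Each of the 23 nominal SOA steps appears exactly four times (92 trials) in
#' random order, with the constraint that the same SOA never occurs on two
#' consecutive trials. Sequences are found by rejection resampling, which is
#' guaranteed to terminate because valid orderings are plentiful.
#'
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return Integer vector of 92 nominal SOAs in ms.
#' @export
#' @examples
#' s <- make_test_sequence(7)
#' table(s)          # every step exactly 4 times
#' any(diff(s) == 0) # FALSE
make_test_sequence <- function(seed) {
  pool <- rep(soa_steps_ms(), each = 4L)
  with_preserved_seed(seed, {
    repeat {
      s <- sample(pool)
      if (!any(diff(s) == 0L)) return(s)
    }
  })
}

#' Training SOA sequence
#'
#' The fixed five-step SJ training order: 0, -800, 400, 800, -400 ms.
#'
#' @return Integer vector of length 5.
#' @export
make_training_sequence <- function() {
  c(0L, -800L, 400L, 800L, -400L)
}

#' Simulate SJ responses for one observer over a sequence
#'
#' For each nominal SOA in `sequence`, the actual SOA is drawn as
#' nominal + Normal(0, `jitter_sd_ms`). With probability `lapse_rate` the
#' response is `"none"`; otherwise the response is `"simultaneous"` with
#' probability \eqn{a \exp\{-(t - b)^2/(2 c^2)\}} at the actual SOA
#' \eqn{t} (seconds), else `"successive"`.
#'
#' @param observer An [observer_model()].
#' @param sequence Nominal SOAs in ms (nonempty numeric vector).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A data frame with columns `trial_index`, `nominal_soa_ms`,
#'   `actual_soa_ms`, `response`.
#' @export
simulate_trials <- function(observer, sequence, seed) {
  if (!inherits(observer, "observer_model")) {
    stop("`observer` must be an observer_model", call. = FALSE)
  }
  if (length(sequence) == 0L || !is.numeric(sequence)) {
    stop("`sequence` must be a nonempty numeric vector of nominal SOAs (ms)",
         call. = FALSE)
  }
  n <- length(sequence)
  with_preserved_seed(seed, {
    actual <- sequence + stats::rnorm(n, 0, observer$jitter_sd_ms)
    u_lapse <- stats::runif(n)
    u_resp <- stats::runif(n)
    p_sim <- observer$amplitude *
      exp(-(actual / 1000 - observer$center_s)^2 / (2 * observer$width_s^2))
    response <- ifelse(u_lapse < observer$lapse_rate, "none",
                       ifelse(u_resp < p_sim, "simultaneous", "successive"))
    data.frame(
      trial_index = seq_len(n),
      nominal_soa_ms = as.numeric(sequence),
      actual_soa_ms = actual,
      response = response,
      stringsAsFactors = FALSE
    )
  })
}

# Draw per-participant observer parameters for both conditions. Widths are
# coupled through a Gaussian copula at the configured correlation; amplitudes
# come from a normal truncated to [0, 1] by inverse-CDF sampling.
draw_cohort_parameters <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  conds <- names(config$condition_specs)
  rho <- config$between_condition_correlation
  lnorm_par <- function(m, s) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    with_preserved_seed(derive_seed(config$seed, i), {
      z1 <- stats::rnorm(1)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
      z <- c(z1, z2)
      per_cond <- lapply(seq_along(conds), function(k) {
        spec <- config$condition_specs[[k]]
        lp <- lnorm_par(spec$width_mean_s, spec$width_sd_s)
        width <- stats::qlnorm(stats::pnorm(z[k]), lp$meanlog, lp$sdlog)
        # inverse-CDF draw from Normal(mean, sd) truncated to [0, 1]
        lo <- stats::pnorm(0, spec$amplitude_mean, spec$amplitude_sd)
        hi <- stats::pnorm(1, spec$amplitude_mean, spec$amplitude_sd)
        amp <- stats::qnorm(lo + stats::runif(1) * (hi - lo),
                            spec$amplitude_mean, spec$amplitude_sd)
        amp <- min(max(amp, 0), 1)
        pss <- stats::rnorm(1, spec$pss_mean_s, spec$pss_sd_s)
        data.frame(
          participant_id = pid, condition = conds[k],
          amplitude = amp, center_s = pss, width_s = width,
          lapse_rate = spec$lapse_rate, jitter_sd_ms = spec$jitter_sd_ms,
          stringsAsFactors = FALSE
        )
      })
      rows[[i]] <- do.call(rbind, per_cond)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full SJ cohort
#'
#' Draws per-participant observer parameters once per condition (shared across
#' that participant's sessions) and simulates every session's 92-trial test
#' sequence. With the defaults (10 participants, 2 conditions, 3 sessions)
#' this yields 5520 trials, 2760 per condition.
#'
#' @param config A [cohort_config()].
#' @return A data frame of trials with columns `participant_id`, `condition`,
#'   `session`, `trial_index`, `nominal_soa_ms`, `actual_soa_ms`, `response`.
#'   The true generating parameters are attached as attribute `"parameters"`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config", call. = FALSE)
  }
  params <- draw_cohort_parameters(config)
  conds <- names(config$condition_specs)
  chunks <- list()
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    for (k in seq_along(conds)) {
      row <- params[params$participant_id == pid & params$condition == conds[k], ]
      obs <- observer_model(row$amplitude, row$center_s, row$width_s,
                            row$lapse_rate, row$jitter_sd_ms)
      for (s in seq_len(config$n_sessions_per_condition)) {
        unit <- (i - 1L) * 97L + (k - 1L) * 31L + s
        seq_seed <- derive_seed(config$seed, 1000000L + unit)
        trial_seed <- derive_seed(config$seed, 2000000L + unit)
        trials <- simulate_trials(obs, make_test_sequence(seq_seed), trial_seed)
        trials <- cbind(
          data.frame(participant_id = pid, condition = conds[k], session = s,
                     stringsAsFactors = FALSE),
          trials
        )
        chunks[[length(chunks) + 1L]] <- trials
      }
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  attr(out, "parameters") <- params
  out
}

#' Write / read a trial table as CSV
#'
#' The on-disk coding mirrors the finger-report convention of the task:
#' `1` = simultaneous, `2` = successive, empty/NA = no response.
#'
#' @param trials Trial data frame as produced by [simulate_cohort()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a trial data frame with the textual `response` column restored.
#' @export
write_trials <- function(trials, path) {
  req <- c("participant_id", "condition", "session", "trial_index",
           "nominal_soa_ms", "actual_soa_ms", "response")
  if (!all(req %in% names(trials))) {
    stop("trial table is missing columns: ",
         paste(setdiff(req, names(trials)), collapse = ", "), call. = FALSE)
  }
  out <- trials[req]
  out$response <- c(simultaneous = 1L, successive = 2L)[out$response]
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "condition", "session", "trial_index",
           "nominal_soa_ms", "actual_soa_ms", "response")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("malformed trial file '%s': missing columns %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(raw$response %in% c(1L, 2L) | is.na(raw$response)))
  if (length(bad)) {
    stop(sprintf("malformed trial file '%s': invalid response code at line %d",
                 path, bad[1] + 1L), call. = FALSE)
  }
  raw$response <- ifelse(is.na(raw$response), "none",
                         ifelse(raw$response == 1L, "simultaneous", "successive"))
  raw
}
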