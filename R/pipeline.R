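# Pipeline module: end-to-end orchestration from trials (simulated or read
# from CSV) to per-participant TBW indices, condition comparisons,
# correlation analyses and post-hoc power, with a serializable report.

#' Configure a study run
#'
#' @param mode `"simulate"` (generate a cohort from `cohort`) or `"read"`
#'   (load trial CSV files written in the package's trial-table format).
#' @param cohort A [cohort_config()] (simulate mode).
#' @param trial_files Character vector of CSV paths (read mode).
#' @param ratings Optional data frame of perceptual-dimension ratings with
#'   columns `participant_id`, `condition`, `dimension`, `value`; one rating
#'   per participant x condition x dimension.
#' @param window_edges SOA window edges in ms.
#' @param alpha Significance level for all tests.
#' @param session_wise Fit each session separately instead of pooling the
#'   sessions of a participant-condition (default pools, matching rates
#'   computed by condition and by participant).
#' @param out_dir Optional output directory for the JSON report and TSV
#'   tables.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "read"),
                         cohort = cohort_config(),
                         trial_files = NULL,
                         ratings = NULL,
                         window_edges = default_window_edges(),
                         alpha = 0.05,
                         session_wise = FALSE,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "read") {
    if (is.null(trial_files) || !all(file.exists(trial_files))) {
      stop("read mode requires existing `trial_files`", call. = FALSE)
    }
  } else if (!inherits(cohort, "cohort_config")) {
    stop("simulate mode requires a cohort_config", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (!is.null(ratings)) {
    req <- c("participant_id", "condition", "dimension", "value")
    if (!is.data.frame(ratings) || !all(req %in% names(ratings))) {
      stop("`ratings` must have columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(mode = mode, cohort = cohort, trial_files = trial_files,
         ratings = ratings, window_edges = window_edges, alpha = alpha,
         session_wise = session_wise, out_dir = out_dir),
    class = "study_config"
  )
}

# Fit one participant-condition cell; never aborts the pipeline.
fit_cell <- function(trials, edges) {
  sel <- select_trials(trials)
  out <- list(n_total = sel$n_total, n_retained = sel$n_retained,
              adoption_rate = sel$adoption_rate)
  res <- tryCatch({
    binned <- bin_trials(sel, edges)
    fit <- fit_gaussian(binned)
    gof <- goodness_of_fit(binned, fit)
    idx <- tbw_indices(fit, gof)
    list(fit = fit, gof = gof, indices = idx, binned = binned, error = NA_character_)
  }, error = function(e) list(fit = NULL, gof = NA_real_, indices = NULL,
                              binned = NULL, error = conditionMessage(e)))
  c(out, res)
}

#' Run the full SJ analysis pipeline
#'
#' Simulates or reads a trial table; applies trial selection, binning,
#' Gaussian fitting and TBW-index extraction per participant and condition
#' (sessions pooled by default); compares the two conditions with a Wilcoxon
#' signed-rank test, effect sizes r and \eqn{d_z}, and A.R.E.-based post-hoc
#' power; and, when ratings are supplied, runs the same battery on each
#' perceptual dimension plus Spearman correlation tests between each
#' dimension and HWHH across conditions (with exact correlation power).
#' Fit failures for individual participants are recorded and the pipeline
#' continues with complete pairs only.
#'
#' @param config A [study_config()].
#' @return An object of class `sj_study_report` (a nested list); written to
#'   `out_dir` as JSON + TSV when configured.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config")) {
    stop("`config` must be a study_config", call. = FALSE)
  }
  trials <- if (config$mode == "simulate") {
    simulate_cohort(config$cohort)
  } else {
    do.call(rbind, lapply(config$trial_files, read_trials))
  }
  conds <- unique(trials$condition)
  participants <- unique(trials$participant_id)
  edges <- config$window_edges

  # --- per participant x condition fits ------------------------------------
  rows <- list()
  fit_errors <- list()
  binned_tables <- list()
  for (pid in participants) {
    for (cond in conds) {
      sub <- trials[trials$participant_id == pid & trials$condition == cond, ]
      if (nrow(sub) == 0L) next
      units <- if (config$session_wise) split(sub, sub$session) else list(sub)
      for (u in seq_along(units)) {
        cell <- fit_cell(units[[u]], edges)
        label <- if (config$session_wise) {
          sprintf("%s/%s/session%s", pid, cond, names(units)[u])
        } else {
          sprintf("%s/%s", pid, cond)
        }
        if (!is.na(cell$error)) {
          fit_errors[[label]] <- cell$error
          next
        }
        rows[[label]] <- data.frame(
          participant_id = pid, condition = cond,
          session = if (config$session_wise) names(units)[u] else "pooled",
          n_total = cell$n_total, n_retained = cell$n_retained,
          adoption_rate = cell$adoption_rate,
          a = cell$fit$a, b_s = cell$fit$b, c_s = cell$fit$c,
          sse = cell$fit$sse, goodness_of_fit = cell$gof,
          hwhh_s = cell$indices$hwhh_s, fwhh_s = cell$indices$fwhh_s,
          sigma_s = cell$indices$sigma_s,
          width75_s = cell$indices$width75_s,
          jnd75_s = cell$indices$jnd75_s,
          delta50_s = cell$indices$delta50_s,
          stringsAsFactors = FALSE
        )
        if (!is.na(cell$gof) && cell$gof < 0.4) {
          warning(sprintf("low goodness of fit (%.2f) for %s", cell$gof, label))
        }
        binned_tables[[label]] <- cbind(cell = label,
                                        as.data.frame(cell$binned))
      }
    }
  }
  indices <- do.call(rbind, rows)
  rownames(indices) <- NULL

  # --- selection statistics per condition ----------------------------------
  selection <- lapply(conds, function(cond) {
    sub <- trials[trials$condition == cond, ]
    sel <- select_trials(sub)
    list(condition = cond, n_total = sel$n_total,
         n_retained = sel$n_retained, adoption_rate = sel$adoption_rate)
  })
  names(selection) <- conds

  # --- condition comparison on HWHH ----------------------------------------
  comparison <- NULL
  if (length(conds) == 2L && !is.null(indices) && !config$session_wise) {
    wide <- merge(
      indices[indices$condition == conds[1], c("participant_id", "hwhh_s")],
      indices[indices$condition == conds[2], c("participant_id", "hwhh_s")],
      by = "participant_id", suffixes = c("_1", "_2")
    )
    comparison <- tryCatch(
      compare_paired(wide$hwhh_s_1, wide$hwhh_s_2, conds, config$alpha,
                     incomplete = length(participants) - nrow(wide)),
      error = function(e) list(error = conditionMessage(e),
                               n_pairs = nrow(wide)))
  }

  # --- perceptual-dimension analyses ---------------------------------------
  dimensions <- NULL
  if (!is.null(config$ratings) && !is.null(comparison)) {
    hw <- indices[, c("participant_id", "condition", "hwhh_s")]
    dimensions <- lapply(split(config$ratings, config$ratings$dimension),
                         function(rr) {
      wide <- merge(rr[rr$condition == conds[1], c("participant_id", "value")],
                    rr[rr$condition == conds[2], c("participant_id", "value")],
                    by = "participant_id", suffixes = c("_1", "_2"))
      comp <- tryCatch(
        compare_paired(wide$value_1, wide$value_2, conds, config$alpha,
                       incomplete = length(participants) - nrow(wide)),
        error = function(e) list(error = conditionMessage(e)))
      # correlation with HWHH across conditions (participants x conditions)
      m <- merge(rr, hw, by = c("participant_id", "condition"))
      corr <- tryCatch({
        rho <- spearman_rho(m$value, m$hwhh_s)
        ct <- no_correlation_test(rho, nrow(m))
        pw <- power_correlation_exact(rho, nrow(m), config$alpha)
        list(rho = rho, t = ct$t, df = ct$df, p_two_sided = ct$p_two_sided,
             strength = ct$strength_label, n = nrow(m), power = pw$power)
      }, error = function(e) list(error = conditionMessage(e)))
      list(comparison = comp, correlation_with_hwhh = corr)
    })
  }

  report <- structure(
    list(
      provenance = list(
        package = "tbwsj",
        version = as.character(utils::packageVersion("tbwsj")),
        mode = config$mode,
        seed = if (config$mode == "simulate") config$cohort$seed else NA,
        alpha = config$alpha,
        n_trials_input = nrow(trials),
        conditions = conds
      ),
      selection = selection,
      indices = indices,
      fit_errors = fit_errors,
      comparison = comparison,
      dimensions = dimensions
    ),
    class = "sj_study_report"
  )
  attr(report, "binned") <- do.call(rbind, binned_tables)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Full paired battery on one variable: Wilcoxon + ES r + d_z + post-hoc power.
compare_paired <- function(x1, x2, cond_names, alpha, incomplete = 0) {
  w <- wilcoxon_signed_rank(x1, x2)
  n_entered <- 2 * length(x1)  # participants x conditions convention
  ps <- paired_summary(x1, x2)
  dz <- tryCatch(cohens_dz(ps), error = function(e) NA_real_)
  pw <- if (is.finite(dz)) {
    power_wilcoxon_matched(dz, n_entered, alpha)$power
  } else {
    NA_real_
  }
  list(
    condition_1 = cond_names[1], condition_2 = cond_names[2],
    n_pairs = length(x1), n_incomplete_pairs = incomplete,
    mean_1 = ps$mean_1, sd_1 = ps$sd_1,
    mean_2 = ps$mean_2, sd_2 = ps$sd_2,
    rho = ps$rho,
    larger_mean = if (ps$mean_1 >= ps$mean_2) cond_names[1] else cond_names[2],
    W = w$W, z = w$z, p_two_sided = w$p_two_sided, p_exact = w$p_exact,
    effect_size_r = effect_size_r(w$z, n_entered),
    d_z = dz,
    power = pw,
    significant = w$p_two_sided < alpha
  )
}

#' Serialize a study report
#'
#' Writes `report.json` plus TSV companions (`indices.tsv`, `binned_rates.tsv`)
#' for spreadsheet users. Numbers are serialized at fixed precision so that
#' identical runs produce byte-identical files.
#'
#' @param report An `sj_study_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- report_json(report)
  writeLines(json, file.path(out_dir, "report.json"))
  utils::write.table(report$indices, file.path(out_dir, "indices.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  binned <- attr(report, "binned")
  if (!is.null(binned)) {
    utils::write.table(binned, file.path(out_dir, "binned_rates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

# JSON text of a report at fixed precision (determinism of serialized output).
report_json <- function(report) {
  jsonlite::toJSON(unclass(report), digits = 10, auto_unbox = TRUE,
                   na = "null", dataframe = "rows", pretty = TRUE)
}

#' @export
print.sj_study_report <- function(x, ...) {
  cat("SJ study report\n")
  cat(sprintf("  input trials : %d (%s mode)\n",
              x$provenance$n_trials_input, x$provenance$mode))
  for (s in x$selection) {
    cat(sprintf("  %-12s : %d/%d retained (%.1f%%)\n", s$condition,
                s$n_retained, s$n_total, s$adoption_rate))
  }
  if (!is.null(x$comparison) && is.null(x$comparison$error)) {
    cm <- x$comparison
    cat(sprintf("  HWHH %s vs %s: z = %.2f, p = %.4f, r = %.2f, d_z = %.2f, 1-beta = %.2f\n",
                cm$condition_1, cm$condition_2, cm$z, cm$p_two_sided,
                cm$effect_size_r, cm$d_z, cm$power))
    cat(sprintf("  larger mean HWHH: %s\n", cm$larger_mean))
  }
  if (length(x$fit_errors)) {
    cat(sprintf("  fit failures : %d\n", length(x$fit_errors)))
  }
  invisible(x)
}
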