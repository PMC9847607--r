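# Trial-preparation module: the exclusion rules and the conversion of
# retained trials into per-window simultaneous-response rates.

#' Apply the trial-selection rules
#'
#' Excludes trials without a judgment response and trials whose actual SOA is
#' `<= -1000` ms or `> 1000` ms (the boundary is deliberately asymmetric:
#' exactly -1000 is excluded, exactly +1000 is retained). The adoption rate is
#' the percentage of input trials that survive.
#'
#' @param records Data frame of trials with at least `actual_soa_ms` and
#'   `response` (values `"simultaneous"`, `"successive"`, `"none"`; `NA` is
#'   treated as no response).
#' @return An object of class `sj_selection`: list with `retained`,
#'   `n_total`, `n_retained`, `adoption_rate` (percent).
#' @export
select_trials <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a nonempty data frame of trials", call. = FALSE)
  }
  req <- c("actual_soa_ms", "response")
  if (!all(req %in% names(records))) {
    stop("`records` must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  resp <- as.character(records$response)
  resp[is.na(resp)] <- "none"
  if (!all(resp %in% response_levels())) {
    stop("`response` values must be one of: ",
         paste(response_levels(), collapse = ", "), call. = FALSE)
  }
  keep <- resp != "none" &
    records$actual_soa_ms > -1000 &
    records$actual_soa_ms <= 1000
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  structure(
    list(retained = retained,
         n_total = nrow(records),
         n_retained = nrow(retained),
         adoption_rate = 100 * nrow(retained) / nrow(records)),
    class = "sj_selection"
  )
}

#' @export
print.sj_selection <- function(x, ...) {
  cat(sprintf("SJ trial selection: %d / %d retained (adoption rate %.1f%%)\n",
              x$n_retained, x$n_total, x$adoption_rate))
  invisible(x)
}

#' Default SOA window edges
#'
#' 21 contiguous 100-ms windows spanning (-1050, +1050] ms, giving centers
#' -1000, -900, ..., +1000 ms. Windows are lower-open / upper-closed,
#' mirroring the asymmetric exclusion boundary.
#'
#' @return Numeric vector of 22 edges.
#' @export
default_window_edges <- function() {
  seq(-1050, 1050, by = 100)
}

#' Bin retained trials into SOA windows
#'
#' Counts trials and simultaneous responses per window and computes the
#' simultaneous-response rate. Windows are lower-open / upper-closed. Empty
#' windows carry an `NA` rate (0/0 is undefined) and are excluded from
#' downstream fitting rather than imputed.
#'
#' @param selection An `sj_selection` from [select_trials()], or a data frame
#'   of already-retained trials.
#' @param edges Strictly increasing window edges in ms; must cover every
#'   retained actual SOA.
#' @return An object of class `sj_binned`: list with `window_centers_ms`,
#'   `window_edges_ms`, `n_trials`, `n_simultaneous`, `rate`.
#' @export
bin_trials <- function(selection, edges = default_window_edges()) {
  retained <- if (inherits(selection, "sj_selection")) {
    selection$retained
  } else if (is.data.frame(selection)) {
    selection
  } else {
    stop("`selection` must be an sj_selection or a data frame", call. = FALSE)
  }
  if (!is.numeric(edges) || length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("`edges` must be a strictly increasing numeric vector", call. = FALSE)
  }
  x <- retained$actual_soa_ms
  out_of_span <- which(x <= edges[1] | x > edges[length(edges)])
  if (length(out_of_span)) {
    stop(sprintf(
      "retained trial outside window span: row %d (actual SOA %.1f ms)",
      out_of_span[1], x[out_of_span[1]]), call. = FALSE)
  }
  nwin <- length(edges) - 1L
  idx <- findInterval(x, edges, left.open = TRUE, rightmost.closed = FALSE)
  n_trials <- tabulate(idx, nbins = nwin)
  n_sim <- tabulate(idx[retained$response == "simultaneous"], nbins = nwin)
  rate <- ifelse(n_trials > 0, n_sim / n_trials, NA_real_)
  structure(
    list(window_centers_ms = (edges[-1] + edges[-length(edges)]) / 2,
         window_edges_ms = edges,
         n_trials = n_trials,
         n_simultaneous = n_sim,
         rate = rate),
    class = "sj_binned"
  )
}

#' @export
print.sj_binned <- function(x, ...) {
  occ <- sum(x$n_trials > 0)
  cat(sprintf("Binned SJ rates: %d windows (%d occupied), %d trials\n",
              length(x$n_trials), occ, sum(x$n_trials)))
  invisible(x)
}

#' @export
as.data.frame.sj_binned <- function(x, ...) {
  data.frame(
    window_center_ms = x$window_centers_ms,
    n_trials = x$n_trials,
    n_simultaneous = x$n_simultaneous,
    rate = x$rate
  )
}
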