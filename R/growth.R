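# Growth-curve summaries and within-strain inhibition calls.
#
# Optical-density (OD) time series (one reading every 30 min for three days
# in the assay this package targets) are reduced to simple kinetic summaries.
# Because inocula were not standardized across strains, comparisons are only
# meaningful within a strain (control vs oxidant-treated); the report layer
# therefore only ever contrasts treatments of the same strain.

#' Kinetic summaries of one growth curve
#'
#' Computes, from a single OD time series:
#' * `delta_od`: plateau rise, `max(od) - baseline`, clipped at 0; the
#'   baseline is the mean of the first `baseline_n` readings (no plate blank
#'   is assumed).
#' * `auc`: trapezoidal area under the baseline-subtracted (and
#'   zero-clipped) curve, in OD·h.
#' * `mu_max`: maximum specific growth rate (per hour), the largest
#'   least-squares slope of `log(od - baseline + eps)` over sliding windows
#'   of `window` consecutive points. Only windows lying entirely in the
#'   growth region (baseline-subtracted OD at or above `rise_threshold` at
#'   every point) are eligible: near the baseline the log signal is dominated
#'   by read noise and the raw maximum diverges. `NA` when no window is
#'   eligible.
#' * `lag`: earliest time at which the baseline-subtracted OD reaches
#'   `rise_threshold`; `NA` when the curve never rises (no growth).
#' * `growth_call`: `TRUE` when `delta_od >= rise_threshold`.
#'
#' @param times Strictly increasing times, hours.
#' @param od OD readings, same length as `times` (>= 10 points).
#' @param baseline_n Readings averaged for the baseline (default 3).
#' @param eps Offset inside the log (default 1e-3).
#' @param rise_threshold OD rise that counts as growth (default 0.05).
#' @param window Sliding-window width in points (default 5).
#' @return A one-row data frame with columns `delta_od`, `auc`, `mu_max`,
#'   `lag`, `growth_call`.
#' @export
growth_metrics <- function(times, od, baseline_n = 3, eps = 1e-3,
                           rise_threshold = 0.05, window = 5) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  n <- length(times)
  if (n != length(od)) {
    gnotostat_error("gnotostat_invalid_curve",
                    "times and od must have the same length")
  }
  if (n < max(10L, window)) {
    gnotostat_error("gnotostat_invalid_curve",
                    sprintf("need at least %d points, got %d", max(10L, window), n))
  }
  if (any(!is.finite(od)) || any(!is.finite(times)) || any(diff(times) <= 0)) {
    gnotostat_error("gnotostat_invalid_curve",
                    "times must be strictly increasing and od finite")
  }
  baseline <- mean(od[seq_len(min(baseline_n, n))])
  y <- pmax(od - baseline, 0)
  delta_od <- max(y)
  auc <- sum(diff(times) * (y[-1] + y[-n]) / 2)
  growth_call <- delta_od >= rise_threshold

  # Sliding-window slopes of log signal; eligibility = whole window in the
  # growth region.
  ly <- log(y + eps)
  w <- as.integer(window)
  nw <- n - w + 1L
  mu_max <- NA_real_
  if (nw >= 1L) {
    tm <- stats::embed(times, w)[, w:1, drop = FALSE]
    ym <- stats::embed(ly, w)[, w:1, drop = FALSE]
    tc <- tm - rowMeans(tm)
    slopes <- rowSums(tc * ym) / rowSums(tc^2)
    eligible <- rowSums(stats::embed(y, w) >= rise_threshold) == w
    if (any(eligible)) mu_max <- max(slopes[eligible])
  }
  lag <- if (growth_call) times[which(y >= rise_threshold)[1L]] else NA_real_
  data.frame(delta_od = delta_od, auc = auc, mu_max = mu_max, lag = lag,
             growth_call = growth_call)
}

#' Within-strain inhibition call
#'
#' Compares treated vs control kinetic summaries of the same strain:
#' * `no_growth_under_h2o2` when the control grows but the treated curve does
#'   not rise at all;
#' * `unaffected` when the inhibition index is at most 0.1;
#' * `reduced_growth` otherwise.
#'
#' The inhibition index is `1 - treated_auc / control_auc`, clipped to
#' \[0, 1\].
#'
#' @param control,treated One-row metric frames from [growth_metrics()] for
#'   the same strain.
#' @return A list with `call` and `inhibition_index`.
#' @export
inhibition_call <- function(control, treated) {
  if (!isTRUE(control$growth_call)) {
    gnotostat_error("gnotostat_no_reference_growth",
                    "control curve shows no growth; within-strain comparison undefined")
  }
  idx <- 1 - treated$auc / control$auc
  idx <- min(max(idx, 0), 1)
  call <- if (!isTRUE(treated$growth_call)) {
    "no_growth_under_h2o2"
  } else if (idx <= 0.1) {
    "unaffected"
  } else {
    "reduced_growth"
  }
  list(call = call, inhibition_index = idx)
}

#' Growth analysis of a long-format OD table
#'
#' Computes per-curve kinetic summaries for every strain x treatment x
#' replicate series and, for each strain with both treatments, the
#' within-strain inhibition call on the replicate-averaged curves (replicates
#' share the plate's time grid and are averaged pointwise, mirroring how such
#' assays are usually reported).
#'
#' @param od_data Data frame with columns `time_h`, `strain`, `treatment`
#'   (`"control"` or `"h2o2"`), `replicate`, `od`.
#' @param ... Passed to [growth_metrics()].
#' @return A list with `metrics` (per-curve summaries) and `calls` (one row
#'   per strain: `call`, `inhibition_index`).
#' @export
growth_analysis <- function(od_data, ...) {
  od_data <- validate_input(od_data, "growth")
  key <- interaction(od_data$strain, od_data$treatment, od_data$replicate,
                     drop = TRUE, lex.order = TRUE)
  metrics <- do.call(rbind, lapply(split(od_data, key), function(s) {
    s <- s[order(s$time_h), , drop = FALSE]
    cbind(
      data.frame(strain = s$strain[1L], treatment = s$treatment[1L],
                 replicate = s$replicate[1L], stringsAsFactors = FALSE),
      growth_metrics(s$time_h, s$od, ...)
    )
  }))
  rownames(metrics) <- NULL

  mean_curve <- function(s) {
    agg <- stats::aggregate(od ~ time_h, data = s, FUN = mean)
    agg[order(agg$time_h), , drop = FALSE]
  }
  calls <- list()
  for (st in unique(od_data$strain)) {
    s <- od_data[od_data$strain == st, , drop = FALSE]
    if (!all(c("control", "h2o2") %in% unique(s$treatment))) next
    ctrl <- mean_curve(s[s$treatment == "control", , drop = FALSE])
    trt <- mean_curve(s[s$treatment == "h2o2", , drop = FALSE])
    mc <- growth_metrics(ctrl$time_h, ctrl$od, ...)
    mt <- growth_metrics(trt$time_h, trt$od, ...)
    ic <- inhibition_call(mc, mt)
    calls[[length(calls) + 1L]] <- data.frame(
      strain = st, call = ic$call, inhibition_index = ic$inhibition_index,
      stringsAsFactors = FALSE
    )
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(strain = character(), call = character(),
               inhibition_index = numeric(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(metrics = metrics, calls = calls)
}
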