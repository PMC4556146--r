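# Relative persistence and clearance statistics.
#
# The persistence statistic compares a test yeast's abundance in the fly gut
# to the S. cerevisiae reference fed in parallel vials. For test-yeast
# replicate X at time t:
#
#   ratio_X(t) = [TY_X(t) / mean(SC(t))] / [TY_X(0) / mean(SC(0))]
#
# Test-yeast replicates pair with their own time-0 value (same vial); the
# reference arm enters only as the average of its replicates, because the two
# arms' replicates are unrelated vials. A ratio above 1 means the test yeast
# is retained relative to the reference; below 1, removed. One historical
# experiment lacked usable time-0 counts (all plates confluent), for which a
# unit (1:1) normalization replaces the time-0 divisor.

#' Per-replicate relative persistence ratios
#'
#' @param ty_t Test-yeast CFU/fly per replicate at time t.
#' @param sc_t Reference (S. cerevisiae) CFU/fly per replicate at time t;
#'   averaged, not paired.
#' @param ty_0,sc_0 The same quantities at time 0. Required under
#'   `normalization = "time0"`; ignored under `"unit"`.
#' @param normalization `"time0"` (divide by each replicate's time-0 ratio) or
#'   `"unit"` (divisor 1, the fallback when time-0 data are unusable).
#' @return Numeric vector of normalized ratios, one per test-yeast replicate.
#' @export
#' @examples
#' relative_persistence(c(2000, 1000, 1500), sc_t = c(400, 500, 600),
#'                      ty_0 = rep(10000, 3), sc_0 = rep(10000, 3))
relative_persistence <- function(ty_t, sc_t, ty_0 = NULL, sc_0 = NULL,
                                 normalization = c("time0", "unit")) {
  normalization <- match.arg(normalization)
  ty_t <- as.numeric(ty_t)
  sc_t <- as.numeric(sc_t)
  if (length(ty_t) == 0L || length(sc_t) == 0L) {
    gnotostat_error("gnotostat_invalid_ratio_input",
                    "ty_t and sc_t must be non-empty")
  }
  if (any(ty_t < 0) || any(sc_t < 0)) {
    gnotostat_error("gnotostat_invalid_ratio_input", "CFU values must be >= 0")
  }
  if (mean(sc_t) == 0) {
    gnotostat_error("gnotostat_zero_reference",
                    "mean reference abundance at time t is 0; apply a zero substitute upstream")
  }
  raw <- ty_t / mean(sc_t)
  if (normalization == "unit") return(raw)
  if (is.null(ty_0) || is.null(sc_0)) {
    gnotostat_error("gnotostat_invalid_ratio_input",
                    "time0 normalization requires ty_0 and sc_0")
  }
  ty_0 <- as.numeric(ty_0)
  sc_0 <- as.numeric(sc_0)
  if (length(ty_0) != length(ty_t)) {
    gnotostat_error("gnotostat_invalid_ratio_input",
                    "ty_0 must pair replicate-wise with ty_t")
  }
  if (mean(sc_0) == 0 || any(ty_0 == 0)) {
    gnotostat_error("gnotostat_zero_reference",
                    "zero time-0 abundance; apply a zero substitute upstream or use unit normalization")
  }
  raw / (ty_0 / mean(sc_0))
}

#' Confidence interval for a mean ratio
#'
#' Two constructions for an interval around the central ratio of a small set
#' of positive per-replicate ratios:
#' * `log_t`: Student-t interval on natural-log ratios, back-transformed
#'   (interval for the geometric mean; assumes multiplicative noise).
#' * `bootstrap_percentile`: percentile interval of the resampled arithmetic
#'   mean, `B` resamples with replacement, inverse-CDF (type 1) quantiles.
#'
#' All requested levels are computed from one resample set, so wider levels
#' always contain narrower ones.
#'
#' @param ratios Numeric vector (length >= 2) of ratios; strictly positive for
#'   `log_t`.
#' @param level Confidence level(s) in (0, 1); may be a vector.
#' @param method `"log_t"` or `"bootstrap_percentile"`.
#' @param B Bootstrap resample count (default 10000).
#' @param seed Optional integer seed for the bootstrap (local to the call).
#' @return A data frame with columns `level`, `lower`, `upper`.
#' @export
#' @examples
#' persistence_ci(c(4, 2, 3), level = c(0.95, 0.99, 0.999))
persistence_ci <- function(ratios, level = 0.95,
                           method = c("log_t", "bootstrap_percentile"),
                           B = 10000, seed = NULL) {
  method <- match.arg(method)
  ratios <- as.numeric(ratios)
  if (length(ratios) < 2L) {
    gnotostat_error("gnotostat_too_few_replicates",
                    "need at least 2 ratios for a confidence interval")
  }
  if (any(!is.finite(ratios)) || any(ratios < 0)) {
    gnotostat_error("gnotostat_invalid_ratio_input",
                    "ratios must be finite and non-negative")
  }
  level <- sort(as.numeric(level))
  if (any(level <= 0) || any(level >= 1)) {
    gnotostat_error("gnotostat_invalid_level", "levels must lie in (0, 1)")
  }
  n <- length(ratios)
  if (method == "log_t") {
    if (any(ratios == 0)) {
      gnotostat_error("gnotostat_zero_reference",
                      "log_t requires strictly positive ratios; apply a zero substitute upstream")
    }
    lr <- log(ratios)
    m <- mean(lr)
    se <- stats::sd(lr) / sqrt(n)
    hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se
    data.frame(level = level, lower = exp(m - hw), upper = exp(m + hw))
  } else {
    means <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
      rowMeans(matrix(ratios[idx], nrow = B))
    })
    lo <- stats::quantile(means, (1 - level) / 2, type = 1, names = FALSE)
    hi <- stats::quantile(means, 1 - (1 - level) / 2, type = 1, names = FALSE)
    data.frame(level = level, lower = lo, upper = hi)
  }
}

#' Classify persistence from nested confidence intervals
#'
#' Persistence calls follow the most stringent confidence level whose interval
#' excludes 1: lower bound above 1 at level L gives "Persists at L", upper
#' bound below 1 gives "Removed at L"; if even the least stringent interval
#' contains 1 the call is "No change".
#'
#' @param ci Data frame with columns `level`, `lower`, `upper` (as returned by
#'   [persistence_ci()]), one row per level; levels need not be sorted but the
#'   intervals must be nested (wider level contains narrower).
#' @param null_value The no-change value the intervals are tested against
#'   (default 1).
#' @return A list with `classification` (`"persists"`, `"removed"`,
#'   `"no_change"`), `level` (the level attained, `NA` for no change) and
#'   `label` (the table vocabulary, e.g. `"Persists at 99.9%"`).
#' @export
classify_persistence <- function(ci, null_value = 1) {
  classify_by_null(ci, null_value,
                   above = "Persists", below = "Removed",
                   none = "No change",
                   class_above = "persists", class_below = "removed",
                   class_none = "no_change")
}

# Shared classifier: most stringent level whose interval excludes `null_value`.
classify_by_null <- function(ci, null_value, above, below, none,
                             class_above, class_below, class_none) {
  stopifnot(all(c("level", "lower", "upper") %in% names(ci)))
  ci <- ci[order(ci$level), , drop = FALSE]
  if (any(ci$lower > ci$upper)) {
    gnotostat_error("gnotostat_invalid_ci", "interval has lower > upper")
  }
  if (nrow(ci) > 1L) {
    nested <- all(diff(ci$lower) <= 1e-12) && all(diff(ci$upper) >= -1e-12)
    if (!nested) {
      gnotostat_error("gnotostat_non_nested_ci",
                      "intervals are not nested across levels (upstream bug)")
    }
  }
  excl_above <- ci$lower > null_value
  excl_below <- ci$upper < null_value
  if (any(excl_above)) {
    lev <- max(ci$level[excl_above])
    list(classification = class_above, level = lev,
         label = sprintf("%s at %s", above, format_level(lev)))
  } else if (any(excl_below)) {
    lev <- max(ci$level[excl_below])
    list(classification = class_below, level = lev,
         label = sprintf("%s at %s", below, format_level(lev)))
  } else {
    list(classification = class_none, level = NA_real_, label = none)
  }
}

#' Fold-clearance between two timepoints
#'
#' Ratio of mean absolute abundance at the earlier timepoint to the mean at
#' the later timepoint, across the replicates of one treatment: 1 means
#' unchanged, 10 means ten-fold fewer CFU at the later time.
#'
#' @param abundances_start CFU/fly per replicate at the earlier timepoint.
#' @param abundances_end CFU/fly per replicate at the later timepoint.
#' @return A single fold-decrease ratio.
#' @export
clearance_ratio <- function(abundances_start, abundances_end) {
  s <- as.numeric(abundances_start)
  e <- as.numeric(abundances_end)
  if (length(s) == 0L || length(e) == 0L) {
    gnotostat_error("gnotostat_invalid_ratio_input",
                    "both timepoints need at least one replicate")
  }
  if (mean(e) == 0) {
    gnotostat_error(
      "gnotostat_zero_reference",
      "mean abundance at the later timepoint is 0; report a detection-limit bound instead"
    )
  }
  mean(s) / mean(e)
}

#' Cross-experiment average of clearance ratios
#'
#' Arithmetic mean of per-experiment fold-clearance ratios for one time
#' interval, rounded half-up to the report precision.
#'
#' @param ratios Numeric vector of per-experiment clearance ratios.
#' @param digits Decimal places for the reported average (default 1); `NULL`
#'   for no rounding.
#' @return The (optionally rounded) mean ratio.
#' @export
#' @examples
#' clearance_summary(c(7.9, 11.2, 24.0, 7.6, 23.3))  # 14.8
clearance_summary <- function(ratios, digits = 1) {
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L || any(!is.finite(ratios))) {
    gnotostat_error("gnotostat_invalid_ratio_input",
                    "ratios must be a non-empty finite vector")
  }
  m <- mean(ratios)
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Persistence analysis of an abundance table
#'
#' Runs the full relative-persistence analysis per experiment and post-zero
#' timepoint: per-replicate normalized ratios, point estimates (geometric mean
#' under `log_t`, arithmetic under the bootstrap; both reported), confidence
#' intervals at all requested levels, and the persists/removed/no-change call.
#'
#' @param abundances Abundance data frame (see [quantify_cfu()]) containing
#'   `test_yeast` and `s_cerevisiae` treatments.
#' @param levels Confidence levels (default 0.95, 0.99, 0.999).
#' @param ci_method `"log_t"` (default) or `"bootstrap_percentile"`.
#' @param normalization `"time0"` (default) or `"unit"` per experiment; may be
#'   a named character vector keyed by experiment to mix conventions (e.g. the
#'   unit fallback for one experiment with unusable time-0 plates).
#' @param B,seed Bootstrap controls, see [persistence_ci()].
#' @return Data frame, one row per experiment x timepoint, with columns
#'   `experiment`, `timepoint_h`, `n_replicates`, `geometric_mean`,
#'   `arithmetic_mean`, `point_estimate`, per-level `ci<level>_lo`/`_hi`,
#'   `classification`, `label`, `ci_method`, and a list column `ratios`.
#' @export
persistence_analysis <- function(abundances, levels = c(0.95, 0.99, 0.999),
                                 ci_method = c("log_t", "bootstrap_percentile"),
                                 normalization = "time0", B = 10000,
                                 seed = NULL) {
  ci_method <- match.arg(ci_method)
  abundances <- validate_input(abundances, "abundance")
  rows <- list()
  for (exp_id in unique(abundances$experiment)) {
    a <- abundances[abundances$experiment == exp_id, , drop = FALSE]
    norm <- if (length(normalization) > 1L || !is.null(names(normalization))) {
      if (exp_id %in% names(normalization)) normalization[[exp_id]] else "time0"
    } else {
      normalization
    }
    ty0 <- a$cfu_per_fly[a$treatment == "test_yeast" & a$timepoint_h == 0]
    sc0 <- a$cfu_per_fly[a$treatment == "s_cerevisiae" & a$timepoint_h == 0]
    tps <- sort(unique(a$timepoint_h[a$timepoint_h > 0]))
    for (tp in tps) {
      ty_rows <- a[a$treatment == "test_yeast" & a$timepoint_h == tp, ,
                   drop = FALSE]
      ty_rows <- ty_rows[order(ty_rows$replicate), , drop = FALSE]
      sc_t <- a$cfu_per_fly[a$treatment == "s_cerevisiae" & a$timepoint_h == tp]
      if (nrow(ty_rows) == 0L || length(sc_t) == 0L) next
      ratios <- if (norm == "unit") {
        relative_persistence(ty_rows$cfu_per_fly, sc_t, normalization = "unit")
      } else {
        relative_persistence(ty_rows$cfu_per_fly, sc_t, ty_0 = ty0, sc_0 = sc0)
      }
      ci <- persistence_ci(ratios, level = levels, method = ci_method, B = B,
                           seed = if (is.null(seed)) NULL
                                  else substream_seed(seed, tp))
      cls <- classify_persistence(ci)
      gm <- exp(mean(log(ratios)))
      am <- mean(ratios)
      row <- data.frame(
        experiment = exp_id, timepoint_h = tp, n_replicates = length(ratios),
        geometric_mean = gm, arithmetic_mean = am,
        point_estimate = if (ci_method == "log_t") gm else am,
        stringsAsFactors = FALSE
      )
      for (i in seq_len(nrow(ci))) {
        lv <- gsub("[.%]", "", format_level(ci$level[i]))
        row[[paste0("ci", lv, "_lo")]] <- ci$lower[i]
        row[[paste0("ci", lv, "_hi")]] <- ci$upper[i]
      }
      row$classification <- cls$classification
      row$label <- cls$label
      row$ci_method <- ci_method
      row$ratios <- I(list(ratios))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    gnotostat_error("gnotostat_no_data",
                    "no experiment had test-yeast and reference records at a shared post-zero timepoint")
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Clearance table across timepoint intervals
#'
#' Per experiment and treatment, the fold-clearance ratio between each pair of
#' consecutive timepoints, plus cross-experiment averages for the test-yeast
#' and reference arms (test-yeast average excludes the reference by
#' construction).
#'
#' @param abundances Abundance data frame (see [quantify_cfu()]).
#' @param treatments Treatments to tabulate (default test yeast and
#'   reference).
#' @return A list with `entries` (data frame: `experiment`, `treatment`,
#'   `t_start`, `t_end`, `ratio`) and `summary` (data frame: `interval`,
#'   `treatment`, `mean_ratio` rounded half-up to one decimal).
#' @export
clearance_table <- function(abundances,
                            treatments = c("test_yeast", "s_cerevisiae")) {
  abundances <- validate_input(abundances, "abundance")
  entries <- list()
  for (exp_id in unique(abundances$experiment)) {
    for (tr in treatments) {
      a <- abundances[abundances$experiment == exp_id &
                        abundances$treatment == tr, , drop = FALSE]
      tps <- sort(unique(a$timepoint_h))
      if (length(tps) < 2L) next
      for (i in seq_len(length(tps) - 1L)) {
        s <- a$cfu_per_fly[a$timepoint_h == tps[i]]
        e <- a$cfu_per_fly[a$timepoint_h == tps[i + 1L]]
        if (mean(e) == 0) next  # detection-limit bounded; not tabulated
        entries[[length(entries) + 1L]] <- data.frame(
          experiment = exp_id, treatment = tr,
          t_start = tps[i], t_end = tps[i + 1L],
          ratio = clearance_ratio(s, e), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(entries) == 0L) {
    gnotostat_error("gnotostat_no_data", "no clearance intervals computable")
  }
  entries <- do.call(rbind, entries)
  rownames(entries) <- NULL
  key <- unique(entries[, c("t_start", "t_end", "treatment")])
  summary <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- entries$t_start == key$t_start[i] & entries$t_end == key$t_end[i] &
      entries$treatment == key$treatment[i]
    data.frame(
      interval = sprintf("%g-%g", key$t_start[i], key$t_end[i]),
      treatment = key$treatment[i],
      mean_ratio = clearance_summary(entries$ratio[sel]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary) <- NULL
  list(entries = entries, summary = summary)
}
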