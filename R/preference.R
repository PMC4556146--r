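# Two-choice feeding preference from dyed abdomen counts.
#
# Flies choose between two dye-labeled yeast patches; abdomens are scored
# red, blue, purple (fed on both) or empty (did not feed). The preference
# index (PI) credits purple flies half to each option:
#
#   PI = (n_focal + n_purple / 2) / (n_red + n_blue + n_purple)
#
# PI = 0.5 means no preference. Choice treatments are run under both dye
# assignments (test yeast blue, then red) to separate yeast preference from
# dye preference; no-choice controls (same yeast in both colors) flag dye
# bias directly.

#' Preference index from abdomen-color counts
#'
#' @param n_red,n_blue,n_purple Counts of red, blue and purple (doubly fed)
#'   abdomens.
#' @param focal_color `"blue"` or `"red"`: the color toward which the index is
#'   oriented (the test yeast's dye in choice treatments; blue in controls).
#' @return PI in \[0, 1\].
#' @export
#' @examples
#' preference_index(10, 30, 0, focal_color = "blue")  # 0.75
preference_index <- function(n_red, n_blue, n_purple,
                             focal_color = c("blue", "red")) {
  focal_color <- match.arg(focal_color)
  counts <- c(n_red, n_blue, n_purple)
  if (any(counts < 0) || any(counts != floor(counts))) {
    gnotostat_error("gnotostat_invalid_counts",
                    "abdomen counts must be non-negative integers")
  }
  fed <- n_red + n_blue + n_purple
  if (fed == 0) {
    gnotostat_error("gnotostat_no_flies_fed",
                    "no flies fed in this replicate; exclude it from inference")
  }
  n_focal <- if (focal_color == "blue") n_blue else n_red
  (n_focal + n_purple / 2) / fed
}

#' Fraction of flies that fed
#'
#' @inheritParams preference_index
#' @param n_empty Count of empty (unfed) abdomens.
#' @return Fraction in \[0, 1\] of flies with any dye in the abdomen.
#' @export
feeding_rate <- function(n_red, n_blue, n_purple, n_empty) {
  counts <- c(n_red, n_blue, n_purple, n_empty)
  if (any(counts < 0) || any(counts != floor(counts))) {
    gnotostat_error("gnotostat_invalid_counts",
                    "abdomen counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total == 0) {
    gnotostat_error("gnotostat_invalid_counts", "all counts are zero")
  }
  (n_red + n_blue + n_purple) / total
}

#' Confidence interval for the mean preference index
#'
#' `t_linear` is a Student-t interval on the per-replicate PI values,
#' truncated to \[0, 1\]; `bootstrap_percentile` resamples the replicate mean
#' as in [persistence_ci()].
#'
#' @param pi_values Per-replicate PI values (length >= 2).
#' @param level Confidence level(s) in (0, 1).
#' @param method `"t_linear"` or `"bootstrap_percentile"`.
#' @param B,seed Bootstrap controls.
#' @return Data frame with columns `level`, `lower`, `upper`.
#' @export
preference_ci <- function(pi_values, level = 0.95,
                          method = c("t_linear", "bootstrap_percentile"),
                          B = 10000, seed = NULL) {
  method <- match.arg(method)
  pi_values <- as.numeric(pi_values)
  if (length(pi_values) < 2L) {
    gnotostat_error("gnotostat_too_few_replicates",
                    "need at least 2 usable replicates")
  }
  if (any(!is.finite(pi_values)) || any(pi_values < 0) || any(pi_values > 1)) {
    gnotostat_error("gnotostat_invalid_counts", "PI values must lie in [0, 1]")
  }
  level <- sort(as.numeric(level))
  if (any(level <= 0) || any(level >= 1)) {
    gnotostat_error("gnotostat_invalid_level", "levels must lie in (0, 1)")
  }
  if (method == "t_linear") {
    n <- length(pi_values)
    m <- mean(pi_values)
    se <- stats::sd(pi_values) / sqrt(n)
    hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se
    data.frame(level = level, lower = pmax(m - hw, 0), upper = pmin(m + hw, 1))
  } else {
    ci <- persistence_ci(pi_values, level = level,
                         method = "bootstrap_percentile", B = B, seed = seed)
    ci$lower <- pmax(ci$lower, 0)
    ci$upper <- pmin(ci$upper, 1)
    ci
  }
}

#' Classify a preference result against the no-preference value 0.5
#'
#' Reports the most stringent confidence level whose interval excludes 0.5:
#' lower bound above 0.5 gives `prefers_focal` ("Prefers <focal> at L"),
#' upper bound below 0.5 gives `prefers_other`; otherwise `no_preference`
#' ("No preference").
#'
#' @param ci Data frame with `level`, `lower`, `upper` rows (nested).
#' @param focal_name,other_name Names used in the label (e.g. the test
#'   yeast's abbreviation and `"SC"`, or `"blue"`/`"red"` for controls).
#' @return List with `classification`, `level`, `label`.
#' @export
classify_preference <- function(ci, focal_name = "focal", other_name = "other") {
  out <- classify_by_null(
    ci, 0.5,
    above = sprintf("Prefers %s", focal_name),
    below = sprintf("Prefers %s", other_name),
    none = "No preference",
    class_above = "prefers_focal", class_below = "prefers_other",
    class_none = "no_preference"
  )
  out
}

#' Reconcile dye-swapped choice treatments into one verdict
#'
#' A yeast is called `preferred` only when it is preferred under both dye
#' assignments (any confidence level), `not_preferred` when neither swap shows
#' preference for it, and `inconsistent` when the swaps disagree. When a
#' no-choice control itself shows a color preference, the additional
#' `dye_confounded` flag is raised.
#'
#' @param class_ty_blue,class_ty_red Classification lists (from
#'   [classify_preference()]) for the treatments with the test yeast labeled
#'   blue and red.
#' @param control_classes Optional list of classification lists for the
#'   no-choice controls.
#' @return List with `verdict`, `dye_confounded` (logical) and `narrative`.
#' @export
dye_swap_verdict <- function(class_ty_blue, class_ty_red,
                             control_classes = list()) {
  if (is.null(class_ty_blue) || is.null(class_ty_red)) {
    gnotostat_error("gnotostat_missing_treatment",
                    "both dye-swap treatments are required for a verdict")
  }
  b <- class_ty_blue$classification
  r <- class_ty_red$classification
  verdict <- if (b == "prefers_focal" && r == "prefers_focal") {
    "preferred"
  } else if (b != "prefers_focal" && r != "prefers_focal") {
    "not_preferred"
  } else {
    "inconsistent"
  }
  confounded <- any(vapply(control_classes,
                           function(cl) cl$classification != "no_preference",
                           logical(1)))
  narrative <- sprintf(
    "labeled blue: %s; labeled red: %s; verdict: %s%s",
    class_ty_blue$label, class_ty_red$label, verdict,
    if (confounded) " (dye-confounded: a no-choice control shows a color preference)" else ""
  )
  list(verdict = verdict, dye_confounded = confounded, narrative = narrative)
}

#' Preference analysis of a choice-count table
#'
#' For every experiment x treatment: per-replicate PIs (replicates in which no
#' fly fed are excluded with a warning), the replicate-mean and pooled-count
#' PIs (the latter applies the index to counts summed across replicates; the
#' two differ when replicate denominators differ), feeding rates, confidence
#' intervals at all requested levels, and the classification against 0.5.
#' Choice treatments (`ty_blue`, `ty_red`) orient the index toward the test
#' yeast whatever its dye; no-choice controls (`sc_control`, `ty_control`)
#' orient it toward blue so a dye bias reads as PI away from 0.5. Experiments
#' with both swap treatments also get a dye-swap verdict.
#'
#' @param counts Data frame with columns `experiment`, `treatment` (one of
#'   `sc_control`, `ty_control`, `ty_blue`, `ty_red`), `replicate`, `n_red`,
#'   `n_blue`, `n_purple`, `n_empty`.
#' @param levels Confidence levels (default 0.95, 0.99, 0.999).
#' @param ci_method `"t_linear"` (default) or `"bootstrap_percentile"`.
#' @param B,seed Bootstrap controls.
#' @param focal_name,other_name Label names for the test yeast and the
#'   reference (defaults `"TY"` and `"SC"`).
#' @return List with `results` (per-treatment data frame) and `verdicts`
#'   (per-experiment data frame with `verdict`, `dye_confounded`,
#'   `narrative`).
#' @export
preference_analysis <- function(counts, levels = c(0.95, 0.99, 0.999),
                                ci_method = c("t_linear", "bootstrap_percentile"),
                                B = 10000, seed = NULL,
                                focal_name = "TY", other_name = "SC") {
  ci_method <- match.arg(ci_method)
  counts <- validate_input(counts, "choice")
  focal_color_of <- c(sc_control = "blue", ty_control = "blue",
                      ty_blue = "blue", ty_red = "red")
  results <- list()
  class_by_key <- list()
  for (exp_id in unique(counts$experiment)) {
    for (tr in unique(counts$treatment[counts$experiment == exp_id])) {
      s <- counts[counts$experiment == exp_id & counts$treatment == tr, ,
                  drop = FALSE]
      s <- s[order(s$replicate), , drop = FALSE]
      fed <- s$n_red + s$n_blue + s$n_purple
      if (any(fed == 0)) {
        warning(sprintf(
          "%s/%s: excluding %d replicate(s) with no fed flies from inference",
          exp_id, tr, sum(fed == 0)
        ), call. = FALSE)
      }
      u <- s[fed > 0, , drop = FALSE]
      fc <- focal_color_of[[tr]]
      pis <- mapply(preference_index, u$n_red, u$n_blue, u$n_purple,
                    MoreArgs = list(focal_color = fc))
      pooled <- preference_index(sum(u$n_red), sum(u$n_blue), sum(u$n_purple),
                                 focal_color = fc)
      frate <- feeding_rate(sum(s$n_red), sum(s$n_blue), sum(s$n_purple),
                            sum(s$n_empty))
      is_control <- tr %in% c("sc_control", "ty_control")
      fn <- if (is_control) "blue" else focal_name
      on <- if (is_control) "red" else other_name
      if (length(pis) >= 2L) {
        ci <- preference_ci(pis, level = levels, method = ci_method, B = B,
                            seed = if (is.null(seed)) NULL
                                   else substream_seed(seed, sum(utf8ToInt(tr))))
        cls <- classify_preference(ci, focal_name = fn, other_name = on)
      } else {
        ci <- data.frame(level = sort(levels), lower = NA_real_,
                         upper = NA_real_)
        cls <- list(classification = NA_character_, level = NA_real_,
                    label = NA_character_)
      }
      row <- data.frame(
        experiment = exp_id, treatment = tr, focal_color = fc,
        n_replicates = length(pis), pi_mean = mean(pis), pi_pooled = pooled,
        feeding_rate = frate, stringsAsFactors = FALSE
      )
      for (i in seq_len(nrow(ci))) {
        lv <- gsub("[.%]", "", format_level(ci$level[i]))
        row[[paste0("ci", lv, "_lo")]] <- ci$lower[i]
        row[[paste0("ci", lv, "_hi")]] <- ci$upper[i]
      }
      row$classification <- cls$classification
      row$label <- cls$label
      row$pi_by_replicate <- I(list(pis))
      results[[length(results) + 1L]] <- row
      class_by_key[[paste(exp_id, tr, sep = "\r")]] <- cls
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  verdicts <- list()
  for (exp_id in unique(results$experiment)) {
    kb <- class_by_key[[paste(exp_id, "ty_blue", sep = "\r")]]
    kr <- class_by_key[[paste(exp_id, "ty_red", sep = "\r")]]
    if (is.null(kb) || is.null(kr) ||
        is.na(kb$classification) || is.na(kr$classification)) next
    ctrls <- Filter(Negate(is.null), list(
      class_by_key[[paste(exp_id, "sc_control", sep = "\r")]],
      class_by_key[[paste(exp_id, "ty_control", sep = "\r")]]
    ))
    v <- dye_swap_verdict(kb, kr, ctrls)
    verdicts[[length(verdicts) + 1L]] <- data.frame(
      experiment = exp_id, verdict = v$verdict,
      dye_confounded = v$dye_confounded, narrative = v$narrative,
      stringsAsFactors = FALSE
    )
  }
  verdicts <- if (length(verdicts)) do.call(rbind, verdicts) else
    data.frame(experiment = character(), verdict = character(),
               dye_confounded = logical(), narrative = character(),
               stringsAsFactors = FALSE)
  rownames(verdicts) <- NULL
  list(results = results, verdicts = verdicts)
}
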