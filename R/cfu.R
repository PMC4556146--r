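# CFU quantification from serial-dilution plate counts.
#
# A homogenate of pooled fly guts is carried through a serial dilution
# (fractions of the original concentration, e.g. 1, 1/10, 1/100, 1/1000) and a
# fixed aliquot of each dilution is plated. Plates too dense to resolve
# individual colonies are recorded with the literal marker "CONFLUENT". The
# most concentrated countable plate is used for quantification.

CONFLUENT <- "CONFLUENT"

# Parse a count vector that may mix non-negative integers with the CONFLUENT
# marker. Returns list(count = numeric with NA at confluent entries,
# confluent = logical).
parse_counts <- function(counts, max_countable = NULL) {
  x <- trimws(as.character(counts))
  confluent <- toupper(x) == CONFLUENT
  n <- suppressWarnings(as.numeric(x))
  bad <- !confluent & (is.na(n) | n < 0 | n != floor(n))
  if (any(bad)) {
    gnotostat_error(
      "gnotostat_invalid_count",
      sprintf(
        "counts must be non-negative integers or \"CONFLUENT\"; offending value(s): %s",
        paste(unique(x[bad]), collapse = ", ")
      )
    )
  }
  if (!is.null(max_countable)) {
    confluent <- confluent | (!is.na(n) & n > max_countable)
  }
  n[confluent] <- NA_real_
  list(count = n, confluent = confluent)
}

#' Select the countable dilution of a serial-dilution series
#'
#' Chooses the most concentrated (largest) dilution factor whose plate is not
#' confluent; that plate's colony count is the one used for quantification.
#' When every plate is confluent, no countable dilution exists and the sample
#' must be re-plated at further dilution. When every plate reads zero, the
#' most concentrated plate is returned and the sample is flagged as below the
#' detection limit.
#'
#' @param dilutions Numeric vector of dilution factors, each in (0, 1],
#'   strictly decreasing (most concentrated first).
#' @param counts Per-dilution plate counts: non-negative integers or the
#'   literal `"CONFLUENT"`. Same length as `dilutions`.
#' @param max_countable Optional numeric; counts above it are additionally
#'   treated as confluent (default `NULL`: confluence only via the marker).
#' @return A list with `dilution`, `count`, and `below_detection` (logical,
#'   `TRUE` when all plates were zero).
#' @export
#' @examples
#' select_countable_dilution(c(1, 0.1, 0.01, 0.001), c("CONFLUENT", 87, 9, 1))
select_countable_dilution <- function(dilutions, counts, max_countable = NULL) {
  dilutions <- as.numeric(dilutions)
  if (length(dilutions) == 0L || any(!is.finite(dilutions)) ||
      any(dilutions <= 0) || any(dilutions > 1)) {
    gnotostat_error("gnotostat_invalid_series",
                    "dilutions must be fractions in (0, 1]")
  }
  if (length(dilutions) > 1L && any(diff(dilutions) >= 0)) {
    gnotostat_error("gnotostat_invalid_series",
                    "dilutions must be strictly decreasing (most concentrated first)")
  }
  if (length(counts) != length(dilutions)) {
    gnotostat_error("gnotostat_invalid_series",
                    "counts and dilutions must have the same length")
  }
  p <- parse_counts(counts, max_countable)
  countable <- which(!p$confluent)
  if (length(countable) == 0L) {
    gnotostat_error(
      "gnotostat_all_confluent",
      "all plates are confluent; no countable dilution (re-plate at further dilution)"
    )
  }
  i <- countable[1L]
  list(
    dilution = dilutions[i],
    count = p$count[i],
    below_detection = all(p$count[countable] == 0)
  )
}

#' Convert a plate count to CFU per fly
#'
#' Corrects a colony count for the dilution factor, the fraction of the
#' homogenate that was plated, and the number of flies pooled into the
#' homogenate:
#' `count / dilution * (homogenate_volume / plated_volume) / n_flies`.
#'
#' @param count Non-negative colony count(s).
#' @param dilution Dilution factor(s) in (0, 1].
#' @param plated_volume Volume plated per dilution, µL (default 10).
#' @param homogenate_volume Homogenate volume, µL (default 200).
#' @param n_flies Number of flies pooled per sample (default 10).
#' @return CFU per fly (vectorized).
#' @export
#' @examples
#' cfu_per_fly(87, 0.1)  # 17400
cfu_per_fly <- function(count, dilution, plated_volume = 10,
                        homogenate_volume = 200, n_flies = 10) {
  if (any(plated_volume <= 0) || any(n_flies < 1) || any(homogenate_volume <= 0)) {
    gnotostat_error("gnotostat_invalid_geometry",
                    "plated_volume, homogenate_volume and n_flies must be positive")
  }
  if (any(plated_volume > homogenate_volume)) {
    gnotostat_error("gnotostat_invalid_geometry",
                    "plated_volume cannot exceed homogenate_volume")
  }
  if (any(count < 0) || any(dilution <= 0) || any(dilution > 1)) {
    gnotostat_error("gnotostat_invalid_geometry",
                    "count must be >= 0 and dilution in (0, 1]")
  }
  count / dilution * (homogenate_volume / plated_volume) / n_flies
}

#' Default detection-limit substitute
#'
#' Half a colony at the most concentrated dilution, corrected to CFU per fly:
#' `0.5 * (homogenate_volume / plated_volume) / n_flies` (1 CFU/fly at the
#' default plating geometry). Used in place of zero only where downstream
#' log-scale statistics require positive abundances.
#'
#' @inheritParams cfu_per_fly
#' @return A single CFU-per-fly value.
#' @export
default_zero_substitute <- function(plated_volume = 10, homogenate_volume = 200,
                                    n_flies = 10) {
  0.5 * (homogenate_volume / plated_volume) / n_flies
}

#' Quantify CFU per fly from a raw serial-dilution count table
#'
#' Applies [select_countable_dilution()] and [cfu_per_fly()] to every sample
#' (one `experiment` x `treatment` x `replicate` x `timepoint_h` group) of a
#' raw count table.
#'
#' @param raw Data frame with columns `experiment`, `treatment`, `replicate`,
#'   `timepoint_h`, `dilution`, `count` (count may contain `"CONFLUENT"`).
#' @param plated_volume,homogenate_volume,n_flies Plating geometry, as in
#'   [cfu_per_fly()].
#' @param zero_substitute Value assigned to all-zero samples. Default `0`
#'   preserves raw zeros (required for absolute clearance ratios); pass
#'   [default_zero_substitute()] where log-scale statistics downstream need
#'   positive values. Such records carry `below_detection = TRUE` either way.
#' @param max_countable Optional numeric, see [select_countable_dilution()].
#' @return Data frame of abundance records: `experiment`, `treatment`,
#'   `replicate`, `timepoint_h`, `cfu_per_fly`, `below_detection`.
#' @export
quantify_cfu <- function(raw, plated_volume = 10, homogenate_volume = 200,
                         n_flies = 10, zero_substitute = 0,
                         max_countable = NULL) {
  raw <- validate_input(raw, "cfu_raw")
  key <- interaction(raw$experiment, raw$treatment, raw$replicate,
                     raw$timepoint_h, drop = TRUE, lex.order = TRUE)
  parts <- split(raw, key)
  out <- lapply(parts, function(s) {
    o <- order(-s$dilution)
    sel <- select_countable_dilution(s$dilution[o], s$count[o], max_countable)
    cfu <- cfu_per_fly(sel$count, sel$dilution, plated_volume,
                       homogenate_volume, n_flies)
    if (sel$below_detection) cfu <- zero_substitute
    data.frame(
      experiment = s$experiment[1L], treatment = s$treatment[1L],
      replicate = s$replicate[1L], timepoint_h = s$timepoint_h[1L],
      cfu_per_fly = cfu, below_detection = sel$below_detection,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$experiment, res$treatment, res$replicate, res$timepoint_h), ,
      drop = FALSE]
}

#' Quality-control an experiment by its negative control
#'
#' An experiment is discarded when any time-zero negative-control sample
#' exceeds the contamination threshold (strictly greater than 50 CFU per fly
#' by default; a control at exactly the threshold keeps the experiment).
#'
#' @param records Abundance data frame (columns as returned by
#'   [quantify_cfu()]) for one experiment, including negative-control rows at
#'   timepoint 0.
#' @param threshold Contamination threshold in CFU per fly (default 50).
#' @return A list with `keep` (logical) and `offending` (data frame of
#'   negative-control records above the threshold).
#' @export
qc_experiment <- function(records, threshold = 50) {
  records <- validate_input(records, "abundance")
  ctrl <- records[records$treatment == "negative_control" &
                    records$timepoint_h == 0, , drop = FALSE]
  if (nrow(ctrl) == 0L) {
    gnotostat_error("gnotostat_missing_control",
                    "no negative-control record at timepoint 0")
  }
  offending <- ctrl[ctrl$cfu_per_fly > threshold, , drop = FALSE]
  list(keep = nrow(offending) == 0L, offending = offending)
}

#' Read a CFU table (raw counts or pre-corrected abundances)
#'
#' Accepts either the raw serial-dilution form (columns `experiment`,
#' `treatment`, `replicate`, `timepoint_h`, `dilution`, `count`) or the
#' corrected form (`experiment`, `treatment`, `replicate`, `timepoint_h`,
#' `cfu_per_fly`), and never both for one file.
#'
#' @param path Path to a UTF-8, comma-separated CSV with a header row.
#' @return The validated data frame, with attribute `"schema"` set to
#'   `"cfu_raw"` or `"cfu_corrected"`.
#' @export
read_cfu_csv <- function(path) {
  if (!file.exists(path)) {
    gnotostat_error("gnotostat_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = TRUE)
  schema <- if ("count" %in% names(df)) "cfu_raw" else "cfu_corrected"
  df <- validate_input(df, schema)
  attr(df, "schema") <- schema
  df
}
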