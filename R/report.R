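# Input validation and report assembly.

schema_defs <- list(
  cfu_raw = list(
    cols = c("experiment", "treatment", "replicate", "timepoint_h",
             "dilution", "count"),
    enums = list(treatment = c("test_yeast", "s_cerevisiae",
                               "negative_control"))
  ),
  cfu_corrected = list(
    cols = c("experiment", "treatment", "replicate", "timepoint_h",
             "cfu_per_fly"),
    enums = list(treatment = c("test_yeast", "s_cerevisiae",
                               "negative_control"))
  ),
  abundance = list(
    cols = c("experiment", "treatment", "replicate", "timepoint_h",
             "cfu_per_fly"),
    enums = list(treatment = c("test_yeast", "s_cerevisiae",
                               "negative_control"))
  ),
  growth = list(
    cols = c("time_h", "strain", "treatment", "replicate", "od"),
    enums = list(treatment = c("control", "h2o2"))
  ),
  choice = list(
    cols = c("experiment", "treatment", "replicate", "n_red", "n_blue",
             "n_purple", "n_empty"),
    enums = list(treatment = c("sc_control", "ty_control", "ty_blue",
                               "ty_red"))
  )
)

#' Validate a table against one of the package's input schemas
#'
#' Checks required columns, numeric types, enum values, non-negativity of
#' counts/abundances, and duplicate key rows. On failure, signals a
#' `gnotostat_schema_error` whose message lists every problem with the
#' offending column or row numbers.
#'
#' @param x A data frame, or a path to a CSV file.
#' @param schema One of `"cfu_raw"`, `"cfu_corrected"`, `"abundance"`,
#'   `"growth"`, `"choice"`.
#' @return The validated data frame, invisibly unchanged apart from CSV
#'   reading.
#' @export
validate_input <- function(x, schema = names(schema_defs)) {
  schema <- match.arg(schema)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      gnotostat_error("gnotostat_io_error", sprintf("file not found: %s", x))
    }
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) {
    gnotostat_error("gnotostat_schema_error", "input must be a data frame or CSV path")
  }
  def <- schema_defs[[schema]]
  problems <- character()
  missing <- setdiff(def$cols, names(x))
  if (length(missing)) {
    problems <- c(problems, sprintf("missing column(s): %s",
                                    paste(missing, collapse = ", ")))
  }
  if (!length(missing)) {
    for (col in names(def$enums)) {
      bad <- !x[[col]] %in% def$enums[[col]]
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "column %s: invalid value(s) %s (row %s)", col,
          paste(unique(x[[col]][bad]), collapse = ", "),
          paste(utils::head(which(bad), 5), collapse = ", ")
        ))
      }
    }
    num_cols <- switch(schema,
      cfu_raw = c("replicate", "timepoint_h", "dilution"),
      cfu_corrected = c("replicate", "timepoint_h", "cfu_per_fly"),
      abundance = c("replicate", "timepoint_h", "cfu_per_fly"),
      growth = c("time_h", "replicate", "od"),
      choice = c("replicate", "n_red", "n_blue", "n_purple", "n_empty")
    )
    for (col in num_cols) {
      v <- suppressWarnings(as.numeric(x[[col]]))
      bad <- is.na(v) & !is.na(x[[col]])
      if (any(bad) || anyNA(x[[col]])) {
        problems <- c(problems, sprintf(
          "column %s: non-numeric or missing value(s) (row %s)", col,
          paste(utils::head(which(bad | is.na(x[[col]])), 5), collapse = ", ")
        ))
      }
    }
    nonneg <- intersect(
      c("cfu_per_fly", "n_red", "n_blue", "n_purple", "n_empty"), num_cols
    )
    for (col in nonneg) {
      v <- suppressWarnings(as.numeric(x[[col]]))
      bad <- !is.na(v) & v < 0
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "column %s: negative value(s) (row %s)", col,
          paste(utils::head(which(bad), 5), collapse = ", ")
        ))
      }
    }
    if (schema == "cfu_raw" && "count" %in% names(x)) {
      cx <- trimws(as.character(x$count))
      nx <- suppressWarnings(as.numeric(cx))
      bad <- toupper(cx) != CONFLUENT & (is.na(nx) | nx < 0 | nx != floor(nx))
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "column count: values must be non-negative integers or \"CONFLUENT\" (row %s)",
          paste(utils::head(which(bad), 5), collapse = ", ")
        ))
      }
    }
    key_cols <- switch(schema,
      cfu_raw = c("experiment", "treatment", "replicate", "timepoint_h",
                  "dilution"),
      cfu_corrected = c("experiment", "treatment", "replicate",
                        "timepoint_h"),
      abundance = c("experiment", "treatment", "replicate", "timepoint_h"),
      growth = c("time_h", "strain", "treatment", "replicate"),
      choice = c("experiment", "treatment", "replicate")
    )
    if (all(key_cols %in% names(x))) {
      dup <- duplicated(x[key_cols])
      if (any(dup)) {
        problems <- c(problems, sprintf(
          "duplicate key row(s): %s",
          paste(utils::head(which(dup), 5), collapse = ", ")
        ))
      }
    }
  }
  if (length(problems)) {
    gnotostat_error(
      "gnotostat_schema_error",
      sprintf("input does not match schema \"%s\":\n- %s", schema,
              paste(problems, collapse = "\n- ")),
      problems = problems
    )
  }
  invisible(x)
}

fmt_num <- function(x, digits = 3) {
  formatC(x, format = "fg", digits = digits, flag = "#")
}

#' Assemble a plain-text report from analysis results
#'
#' Builds a deterministic, human-readable report with one section per
#' supplied result set, shaped like the package's summary tables:
#' persistence calls per experiment and timepoint, clearance ratios per time
#' interval, within-strain growth-inhibition calls, and feeding-preference
#' calls with dye-swap verdicts. The configuration (and seed, when given) is
#' echoed into the header for provenance. Two runs on identical inputs and
#' config produce byte-identical output.
#'
#' @param persistence Optional result of [persistence_analysis()].
#' @param clearance Optional result of [clearance_table()].
#' @param growth Optional result of [growth_analysis()].
#' @param preference Optional result of [preference_analysis()].
#' @param config Optional named list echoed into the header.
#' @return Character vector of report lines (print with `writeLines()`).
#' @export
build_report <- function(persistence = NULL, clearance = NULL, growth = NULL,
                         preference = NULL, config = list()) {
  if (is.null(persistence) && is.null(clearance) && is.null(growth) &&
      is.null(preference)) {
    gnotostat_error("gnotostat_no_data",
                    "at least one analysis result is required")
  }
  lines <- c("# gnotostat report", "")
  if (length(config)) {
    lines <- c(lines, "## Configuration",
               sprintf("- %s: %s", names(config),
                       vapply(config, function(v) paste(format(v), collapse = " "),
                              character(1))),
               "")
  }
  if (!is.null(persistence)) {
    lines <- c(lines, "## Relative persistence", "",
               "experiment | timepoint_h | point_estimate | call")
    for (i in seq_len(nrow(persistence))) {
      lines <- c(lines, sprintf(
        "%s | %g | %s | %s",
        persistence$experiment[i], persistence$timepoint_h[i],
        fmt_num(persistence$point_estimate[i]), persistence$label[i]
      ))
    }
    lines <- c(lines, "")
  }
  if (!is.null(clearance)) {
    lines <- c(lines, "## Fold clearance (ratio of mean CFU/fly, start/end)",
               "", "experiment | treatment | interval | ratio")
    e <- clearance$entries
    for (i in seq_len(nrow(e))) {
      lines <- c(lines, sprintf(
        "%s | %s | %g-%g | %g", e$experiment[i], e$treatment[i],
        e$t_start[i], e$t_end[i], round_half_up(e$ratio[i], 1)
      ))
    }
    s <- clearance$summary
    lines <- c(lines, "", "interval | treatment | mean ratio")
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf("%s | %s | %g", s$interval[i],
                                s$treatment[i], s$mean_ratio[i]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(growth)) {
    lines <- c(lines, "## Growth inhibition (within strain)", "",
               "strain | call | inhibition_index")
    g <- growth$calls
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, sprintf("%s | %s | %s", g$strain[i], g$call[i],
                                fmt_num(g$inhibition_index[i])))
    }
    lines <- c(lines, "")
  }
  if (!is.null(preference)) {
    lines <- c(lines, "## Feeding preference", "",
               "experiment | treatment | PI (mean) | call")
    p <- preference$results
    for (i in seq_len(nrow(p))) {
      lines <- c(lines, sprintf(
        "%s | %s | %s | %s", p$experiment[i], p$treatment[i],
        fmt_num(p$pi_mean[i]), p$label[i]
      ))
    }
    v <- preference$verdicts
    if (nrow(v)) {
      lines <- c(lines, "", "experiment | dye-swap verdict")
      for (i in seq_len(nrow(v))) {
        lines <- c(lines, sprintf(
          "%s | %s%s", v$experiment[i], v$verdict[i],
          if (v$dye_confounded[i]) " [dye-confounded]" else ""
        ))
      }
    }
    lines <- c(lines, "")
  }
  lines
}
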