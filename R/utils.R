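# Shared helpers: rounding, seeded evaluation, condition constructors.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in the package's report tables.
#' Base [round()] rounds half to even, which would print e.g. the mean of
#' fold-clearance ratios ending in .25 one ulp low.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the report precision).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(841.25, 1)  # 841.3, not 841.2
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic per-module substream seed from a top-level seed.
# Keeps all derived seeds in the 32-bit integer range.
substream_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% .Machine$integer.max
}

gnotostat_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "gnotostat_error")))
}

# Format a confidence level the way the assay tables print it: 0.999 -> "99.9%"
format_level <- function(level) {
  paste0(formatC(round(level * 100, 3), format = "fg"), "%")
}
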