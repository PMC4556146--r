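# Small in-code fixtures shared across test files.

# Abundance table for one experiment with paired test-yeast replicates and an
# averaged reference arm, plus clean negative controls.
make_abundances <- function(experiment = "EXP1",
                            ty0 = c(10000, 10000, 10000),
                            sc0 = c(10000, 10000, 10000),
                            ty24 = c(2000, 1000, 1500),
                            sc24 = c(400, 500, 600)) {
  n <- length(ty0)
  rows <- rbind(
    data.frame(treatment = "test_yeast", replicate = 1:n, timepoint_h = 0,
               cfu_per_fly = ty0),
    data.frame(treatment = "s_cerevisiae", replicate = 1:n, timepoint_h = 0,
               cfu_per_fly = sc0),
    data.frame(treatment = "test_yeast", replicate = 1:n, timepoint_h = 24,
               cfu_per_fly = ty24),
    data.frame(treatment = "s_cerevisiae", replicate = 1:n, timepoint_h = 24,
               cfu_per_fly = sc24),
    data.frame(treatment = "negative_control", replicate = 1:n,
               timepoint_h = 0, cfu_per_fly = 0)
  )
  rows$experiment <- experiment
  rows$below_detection <- rows$cfu_per_fly == 0
  rows[, c("experiment", "treatment", "replicate", "timepoint_h",
           "cfu_per_fly", "below_detection")]
}

# Raw serial-dilution table for one sample.
make_raw_sample <- function(counts, dilutions = c(1, 0.1, 0.01, 0.001),
                            treatment = "test_yeast", replicate = 1,
                            timepoint_h = 0, experiment = "EXP1") {
  data.frame(
    experiment = experiment, treatment = treatment, replicate = replicate,
    timepoint_h = timepoint_h, dilution = dilutions,
    count = as.character(counts), stringsAsFactors = FALSE
  )
}

# Inverse-CDF (type-1) quantile computed by hand, used as the independent
# oracle for bootstrap intervals.
oracle_quantile <- function(x, p) {
  sorted <- sort(x)
  sorted[pmax(1L, ceiling(length(x) * p))]
}

# All resamples of size n from x, with replacement: n^n rows.
enumerate_resamples <- function(x) {
  n <- length(x)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  matrix(x[as.matrix(grid)], ncol = n)
}
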