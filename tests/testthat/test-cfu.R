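test_that("countable-dilution selection follows the most-concentrated-countable rule", {
  d <- c(1, 0.1, 0.01, 0.001)
  sel <- select_countable_dilution(d, c("CONFLUENT", "87", "9", "1"))
  expect_equal(sel$dilution, 0.1)
  expect_equal(sel$count, 87)
  expect_false(sel$below_detection)

  sel <- select_countable_dilution(d, c(12, 1, 0, 0))
  expect_equal(sel$dilution, 1)
  expect_equal(sel$count, 12)

  expect_error(select_countable_dilution(d, rep("CONFLUENT", 4)),
               class = "gnotostat_all_confluent")

  # all-zero sample: most concentrated plate, flagged below detection
  sel <- select_countable_dilution(d, c(0, 0, 0, 0))
  expect_equal(sel$dilution, 1)
  expect_true(sel$below_detection)

  # selection ignores counts more dilute than the selected plate
  sel1 <- select_countable_dilution(d, c("CONFLUENT", "87", "9", "1"))
  sel2 <- select_countable_dilution(d, c("CONFLUENT", "87", "300", "CONFLUENT"))
  expect_equal(sel1[c("dilution", "count")], sel2[c("dilution", "count")])

  # optional numeric confluence cutoff
  sel <- select_countable_dilution(d, c(400, 87, 9, 1), max_countable = 300)
  expect_equal(sel$dilution, 0.1)

  expect_error(select_countable_dilution(c(0.1, 1), c(1, 2)),
               class = "gnotostat_invalid_series")
  expect_error(select_countable_dilution(d, c(1, 2, -3, 4)),
               class = "gnotostat_invalid_count")
})

test_that("plate counts convert to CFU per fly by dilution, volume, and fly number", {
  expect_equal(cfu_per_fly(50, 1, 10, 200, 10), 100)
  expect_equal(cfu_per_fly(87, 0.1, 10, 200, 10), 1740)
  expect_equal(cfu_per_fly(0, 1, 10, 200, 10), 0)
  expect_error(cfu_per_fly(5, 1, plated_volume = 0),
               class = "gnotostat_invalid_geometry")

  # degree 1 in count, degree -1 in dilution
  counts <- c(3, 17, 150)
  dil <- c(1, 0.1, 0.01)
  expect_equal(cfu_per_fly(2 * counts, dil), 2 * cfu_per_fly(counts, dil))
  expect_equal(cfu_per_fly(counts, dil / 2), 2 * cfu_per_fly(counts, dil))
})

test_that("experiment QC discards only when a time-0 negative control strictly exceeds 50 CFU/fly", {
  ab <- make_abundances()
  expect_true(qc_experiment(ab)$keep)

  set_ctrl <- function(ab, v) {
    i <- which(ab$treatment == "negative_control" & ab$timepoint_h == 0)[1]
    ab$cfu_per_fly[i] <- v
    ab
  }
  expect_false(qc_experiment(set_ctrl(ab, 51))$keep)
  expect_true(qc_experiment(set_ctrl(ab, 50))$keep)   # boundary keeps
  expect_true(qc_experiment(set_ctrl(ab, 0))$keep)
  expect_equal(nrow(qc_experiment(set_ctrl(ab, 51))$offending), 1L)

  no_ctrl <- ab[ab$treatment != "negative_control", ]
  expect_error(qc_experiment(no_ctrl), class = "gnotostat_missing_control")
})

test_that("raw tables quantify sample-wise, with zero substitution only on request", {
  raw <- rbind(
    make_raw_sample(c("CONFLUENT", "87", "9", "1")),
    make_raw_sample(c(0, 0, 0, 0), treatment = "negative_control")
  )
  ab <- quantify_cfu(raw)
  ty <- ab[ab$treatment == "test_yeast", ]
  expect_equal(ty$cfu_per_fly, 1740)
  expect_false(ty$below_detection)
  nc <- ab[ab$treatment == "negative_control", ]
  expect_equal(nc$cfu_per_fly, 0)
  expect_true(nc$below_detection)

  ab2 <- quantify_cfu(raw, zero_substitute = default_zero_substitute())
  expect_equal(ab2$cfu_per_fly[ab2$treatment == "negative_control"], 1)
  expect_equal(default_zero_substitute(), 0.5 * 20 / 10)
})

test_that("round-trip with the simulator: selected-count estimates are nearly unbiased", {
  # Known fixed load, Poisson plating noise only; relative bias of the
  # CFU/fly estimate is < 5% whenever the selected plate count is >= 30.
  sims <- lapply(1:60, function(i) {
    simulate_persistence(
      log10_n0_mean = 4.3, log10_n0_sd = 0, log10_sample_sd = 0,
      k_ty = 0, k_sc = 0, timepoints = c(0, 24), n_replicates = 5,
      seed = 1000 + i
    )
  })
  est <- unlist(lapply(sims, function(s) {
    ab <- quantify_cfu(s$raw)
    ab$cfu_per_fly[ab$treatment != "negative_control"]
  }))
  expect_gte(length(est), 1000)
  rel_bias <- abs(mean(est) - 10^4.3) / 10^4.3
  expect_lt(rel_bias, 0.05)
})

test_that("the CSV reader accepts raw and corrected forms and validates them", {
  raw <- make_raw_sample(c("CONFLUENT", "87", "9", "1"))
  f <- tempfile(fileext = ".csv")
  write.csv(raw, f, row.names = FALSE, quote = FALSE)
  got <- read_cfu_csv(f)
  expect_equal(attr(got, "schema"), "cfu_raw")
  expect_equal(nrow(got), 4L)

  corr <- make_abundances()[, 1:5]
  f2 <- tempfile(fileext = ".csv")
  write.csv(corr, f2, row.names = FALSE, quote = FALSE)
  got2 <- read_cfu_csv(f2)
  expect_equal(attr(got2, "schema"), "cfu_corrected")

  expect_error(read_cfu_csv(file.path(tempdir(), "nope.csv")),
               class = "gnotostat_io_error")
})
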