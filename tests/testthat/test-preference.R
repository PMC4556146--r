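test_that("the preference index splits purple flies evenly and ignores empties", {
  expect_equal(preference_index(10, 10, 4, "blue"), 0.5)
  expect_equal(preference_index(10, 30, 0, "blue"), 0.75)
  expect_equal(preference_index(0, 0, 8, "blue"), 0.5)
  expect_equal(preference_index(0, 0, 8, "red"), 0.5)
  expect_error(preference_index(0, 0, 0, "blue"), class = "gnotostat_no_flies_fed")
  expect_error(preference_index(-1, 2, 0, "blue"), class = "gnotostat_invalid_counts")
})

test_that("feeding rate is the fed fraction of all flies", {
  expect_equal(feeding_rate(10, 10, 5, 25), 0.5)
  expect_equal(feeding_rate(3, 4, 1, 0), 1)
  expect_equal(feeding_rate(0, 0, 0, 12), 0)
  expect_error(feeding_rate(0, 0, 0, 0), class = "gnotostat_invalid_counts")
})

test_that("t intervals on PI values match the closed form and truncate to [0, 1]", {
  ci <- preference_ci(c(0.7, 0.7, 0.7), 0.95)
  expect_equal(ci$lower, 0.7)
  expect_equal(ci$upper, 0.7)

  # hand computation: mean 0.7, sd 0.1, half-width 4.3027 * 0.1 / sqrt(3)
  ci <- preference_ci(c(0.6, 0.7, 0.8), 0.95)
  hw <- 4.3027 * 0.1 / sqrt(3)
  expect_equal(ci$lower, 0.7 - hw, tolerance = 1e-4)
  expect_equal(ci$upper, 0.7 + hw, tolerance = 1e-4)

  # truncation at the unit interval
  ci <- preference_ci(c(0.9, 0.99, 0.95), 0.999)
  expect_lte(ci$upper, 1)

  # bootstrap equals its 27-resample enumeration
  x <- c(0.6, 0.7, 0.8)
  means <- rowMeans(enumerate_resamples(x))
  ci <- preference_ci(x, 0.95, method = "bootstrap_percentile", B = 10000,
                      seed = 3)
  expect_equal(ci$lower, oracle_quantile(means, 0.025))
  expect_equal(ci$upper, oracle_quantile(means, 0.975))

  expect_error(preference_ci(0.5, 0.95), class = "gnotostat_too_few_replicates")
})

test_that("preference classification uses the table vocabulary against 0.5", {
  cls <- classify_preference(
    data.frame(level = c(0.95, 0.99, 0.999), lower = c(0.66, 0.64, 0.62),
               upper = c(0.77, 0.79, 0.81)),
    focal_name = "HO", other_name = "SC"
  )
  expect_equal(cls$classification, "prefers_focal")
  expect_equal(cls$label, "Prefers HO at 99.9%")

  cls <- classify_preference(data.frame(level = 0.95, lower = 0.41, upper = 0.66))
  expect_equal(cls$classification, "no_preference")
  expect_equal(cls$label, "No preference")

  # only the least stringent level excludes 0.5
  cls <- classify_preference(
    data.frame(level = c(0.95, 0.99), lower = c(0.55, 0.48),
               upper = c(0.9, 0.95)),
    focal_name = "SP"
  )
  expect_equal(cls$classification, "prefers_focal")
  expect_equal(cls$level, 0.95)
  expect_equal(cls$label, "Prefers SP at 95%")

  cls <- classify_preference(
    data.frame(level = 0.95, lower = 0.2, upper = 0.45),
    focal_name = "TY", other_name = "SC"
  )
  expect_equal(cls$classification, "prefers_other")
  expect_equal(cls$label, "Prefers SC at 95%")
})

test_that("dye-swap verdicts require agreement across labelings and flag dye bias", {
  pf <- list(classification = "prefers_focal", level = 0.999,
             label = "Prefers TY at 99.9%")
  np <- list(classification = "no_preference", level = NA, label = "No preference")

  expect_equal(dye_swap_verdict(pf, pf)$verdict, "preferred")
  expect_equal(dye_swap_verdict(np, np)$verdict, "not_preferred")
  expect_equal(dye_swap_verdict(pf, np)$verdict, "inconsistent")
  expect_error(dye_swap_verdict(pf, NULL), class = "gnotostat_missing_treatment")

  v <- dye_swap_verdict(pf, pf, control_classes = list(
    list(classification = "prefers_focal", level = 0.95,
         label = "Prefers blue at 95%")
  ))
  expect_true(v$dye_confounded)
  v <- dye_swap_verdict(pf, pf, control_classes = list(np))
  expect_false(v$dye_confounded)
})

test_that("the preference driver orients focal colors, pools counts, and excludes unfed replicates", {
  counts <- data.frame(
    experiment = "HO",
    treatment = rep(c("sc_control", "ty_control", "ty_blue", "ty_red"), each = 3),
    replicate = rep(1:3, 4),
    n_red = c(12, 11, 13, 10, 12, 11, 5, 6, 4, 30, 31, 29),
    n_blue = c(12, 12, 12, 11, 11, 12, 30, 32, 31, 6, 5, 7),
    n_purple = c(4, 4, 4, 4, 4, 4, 5, 4, 5, 4, 5, 4),
    n_empty = c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10)
  )
  res <- preference_analysis(counts, focal_name = "HO", other_name = "SC")
  r <- res$results
  expect_equal(r$focal_color[r$treatment == "ty_red"], "red")
  # ty_red PI oriented toward red (the test yeast's dye)
  pis_red <- mapply(preference_index, c(30, 31, 29), c(6, 5, 7), c(4, 5, 4),
                    MoreArgs = list(focal_color = "red"))
  expect_equal(r$pi_by_replicate[r$treatment == "ty_red"][[1]], unname(pis_red))
  # pooled-count PI applies the index to summed counts
  expect_equal(r$pi_pooled[r$treatment == "ty_blue"],
               preference_index(15, 93, 14, "blue"))
  expect_equal(res$verdicts$verdict, "preferred")
  expect_false(res$verdicts$dye_confounded)

  # a replicate with no fed flies is excluded with a warning
  counts2 <- counts
  counts2[counts2$treatment == "ty_blue" & counts2$replicate == 3,
          c("n_red", "n_blue", "n_purple")] <- 0
  expect_warning(res2 <- preference_analysis(counts2), "no fed flies")
  expect_equal(res2$results$n_replicates[res2$results$treatment == "ty_blue"], 2L)
})
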