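test_that("relative persistence pairs test-yeast replicates and averages the reference", {
  r <- relative_persistence(c(2000, 1000, 1500), sc_t = c(400, 500, 600),
                            ty_0 = rep(10000, 3), sc_0 = rep(10000, 3))
  expect_equal(r, c(4, 2, 3))

  # unit normalization (time-0 fallback): divisor is 1
  expect_equal(relative_persistence(c(40, 60), sc_t = c(15, 25),
                                    normalization = "unit"), c(2, 3))

  # invariant to rescaling all CFU values at one timepoint
  s <- 7.3
  r2 <- relative_persistence(s * c(2000, 1000, 1500), sc_t = s * c(400, 500, 600),
                             ty_0 = rep(10000, 3), sc_0 = rep(10000, 3))
  expect_equal(r2, r)

  expect_error(relative_persistence(c(1, 2), sc_t = c(0, 0)),
               class = "gnotostat_zero_reference")
  expect_error(relative_persistence(c(1, 2), sc_t = c(1, 1),
                                    ty_0 = c(0, 1), sc_0 = c(1, 1)),
               class = "gnotostat_zero_reference")
  expect_error(relative_persistence(c(1, 2), sc_t = c(1, 1), ty_0 = c(1, 1, 1),
                                    sc_0 = c(1, 1)),
               class = "gnotostat_invalid_ratio_input")
})

test_that("log-t intervals match the closed-form computation and degenerate correctly", {
  # zero variance: interval collapses to the point
  ci <- persistence_ci(c(2, 2, 2), level = 0.95)
  expect_equal(ci$lower, 2)
  expect_equal(ci$upper, 2)

  # independent hand computation for (4, 2, 3), t_{0.975,2} = 4.3027
  lr <- log(c(4, 2, 3))
  hw <- 4.3027 * sd(lr) / sqrt(3)
  ci <- persistence_ci(c(4, 2, 3), level = 0.95)
  expect_equal(ci$lower, exp(mean(lr) - hw), tolerance = 1e-4)
  expect_equal(ci$upper, exp(mean(lr) + hw), tolerance = 1e-4)

  expect_error(persistence_ci(c(2), 0.95), class = "gnotostat_too_few_replicates")
  expect_error(persistence_ci(c(0, 1, 2), 0.95), class = "gnotostat_zero_reference")
  expect_error(persistence_ci(c(1, 2), level = 1.2), class = "gnotostat_invalid_level")
})

test_that("bootstrap intervals agree with exhaustive resample enumeration at n = 3", {
  x <- c(4, 2, 3)
  means <- rowMeans(enumerate_resamples(x))
  expect_equal(length(means), 27L)
  ci <- persistence_ci(x, level = 0.95, method = "bootstrap_percentile",
                       B = 10000, seed = 11)
  expect_equal(ci$lower, oracle_quantile(means, 0.025))
  expect_equal(ci$upper, oracle_quantile(means, 0.975))

  # all levels from one resample set: nesting holds
  ci3 <- persistence_ci(x, level = c(0.95, 0.99, 0.999),
                        method = "bootstrap_percentile", B = 5000, seed = 2)
  expect_true(all(diff(ci3$lower) <= 0))
  expect_true(all(diff(ci3$upper) >= 0))

  # reproducible under the same seed
  ci_a <- persistence_ci(x, 0.95, "bootstrap_percentile", B = 2000, seed = 5)
  ci_b <- persistence_ci(x, 0.95, "bootstrap_percentile", B = 2000, seed = 5)
  expect_identical(ci_a, ci_b)
})

test_that("persistence classification reports the most stringent level excluding 1", {
  ci <- data.frame(level = c(0.95, 0.99, 0.999),
                   lower = c(1.2, 1.05, 0.9), upper = c(3.0, 3.4, 4.0))
  cls <- classify_persistence(ci)
  expect_equal(cls$classification, "persists")
  expect_equal(cls$level, 0.99)
  expect_equal(cls$label, "Persists at 99%")

  cls <- classify_persistence(data.frame(level = 0.95, lower = 0.8, upper = 1.2))
  expect_equal(cls$classification, "no_change")
  expect_equal(cls$label, "No change")

  ci <- data.frame(level = c(0.95, 0.99, 0.999),
                   lower = c(0.2, 0.15, 0.1), upper = c(0.8, 0.9, 0.95))
  cls <- classify_persistence(ci)
  expect_equal(cls$classification, "removed")
  expect_equal(cls$label, "Removed at 99.9%")

  bad <- data.frame(level = c(0.95, 0.99), lower = c(1.0, 1.2), upper = c(3, 2))
  expect_error(classify_persistence(bad), class = "gnotostat_non_nested_ci")
})

test_that("clearance ratios are ratios of replicate means with multiplicative structure", {
  expect_equal(clearance_ratio(1000, 100), 10)
  expect_equal(clearance_ratio(c(5, 5), c(5, 5)), 1)
  expect_equal(clearance_ratio(c(9000, 10000, 11000), c(400, 500, 600)), 20)
  expect_error(clearance_ratio(c(1, 2), c(0, 0)), class = "gnotostat_zero_reference")

  # multiplicativity over a partition of the time axis
  a0 <- c(12000, 9000, 10000); a24 <- c(900, 1100, 1000); a48 <- c(45, 55, 50)
  expect_equal(clearance_ratio(a0, a48),
               clearance_ratio(a0, a24) * clearance_ratio(a24, a48))

  expect_equal(clearance_summary(5.0), 5.0)
  expect_error(clearance_summary(numeric(0)), class = "gnotostat_invalid_ratio_input")
})

test_that("report rounding is half-up at one decimal", {
  expect_equal(round_half_up(841.25, 1), 841.3)
  expect_equal(round_half_up(14.84, 1), 14.8)
  expect_equal(round_half_up(-2.25, 1), -2.3)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("the persistence driver reproduces per-timepoint ratios, CIs, and labels", {
  ab <- make_abundances()
  res <- persistence_analysis(ab)
  expect_equal(nrow(res), 1L)
  expect_equal(res$ratios[[1]], c(4, 2, 3))
  expect_equal(res$geometric_mean, exp(mean(log(c(4, 2, 3)))))
  expect_equal(res$point_estimate, res$geometric_mean)
  ci <- persistence_ci(c(4, 2, 3), c(0.95, 0.99, 0.999))
  expect_equal(res$ci95_lo, ci$lower[1])
  expect_equal(res$ci999_hi, ci$upper[3])
  expect_equal(res$label, "Persists at 95%")
  expect_true(all(c("ci95_lo", "ci95_hi", "ci99_lo", "ci99_hi",
                    "ci999_lo", "ci999_hi") %in% names(res)))

  # unit normalization per experiment via named vector
  res_u <- persistence_analysis(ab, normalization = c(EXP1 = "unit"))
  expect_equal(res_u$ratios[[1]], c(2000, 1000, 1500) / 500)

  # clearance table on the same abundances
  ct <- clearance_table(ab)
  ty <- ct$entries[ct$entries$treatment == "test_yeast", ]
  expect_equal(ty$ratio, mean(c(10000, 10000, 10000)) / mean(c(2000, 1000, 1500)))
  expect_equal(ct$summary$mean_ratio[ct$summary$treatment == "test_yeast"],
               round_half_up(ty$ratio, 1))
})
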