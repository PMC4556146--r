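# Synthetic-data generators for the three assay types.
#
# Each generator is a pure function of its parameters and seed, and emits the
# same table schemas the analysis functions read, plus a ground-truth table,
# so every pipeline stage can be checked against known parameters.

#' Simulate a serial-dilution persistence assay
#'
#' Per replicate vial, the true initial load per fly is lognormal:
#' `N0 = 10^Normal(log10_n0_mean, log10_n0_sd)`. Loads decay exponentially,
#' `N(t) = N0 * exp(-k * t)`, with arm-specific clearance rates `k_ty` and
#' `k_sc`. Each measured sample (one pooled homogenate per vial and
#' timepoint) additionally carries lognormal sampling noise with standard
#' deviation `log10_sample_sd` (pooling, homogenization and dissection
#' variability between samples of the same vial). Plating follows standard
#' dilution-plating theory: the expected colony count at dilution `d` is
#' `N(t) * n_flies * d * plated_volume / homogenate_volume`, and the observed
#' count is Poisson. Plates whose drawn count exceeds `confluence_cutoff` are
#' emitted as the literal `"CONFLUENT"`. Negative-control vials carry no
#' yeast (all plates zero).
#'
#' Default clearance rates mirror the fold-declines observed in gnotobiotic
#' persistence assays (roughly 15-fold over the first day for test yeasts and
#' 60-fold for the reference): `k_ty = 0.11`, `k_sc = 0.17` per hour.
#'
#' @param log10_n0_mean,log10_n0_sd Mean and SD of log10 initial CFU/fly
#'   across replicate vials (defaults 5 and 0.3).
#' @param k_ty,k_sc Exponential clearance rates per hour for the test-yeast
#'   and reference arms.
#' @param log10_sample_sd Lognormal per-sample (vial x timepoint) noise SD in
#'   log10 units (default 0.3).
#' @param timepoints Sampling times in hours (default 0, 24, 48).
#' @param n_replicates Vials per arm (default 3).
#' @param n_flies Flies pooled per sample (default 10).
#' @param plated_volume,homogenate_volume Plating geometry, µL (defaults 10
#'   and 200).
#' @param dilutions Dilution factors, most concentrated first (default 1,
#'   0.1, 0.01, 0.001).
#' @param confluence_cutoff Colony count above which a plate is a confluent
#'   lawn (default 300).
#' @param experiment Experiment label (default `"sim"`).
#' @param seed Integer seed; same seed, same output.
#' @return List with `raw` (serial-dilution count table: `experiment`,
#'   `treatment`, `replicate`, `timepoint_h`, `dilution`, `count`) and
#'   `truth` (true per-fly loads per vial and timepoint, before sampling
#'   noise).
#' @export
simulate_persistence <- function(log10_n0_mean = 5, log10_n0_sd = 0.3,
                                 k_ty = 0.11, k_sc = 0.17,
                                 log10_sample_sd = 0.3,
                                 timepoints = c(0, 24, 48), n_replicates = 3,
                                 n_flies = 10, plated_volume = 10,
                                 homogenate_volume = 200,
                                 dilutions = c(1, 0.1, 0.01, 0.001),
                                 confluence_cutoff = 300,
                                 experiment = "sim", seed = NULL) {
  stopifnot(k_ty >= 0, k_sc >= 0, log10_n0_sd >= 0, log10_sample_sd >= 0,
            n_replicates >= 1, n_flies >= 1,
            all(dilutions > 0), all(dilutions <= 1))
  if (length(dilutions) > 1L && any(diff(dilutions) >= 0)) {
    gnotostat_error("gnotostat_invalid_series",
                    "dilutions must be strictly decreasing")
  }
  with_seed(seed, {
    arms <- list(test_yeast = k_ty, s_cerevisiae = k_sc)
    raw <- list()
    truth <- list()
    for (arm in names(arms)) {
      k <- arms[[arm]]
      n0 <- 10^stats::rnorm(n_replicates, log10_n0_mean, log10_n0_sd)
      for (rep_i in seq_len(n_replicates)) {
        for (tp in timepoints) {
          true_load <- n0[rep_i] * exp(-k * tp)
          sampled <- true_load *
            10^stats::rnorm(1, 0, log10_sample_sd)
          mu <- sampled * n_flies * dilutions *
            (plated_volume / homogenate_volume)
          obs <- stats::rpois(length(dilutions), mu)
          count <- ifelse(obs > confluence_cutoff, CONFLUENT,
                          as.character(obs))
          raw[[length(raw) + 1L]] <- data.frame(
            experiment = experiment, treatment = arm, replicate = rep_i,
            timepoint_h = tp, dilution = dilutions, count = count,
            stringsAsFactors = FALSE
          )
          truth[[length(truth) + 1L]] <- data.frame(
            experiment = experiment, treatment = arm, replicate = rep_i,
            timepoint_h = tp, true_cfu_per_fly = true_load,
            sampled_cfu_per_fly = sampled, stringsAsFactors = FALSE
          )
        }
      }
    }
    # clean negative-control vials: no yeast, zero counts at every dilution
    for (rep_i in seq_len(n_replicates)) {
      for (tp in timepoints) {
        raw[[length(raw) + 1L]] <- data.frame(
          experiment = experiment, treatment = "negative_control",
          replicate = rep_i, timepoint_h = tp, dilution = dilutions,
          count = "0", stringsAsFactors = FALSE
        )
      }
    }
    list(raw = do.call(rbind, raw), truth = do.call(rbind, truth))
  })
}

#' Simulate logistic growth curves
#'
#' `od(t) = baseline + (h2o2_effect * K) / (1 + exp(-(h2o2_effect * r) *
#' (t - tm))) + Normal(0, noise_sd)`. An `h2o2_effect` of 0 models complete
#' inhibition (flat noisy baseline), 1 models no effect, and intermediate
#' values scale both the plateau and the rate.
#'
#' Defaults reflect a yeast growing in rich medium in a plate reader:
#' plateau rise `K = 1` OD, rate `r = 0.45`/h (about a 90-minute doubling
#' time), midpoint 12 h, readings every 0.5 h for 72 h, read noise SD 0.01.
#'
#' @param strain,treatment Labels for the output table (defaults `"sim"`,
#'   `"control"`).
#' @param n_replicates Curves to generate (default 3).
#' @param baseline Starting OD (default 0.05).
#' @param K Plateau rise above baseline, OD units (default 1).
#' @param r Logistic growth rate per hour (default 0.45).
#' @param tm Logistic midpoint, hours (default 12).
#' @param noise_sd Gaussian read noise SD, OD units (default 0.01).
#' @param h2o2_effect Multiplier in \[0, 1\] on `K` and `r` (default 1).
#' @param interval,duration Sampling interval and total duration, hours
#'   (defaults 0.5 and 72).
#' @param seed Integer seed.
#' @return Data frame `time_h`, `strain`, `treatment`, `replicate`, `od`.
#' @export
simulate_growth <- function(strain = "sim", treatment = "control",
                            n_replicates = 3, baseline = 0.05, K = 1,
                            r = 0.45, tm = 12, noise_sd = 0.01,
                            h2o2_effect = 1, interval = 0.5, duration = 72,
                            seed = NULL) {
  stopifnot(K >= 0, noise_sd >= 0, h2o2_effect >= 0, h2o2_effect <= 1,
            interval > 0, duration > interval, n_replicates >= 1)
  with_seed(seed, {
    t <- seq(0, duration, by = interval)
    mu <- baseline +
      (h2o2_effect * K) / (1 + exp(-(h2o2_effect * r) * (t - tm)))
    do.call(rbind, lapply(seq_len(n_replicates), function(rep_i) {
      data.frame(
        time_h = t, strain = strain, treatment = treatment,
        replicate = rep_i,
        od = mu + stats::rnorm(length(t), 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }))
  })
}

#' Simulate a two-choice feeding assay
#'
#' Each fly independently feeds with probability `feed_prob`; a fed fly is
#' purple (fed on both patches) with probability `purple_prob`, and otherwise
#' takes the focal color with probability `preference`. The expected
#' preference index is therefore
#' `(1 - purple_prob) * preference + purple_prob / 2`.
#'
#' @param n_flies Flies per replicate plate (default 50).
#' @param feed_prob Probability a fly feeds at all (default 0.8).
#' @param purple_prob Probability a fed fly fed on both patches (default
#'   0.1).
#' @param preference Probability a single-color fed fly chose the focal patch
#'   (default 0.5, no preference).
#' @param n_replicates Replicate plates (default 4).
#' @param focal_color `"blue"` or `"red"`: which dye labels the focal patch
#'   (default `"blue"`).
#' @param experiment,treatment Labels for the output table.
#' @param seed Integer seed.
#' @return Data frame `experiment`, `treatment`, `replicate`, `n_red`,
#'   `n_blue`, `n_purple`, `n_empty`.
#' @export
simulate_choice <- function(n_flies = 50, feed_prob = 0.8, purple_prob = 0.1,
                            preference = 0.5, n_replicates = 4,
                            focal_color = c("blue", "red"),
                            experiment = "sim", treatment = "ty_blue",
                            seed = NULL) {
  focal_color <- match.arg(focal_color)
  stopifnot(feed_prob >= 0, feed_prob <= 1, purple_prob >= 0,
            purple_prob <= 1, preference >= 0, preference <= 1,
            n_flies >= 1, n_replicates >= 1)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(rep_i) {
      fed <- stats::rbinom(1, n_flies, feed_prob)
      purple <- stats::rbinom(1, fed, purple_prob)
      focal <- stats::rbinom(1, fed - purple, preference)
      other <- fed - purple - focal
      data.frame(
        experiment = experiment, treatment = treatment, replicate = rep_i,
        n_red = if (focal_color == "red") focal else other,
        n_blue = if (focal_color == "blue") focal else other,
        n_purple = purple, n_empty = n_flies - fed,
        stringsAsFactors = FALSE
      )
    }))
  })
}
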