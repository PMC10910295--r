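#' Balanced accuracy of a binary classification
#'
#' Mean of sensitivity and specificity; insensitive to class imbalance.
#'
#' @param truth,predicted Logical vectors (TRUE = positive class).
#' @return Numeric scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  sens <- mean(predicted[truth])
  spec <- mean(!predicted[!truth])
  (sens + spec) / 2
}

#' Classifier ground-truth recovery experiment
#'
#' Simulates cohorts with known archetypes and measures how well the
#' selection procedure recovers (a) the bilateral-vs-contralateral label
#' (balanced accuracy over units whose ground truth is a bilateral archetype
#' or `contra_only`; a unit screened out as non-responsive counts as a miss)
#' and (b) the integration sign (fraction of `bilateral_excitatory` /
#' `bilateral_suppressive` units whose ON integration call matches).
#'
#' @param seeds Integer vector of simulation seeds, one cohort each.
#' @param n_units_per_cell Units per (treatment, hemisphere) cell.
#' @param thresholds A [classifier_thresholds()].
#' @param config_fun Function `seed -> sim_config`; defaults to the
#'   default cohort preset at the given cohort size.
#' @return Data frame with one row per seed: `seed`,
#'   `balanced_accuracy`, `integration_accuracy`, `n_truth_bilateral`,
#'   `n_truth_contra`.
#' @export
recovery_experiment <- function(seeds, n_units_per_cell = 50L,
                                thresholds = classifier_thresholds(),
                                config_fun = NULL) {
  if (is.null(config_fun)) {
    config_fun <- function(seed) {
      sim_config(n_units_per_cell = n_units_per_cell, seed = seed)
    }
  }
  bilateral_labels <- c("bilateral_independent", "bilateral_excitatory",
                        "bilateral_suppressive")
  rows <- lapply(seeds, function(seed) {
    ds <- simulate_cohort(config_fun(seed))
    cls <- classify_cohort(ds, thresholds)
    d <- merge(cls, ds$units, by = "unit_id")
    scored <- d[d$ground_truth %in% c(bilateral_labels, "contra_only"), ]
    truth <- scored$ground_truth %in% bilateral_labels
    pred <- scored$response_class == "bilateral"
    signed <- d[d$ground_truth %in% c("bilateral_excitatory",
                                      "bilateral_suppressive"), ]
    expected_sign <- ifelse(signed$ground_truth == "bilateral_excitatory",
                            "excitation", "suppression")
    data.frame(seed = seed,
               balanced_accuracy = balanced_accuracy(truth, pred),
               integration_accuracy =
                 if (nrow(signed)) mean(signed$integration_on ==
                                          expected_sign) else NA_real_,
               n_truth_bilateral = sum(truth),
               n_truth_contra = sum(!truth))
  })
  do.call(rbind, rows)
}

#' End-to-end detection power for the injected treatment effect
#'
#' Runs the full pipeline on default-preset cohorts (it injects a higher
#' baseline rate under light incubation) and records, per seed, whether the
#' Scheirer-Ray-Hare treatment effect on the spontaneous firing rate of the
#' bilateral population is significant.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param n_units_per_cell Units per cell.
#' @param alpha Significance level.
#' @return Data frame per seed: `seed`, `p_treatment`, `detected`.
#' @export
srh_power_experiment <- function(seeds, n_units_per_cell = 40L,
                                 alpha = 0.05) {
  rows <- lapply(seeds, function(seed) {
    ds <- simulate_cohort(sim_config(n_units_per_cell = n_units_per_cell,
                                     seed = seed))
    rep <- suppressWarnings(run_analysis(ds, verbose = FALSE))
    s <- rep$stats
    p <- s$p[s$population == "bilateral" &
               s$variable == "spontaneous_rate" & s$effect == "treatment"]
    p <- if (length(p)) p[1L] else NA_real_
    data.frame(seed = seed, p_treatment = p,
               detected = !is.na(p) && p < alpha)
  })
  do.call(rbind, rows)
}

#' Null calibration of the factorial rank test
#'
#' Draws balanced 2x2 samples from a single distribution and records the
#' rejection rate of each Scheirer-Ray-Hare effect, which should match the
#' nominal level.
#'
#' @param n_reps Number of replicates.
#' @param n_per_cell Observations per cell.
#' @param alpha Significance level.
#' @param rdist Sampling function `n -> numeric(n)`.
#' @return Named rejection rates for `treatment`, `hemisphere`,
#'   `interaction`.
#' @export
srh_null_calibration <- function(n_reps = 2000L, n_per_cell = 25L,
                                 alpha = 0.05, rdist = stats::rnorm) {
  fa <- rep(c("dark", "light"), each = 2L * n_per_cell)
  fb <- rep(rep(c("left", "right"), each = n_per_cell), 2L)
  rej <- matrix(FALSE, n_reps, 3L)
  for (i in seq_len(n_reps)) {
    res <- scheirer_ray_hare(rdist(4L * n_per_cell), fa, fb)
    rej[i, ] <- res$p < alpha
  }
  stats::setNames(colMeans(rej), c("treatment", "hemisphere", "interaction"))
}
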