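#' Classifier thresholds
#'
#' Tunable constants of the unit-selection procedure, with the analysis
#' defaults: a response window peak must be at least `responsiveness_fold`
#' (2x) any baseline-window peak and at least `min_peak_rate` (5 Hz) for a
#' unit to count as visually responsive; the ipsilateral peak must exceed
#' the baseline noise mean by `ipsi_sigma` (4) standard deviations to flag
#' bilateral integration; the rank-sum criteria fire at significance level
#' `alpha` (0.05).
#'
#' @param responsiveness_fold Fold change over the baseline peak (> 1).
#' @param min_peak_rate Absolute peak floor, Hz.
#' @param ipsi_sigma Noise s.d. multiples for the ipsilateral criterion.
#' @param alpha Two-sided significance level for the rank-sum criteria.
#' @return A `classifier_thresholds` list.
#' @export
classifier_thresholds <- function(responsiveness_fold = 2,
                                  min_peak_rate = 5,
                                  ipsi_sigma = 4,
                                  alpha = 0.05) {
  stopifnot(responsiveness_fold > 1, min_peak_rate >= 0, ipsi_sigma > 0,
            alpha > 0, alpha < 1)
  structure(list(responsiveness_fold = responsiveness_fold,
                 min_peak_rate = min_peak_rate,
                 ipsi_sigma = ipsi_sigma, alpha = alpha),
            class = "classifier_thresholds")
}

#' Visual responsiveness screen
#'
#' A unit is visually responsive if, in at least one stimulation condition,
#' its raw ON- or OFF-window peak rate is at least `responsiveness_fold`
#' times any peak occurring in that condition's baseline window AND at least
#' `min_peak_rate`. The fold rule compares raw (not baseline-subtracted)
#' peaks; a silent baseline (`pre_peak = 0`) leaves only the absolute floor.
#'
#' @param features A [extract_features()] result.
#' @param thresholds A [classifier_thresholds()].
#' @return Logical scalar.
#' @export
is_visually_responsive <- function(features,
                                   thresholds = classifier_thresholds()) {
  co <- features$conditions
  peaks <- cbind(co$on_peak_raw, co$off_peak_raw)
  pass <- peaks >= thresholds$responsiveness_fold * co$pre_peak &
    peaks >= thresholds$min_peak_rate
  any(pass)
}

#' Ipsilateral 4-sigma criterion
#'
#' First bilateral-integration criterion: the ipsilateral peak response must
#' stand `ipsi_sigma` standard deviations above the mean noise level. Noise
#' mean and s.d. are estimated from the ipsilateral PSTH's baseline-window
#' bin rates (the only stimulus-free estimate available for that condition).
#' If the baseline is silent (s.d. = 0), the criterion degenerates to
#' requiring a nonzero peak that clears the absolute `min_peak_rate` floor.
#'
#' @param psth_ipsi The ipsilateral-condition [compute_psth()].
#' @param thresholds A [classifier_thresholds()].
#' @return List with logicals `fired_ON`, `fired_OFF`.
#' @export
ipsi_sigma_criterion <- function(psth_ipsi,
                                 thresholds = classifier_thresholds()) {
  base <- psth_ipsi$rate[window_bins(psth_ipsi$protocol, "baseline")]
  mu <- mean(base)
  s <- stats::sd(base)
  check <- function(window) {
    peak <- window_peak(psth_ipsi, window)$peak
    if (s == 0) {
      peak > 0 && peak >= thresholds$min_peak_rate
    } else {
      peak > mu + thresholds$ipsi_sigma * s
    }
  }
  list(fired_ON = check("on"), fired_OFF = check("off"))
}

# Per-trial samples used by the rank-sum criteria: for the peak test, the
# spike count in the condition's own peak bin (located on the trial-averaged
# PSTH; earliest maximal bin) in Hz; for the rate test, the mean rate over
# the full ON or OFF window.
.trial_samples <- function(psth, window) {
  p <- psth$protocol
  pk <- window_peak(psth, window)
  peak_bin <- pk$bin
  if (is.na(peak_bin)) peak_bin <- which(window_bins(p, window))[1L]
  mask <- window_bins(p, window)
  list(peak = psth$trial_counts[, peak_bin] / p$bin_width,
       rate = rowSums(psth$trial_counts[, mask, drop = FALSE]) /
         window_duration(p, window))
}

#' Bilateral-vs-contralateral modulation tests
#'
#' Second and third bilateral-integration criteria: Wilcoxon rank-sum tests
#' with continuity correction comparing contralateral and bilateral trials
#' on (a) per-trial firing rates in each condition's own peak bin and (b)
#' per-trial mean rates over the full ON (or OFF) window. A significant test
#' indicates that concurrent ipsilateral stimulation modulates the
#' contralateral response.
#'
#' @param dataset A [spike_dataset()].
#' @param unit_id Unit identifier.
#' @param thresholds A [classifier_thresholds()].
#' @return List with p-values `peak_ON_p`, `peak_OFF_p`, `rate_ON_p`,
#'   `rate_OFF_p` and, for direction calls, the median bilateral-minus-
#'   contralateral differences `peak_ON_diff`, `peak_OFF_diff`,
#'   `rate_ON_diff`, `rate_OFF_diff`.
#' @export
bilateral_modulation_tests <- function(dataset, unit_id,
                                       thresholds = classifier_thresholds()) {
  ps_c <- compute_psth(dataset, unit_id, "contra")
  ps_b <- compute_psth(dataset, unit_id, "bilateral")
  out <- list()
  for (w in c("on", "off")) {
    sc <- .trial_samples(ps_c, w)
    sb <- .trial_samples(ps_b, w)
    W <- toupper(w)
    for (kind in c("peak", "rate")) {
      test <- wilcoxon_ranksum_cc(sc[[kind]], sb[[kind]])
      out[[paste0(kind, "_", W, "_p")]] <- test$p_two_sided
      out[[paste0(kind, "_", W, "_diff")]] <-
        stats::median(sb[[kind]]) - stats::median(sc[[kind]])
    }
  }
  out
}

#' Classify one unit
#'
#' Applies the full selection procedure: the responsiveness screen, then the
#' three bilateral-integration criteria (ipsilateral sigma criterion and the
#' two rank-sum criteria, each on ON and OFF windows — six flags in all). A
#' responsive unit is `bilateral` if any flag fires, else `contralateral`;
#' non-responsive units are `none`. For bilateral units, integration sign
#' per window is `excitation`/`suppression` when the peak or rate test for
#' that window is significant, with direction from the sign of the median
#' bilateral-minus-contralateral difference (the significant peak test is
#' consulted first; a tied peak median defers to the significant rate test,
#' and fully tied medians give `none`).
#'
#' @param dataset A [spike_dataset()].
#' @param unit_id Unit identifier.
#' @param thresholds A [classifier_thresholds()].
#' @param features Optional precomputed [extract_features()] result.
#' @return One-row data frame: `unit_id`, `visually_responsive`,
#'   `response_class`, `criteria_fired` (comma-joined flag names),
#'   `integration_on`, `integration_off`.
#' @export
classify_unit <- function(dataset, unit_id,
                          thresholds = classifier_thresholds(),
                          features = NULL) {
  if (is.null(features)) features <- extract_features(dataset, unit_id)
  responsive <- is_visually_responsive(features, thresholds)
  row <- data.frame(unit_id = unit_id, visually_responsive = responsive,
                    response_class = "none", criteria_fired = "",
                    integration_on = "none", integration_off = "none",
                    stringsAsFactors = FALSE)
  if (!responsive) return(row)

  sig <- ipsi_sigma_criterion(compute_psth(dataset, unit_id, "ipsi"),
                              thresholds)
  mod <- bilateral_modulation_tests(dataset, unit_id, thresholds)
  a <- thresholds$alpha
  fired <- c(ipsi_sigma_ON = sig$fired_ON,
             ipsi_sigma_OFF = sig$fired_OFF,
             peak_wilcoxon_ON = mod$peak_ON_p < a,
             peak_wilcoxon_OFF = mod$peak_OFF_p < a,
             rate_wilcoxon_ON = mod$rate_ON_p < a,
             rate_wilcoxon_OFF = mod$rate_OFF_p < a)
  bilateral <- any(fired)
  row$response_class <- if (bilateral) "bilateral" else "contralateral"
  row$criteria_fired <- paste(names(fired)[fired], collapse = ",")

  integration <- function(W) {
    peak_sig <- mod[[paste0("peak_", W, "_p")]] < a
    rate_sig <- mod[[paste0("rate_", W, "_p")]] < a
    if (!bilateral || (!peak_sig && !rate_sig)) return("none")
    # Direction from the significant tests' median differences: the peak
    # test is consulted first, but a tied peak median (common for sparse
    # peak-bin counts) defers to the rate test's direction; only fully tied
    # medians yield "none".
    diffs <- c(if (peak_sig) mod[[paste0("peak_", W, "_diff")]],
               if (rate_sig) mod[[paste0("rate_", W, "_diff")]])
    d <- diffs[diffs != 0][1L]
    if (is.na(d)) "none" else if (d > 0) "excitation" else "suppression"
  }
  row$integration_on <- integration("ON")
  row$integration_off <- integration("OFF")
  row
}

#' Classify every unit in a dataset
#'
#' @param dataset A [spike_dataset()].
#' @param thresholds A [classifier_thresholds()].
#' @return Data frame with one [classify_unit()] row per unit.
#' @export
classify_cohort <- function(dataset, thresholds = classifier_thresholds()) {
  views <- split_by_unit(dataset)
  rows <- lapply(dataset$units$unit_id, function(uid) {
    classify_unit(views[[uid]], uid, thresholds)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
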