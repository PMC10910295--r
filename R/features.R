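#' Peristimulus time histogram for one unit and condition
#'
#' Bins each trial's spikes into the protocol's half-open bins and averages
#' over trials: `rate[b] = sum_trials count[trial, b] / (n_trials * bin_width)`.
#' The per-trial count matrix is retained because the classifier's rank-sum
#' tests operate on per-trial samples.
#'
#' @param dataset A [spike_dataset()].
#' @param unit_id Unit identifier.
#' @param condition Condition label.
#' @return An object of class `psth` with fields `unit_id`, `condition`,
#'   `bin_edges`, `rate` (Hz per bin) and `trial_counts`
#'   (`n_trials x n_bins` matrix of spike counts).
#' @export
compute_psth <- function(dataset, unit_id, condition) {
  p <- dataset$protocol
  if (!unit_id %in% dataset$units$unit_id) {
    stop("unknown unit '", unit_id, "'", call. = FALSE)
  }
  if (!condition %in% p$conditions) {
    stop("unknown condition '", condition, "'", call. = FALSE)
  }
  nb <- n_bins(p)
  sel <- dataset$spikes$unit_id == unit_id &
    dataset$spikes$condition == condition
  t <- dataset$spikes$spike_time_s[sel]
  trial <- dataset$spikes$trial[sel]
  counts <- matrix(0L, nrow = p$n_trials, ncol = nb)
  if (length(t)) {
    b <- time_to_bin(t, p)
    idx <- trial * nb + b   # trial is 0-based
    tab <- tabulate(idx, nbins = p$n_trials * nb)
    counts <- matrix(tab, nrow = p$n_trials, ncol = nb, byrow = TRUE)
  }
  structure(list(unit_id = unit_id, condition = condition,
                 bin_edges = bin_edges(p),
                 rate = colSums(counts) / (p$n_trials * p$bin_width),
                 trial_counts = counts,
                 protocol = p),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat("<psth>", x$unit_id, "/", x$condition, "-", length(x$rate),
      "bins, peak", round(max(x$rate), 2), "Hz\n")
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  centers <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
  plot(centers, x$rate, type = "s", xlab = "time from onset (s)",
       ylab = "rate (Hz)",
       main = paste(x$unit_id, x$condition, sep = " / "), ...)
  abline(v = c(0, x$protocol$stim_duration), lty = 2, col = "grey40")
  invisible(x)
}

# Peak (max bin rate) and latency (center of the earliest maximal bin,
# relative to the window start) within one analysis window of a PSTH.
window_peak <- function(psth, window) {
  p <- psth$protocol
  mask <- window_bins(p, window)
  r <- psth$rate[mask]
  left <- psth$bin_edges[-(n_bins(p) + 1L)][mask]
  peak <- max(r)
  if (peak <= 0) {
    return(list(peak = 0, latency = NA_real_, bin = NA_integer_))
  }
  i <- which(r == peak)[1L]          # earliest maximal bin
  start <- switch(window, baseline = -p$pre_window, on = 0,
                  off = p$stim_duration)
  list(peak = peak,
       latency = left[i] + p$bin_width / 2 - start,
       bin = which(mask)[i])
}

#' Response features of one unit
#'
#' Extracts the dependent variables of the factorial analysis from the
#' unit's three PSTHs:
#' * `spontaneous_rate`: mean rate over the baseline window, averaged across
#'   the three stimulation conditions;
#' * per condition: raw ON/OFF peak rates (max bin rate in the stimulus /
#'   post-offset window), baseline-subtracted peaks (raw minus the
#'   cross-condition spontaneous rate), peak latencies (center of the
#'   earliest maximal bin, measured from the start of its window), and
#'   `pre_peak`, the maximal baseline-window bin rate of that condition
#'   (used by the responsiveness screen).
#'
#' Latencies of windows with no spikes are `NA` and are excluded from
#' downstream statistics. Because baseline subtraction shifts all bins by a
#' constant, peak latency is the same whether measured on raw or subtracted
#' rates.
#'
#' @param dataset A [spike_dataset()].
#' @param unit_id Unit identifier.
#' @return An object of class `response_features`: a list with
#'   `unit_id`, `spontaneous_rate`, and `conditions`, a data frame with one
#'   row per condition and columns `pre_peak`, `on_peak_raw`, `off_peak_raw`,
#'   `on_peak_sub`, `off_peak_sub`, `on_latency`, `off_latency`.
#' @export
extract_features <- function(dataset, unit_id) {
  p <- dataset$protocol
  psths <- lapply(p$conditions, function(cond) {
    compute_psth(dataset, unit_id, cond)
  })
  base_mask <- window_bins(p, "baseline")
  base_means <- vapply(psths, function(ps) mean(ps$rate[base_mask]), 0)
  spont <- mean(base_means)
  rows <- lapply(seq_along(psths), function(i) {
    ps <- psths[[i]]
    on <- window_peak(ps, "on")
    off <- window_peak(ps, "off")
    pre <- window_peak(ps, "baseline")
    data.frame(condition = p$conditions[i],
               pre_peak = pre$peak,
               on_peak_raw = on$peak, off_peak_raw = off$peak,
               on_peak_sub = on$peak - spont, off_peak_sub = off$peak - spont,
               on_latency = on$latency, off_latency = off$latency,
               stringsAsFactors = FALSE)
  })
  structure(list(unit_id = unit_id, spontaneous_rate = spont,
                 conditions = do.call(rbind, rows)),
            class = "response_features")
}

#' @export
print.response_features <- function(x, ...) {
  cat("<response_features>", x$unit_id, "- spontaneous",
      round(x$spontaneous_rate, 2), "Hz\n")
  print(x$conditions)
  invisible(x)
}

#' Feature table for all units
#'
#' Runs [extract_features()] on every unit and flattens the result into one
#' wide row per unit (columns `<condition>_<feature>`), joined with the unit
#' metadata. This is the table the factorial statistics consume.
#'
#' @param dataset A [spike_dataset()].
#' @return Data frame, one row per unit.
#' @export
extract_features_all <- function(dataset) {
  views <- split_by_unit(dataset)
  rows <- lapply(dataset$units$unit_id, function(uid) {
    f <- extract_features(views[[uid]], uid)
    wide <- list(unit_id = uid, spontaneous_rate = f$spontaneous_rate)
    for (i in seq_len(nrow(f$conditions))) {
      cond <- f$conditions$condition[i]
      for (col in c("pre_peak", "on_peak_raw", "off_peak_raw", "on_peak_sub",
                    "off_peak_sub", "on_latency", "off_latency")) {
        wide[[paste(cond, col, sep = "_")]] <- f$conditions[[col]][i]
      }
    }
    as.data.frame(wide, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  merge(dataset$units, out, by = "unit_id", sort = TRUE)
}
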