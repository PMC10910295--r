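# Shared fixture builders: crafted datasets with exactly known PSTHs, plus
# small constructors mirroring the package's S3 shapes for unit-level tests.

default_protocol <- function(n_trials = 40L) stim_protocol(n_trials = n_trials)

# Dataset with a single unit and given spike rows (possibly none).
one_unit_dataset <- function(spikes = NULL, protocol = default_protocol(),
                             treatment = "dark", hemisphere = "left") {
  units <- data.frame(unit_id = "u1", subject_id = "s1",
                      treatment = treatment, hemisphere = hemisphere,
                      stringsAsFactors = FALSE)
  if (is.null(spikes)) {
    spikes <- data.frame(unit_id = character(), condition = character(),
                         trial = integer(), spike_time_s = numeric())
  }
  spike_dataset(protocol, units, spikes)
}

# Spike rows realising an exact per-bin total count for one unit/condition:
# `counts[b]` spikes are placed in bin b, one per trial (trials 0, 1, ...),
# at distinct times inside the bin. Requires counts[b] <= n_trials.
spikes_for_bin_counts <- function(counts, condition,
                                  protocol = default_protocol(),
                                  unit_id = "u1") {
  edges <- bin_edges(protocol)
  rows <- list()
  for (b in seq_along(counts)) {
    k <- counts[b]
    if (k == 0) next
    stopifnot(k <= protocol$n_trials)
    t0 <- edges[b] + protocol$bin_width / 4
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = unit_id, condition = condition,
      trial = seq_len(k) - 1L,
      spike_time_s = t0 + (seq_len(k) - 1L) * protocol$bin_width / (4 * k),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(unit_id = character(), condition = character(),
                      trial = integer(), spike_time_s = numeric()))
  }
  do.call(rbind, rows)
}

# A response_features object with one condition row per condition, built the
# same shape extract_features() returns, for direct classifier-rule tests.
make_features <- function(pre_peak, on_peak, off_peak = 0, spont = 0,
                          conditions = c("contra", "ipsi", "bilateral")) {
  n <- length(conditions)
  structure(list(
    unit_id = "u1", spontaneous_rate = spont,
    conditions = data.frame(
      condition = conditions,
      pre_peak = rep_len(pre_peak, n),
      on_peak_raw = rep_len(on_peak, n),
      off_peak_raw = rep_len(off_peak, n),
      on_peak_sub = rep_len(on_peak, n) - spont,
      off_peak_sub = rep_len(off_peak, n) - spont,
      on_latency = 0.1, off_latency = 0.1,
      stringsAsFactors = FALSE)),
    class = "response_features")
}

# A psth object with a prescribed trial-averaged rate vector (trial counts
# left at zero; only rate-based criteria may be exercised against it).
make_psth <- function(rate, protocol = default_protocol(),
                      condition = "ipsi") {
  stopifnot(length(rate) == n_bins(protocol))
  structure(list(unit_id = "u1", condition = condition,
                 bin_edges = bin_edges(protocol), rate = rate,
                 trial_counts = matrix(0L, protocol$n_trials,
                                       n_bins(protocol)),
                 protocol = protocol),
            class = "psth")
}

# Exact two-sided rank-sum p-value by enumerating all choose(N, n1)
# assignments of the joint ranks to the first sample.
exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (length(y)) / 2
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(N, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
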