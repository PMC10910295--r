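test_that("PSTH bin rates follow the trial-averaged count formula", {
  p <- default_protocol()
  # One spike per trial at t = 0.110 over 40 trials: the bin [0.100, 0.125)
  # carries rate 1/0.025 = 40 Hz, every other bin is silent.
  sp <- data.frame(unit_id = "u1", condition = "contra",
                   trial = 0:39, spike_time_s = 0.110 + (0:39) * 1e-6)
  ds <- one_unit_dataset(sp)
  psth <- compute_psth(ds, "u1", "contra")
  hot <- which(psth$rate > 0)
  expect_length(hot, 1L)
  expect_equal(psth$bin_edges[hot], 0.100)
  expect_equal(psth$rate[hot], 40)
  expect_error(compute_psth(ds, "nope", "contra"), "unknown unit")
  expect_error(compute_psth(ds, "u1", "nope"), "unknown condition")
})

test_that("PSTH mass is conserved and sampling noise matches Poisson", {
  p <- default_protocol()
  a <- unit_archetype("contra_only", 10, c(contra = 0, ipsi = 0,
                                           bilateral = 0),
                      c(contra = 0, ipsi = 0, bilateral = 0))
  set.seed(31)
  ds <- spike_dataset(p, data.frame(unit_id = "u1", subject_id = "s1",
                                    treatment = "dark", hemisphere = "left"),
                      simulate_unit(a, p, "u1"))
  for (cond in p$conditions) {
    psth <- compute_psth(ds, "u1", cond)
    total <- sum(ds$spikes$condition == cond)
    expect_equal(sum(psth$rate) * p$bin_width * p$n_trials, total)
    # Homogeneous 10 Hz: nearly all bins within 3 s.e. of the rate.
    se <- sqrt(10 / (p$n_trials * p$bin_width))
    expect_gte(mean(abs(psth$rate - 10) <= 3 * se), 0.95)
  }
})

test_that("peak, latency and spontaneous-rate definitions are exact", {
  p <- default_protocol()
  # ON-window bin rates 2, 10, 30, 8 in the first four ON bins: with 40
  # trials, a rate of r Hz needs exactly r spikes in the 25-ms bin.
  on_counts <- integer(n_bins(p))
  on_counts[41:44] <- c(2, 10, 30, 8)   # ON window starts at bin 41
  sp <- spikes_for_bin_counts(on_counts, "contra", p)
  ds <- one_unit_dataset(sp)
  f <- extract_features(ds, "u1")
  contra <- f$conditions[f$conditions$condition == "contra", ]
  expect_equal(contra$on_peak_raw, 30)
  expect_equal(contra$on_latency, 0.0625)  # center of [0.050, 0.075)
  expect_equal(contra$off_peak_raw, 0)
  expect_true(is.na(contra$off_latency))   # silent window: no latency

  # Latency ties break toward the earliest maximal bin.
  tie_counts <- integer(n_bins(p))
  tie_counts[c(45, 50)] <- 20L
  f2 <- extract_features(one_unit_dataset(
    spikes_for_bin_counts(tie_counts, "contra", p)), "u1")
  expect_equal(f2$conditions$on_latency[1], 4 * 0.025 + 0.0125)

  # Spontaneous rate averages the three per-condition baseline means:
  # baselines of 4, 5, 6 Hz give 5 Hz.
  base <- function(rate, cond) {
    counts <- integer(n_bins(p))
    counts[1:40] <- rate   # r spikes per 25-ms bin over 40 trials = r Hz
    spikes_for_bin_counts(counts, cond, p)
  }
  sp3 <- rbind(base(4, "contra"), base(5, "ipsi"), base(6, "bilateral"))
  f3 <- extract_features(one_unit_dataset(sp3), "u1")
  expect_equal(f3$spontaneous_rate, 5)
  expect_equal(f3$conditions$on_peak_sub,
               f3$conditions$on_peak_raw - 5)
})

test_that("features are invariant to trial relabeling and spike order", {
  set.seed(33)
  cfg <- sim_config(n_units_per_cell = 2L, seed = 41L)
  ds <- simulate_cohort(cfg)
  uid <- ds$units$unit_id[1]
  f1 <- extract_features(ds, uid)
  # Permute trial labels within each condition and shuffle row order.
  sp <- ds$spikes
  for (cond in ds$protocol$conditions) {
    sel <- sp$unit_id == uid & sp$condition == cond
    perm <- sample(0:39)
    sp$trial[sel] <- perm[sp$trial[sel] + 1L]
  }
  sp <- sp[sample(nrow(sp)), ]
  ds2 <- spike_dataset(ds$protocol, ds$units, sp)
  f2 <- extract_features(ds2, uid)
  expect_equal(f2$spontaneous_rate, f1$spontaneous_rate)
  expect_equal(f2$conditions, f1$conditions)
})

test_that("estimated peak latency converges to the generative latency", {
  p <- stim_protocol(n_trials = 2000L)
  a <- unit_archetype("contra_only", 4,
                      c(contra = 40, ipsi = 0, bilateral = 40),
                      c(contra = 12, ipsi = 0, bilateral = 12),
                      on_latency = 0.31, off_latency = 0.22,
                      transient_width = 0.04)
  set.seed(35)
  ds <- spike_dataset(p, data.frame(unit_id = "u1", subject_id = "s1",
                                    treatment = "dark", hemisphere = "left"),
                      simulate_unit(a, p, "u1"))
  f <- extract_features(ds, "u1")
  contra <- f$conditions[f$conditions$condition == "contra", ]
  expect_lt(abs(contra$on_latency - 0.31), p$bin_width + 1e-9)
  expect_lt(abs(contra$off_latency - 0.22), p$bin_width + 1e-9)
})
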