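#' Unit response archetype
#'
#' Generative description of one unit's firing: a constant baseline plus
#' transient ON and OFF Gaussian bumps whose amplitudes depend on the
#' stimulation condition. The instantaneous rate is
#' \deqn{\lambda_c(t) = \max\{0,\; b + A^{on}_c\, g(t; \ell_{on}, w) +
#'   A^{off}_c\, g(t - d; \ell_{off}, w)\}}
#' with `g` a unit-peak Gaussian, `d` the stimulus duration, and clipping at
#' zero so suppressive bilateral interactions (negative relative amplitudes)
#' stay physical.
#'
#' Archetype labels encode the ground-truth class used by recovery tests:
#' * `nonresponsive` — baseline only;
#' * `contra_only` — responds to the contralateral eye, bilateral response
#'   identical to contralateral, no ipsilateral response;
#' * `bilateral_independent` — adds an ipsilateral response but no
#'   contra/bilateral modulation;
#' * `bilateral_excitatory` — bilateral amplitude above contralateral;
#' * `bilateral_suppressive` — bilateral amplitude below contralateral.
#'
#' @param label Archetype label (see above).
#' @param baseline_rate Baseline rate, Hz.
#' @param on_amp,off_amp Named numeric vectors (one entry per condition) of
#'   transient peak amplitudes above baseline, Hz. May be negative for
#'   suppression; the rate is clipped at zero.
#' @param on_latency Center of the ON transient after onset, seconds.
#' @param off_latency Center of the OFF transient after offset, seconds.
#' @param transient_width Gaussian s.d. of the transients, seconds.
#' @return An object of class `unit_archetype`.
#' @export
unit_archetype <- function(label,
                           baseline_rate,
                           on_amp,
                           off_amp,
                           on_latency = 0.1,
                           off_latency = 0.15,
                           transient_width = 0.04) {
  labels <- c("nonresponsive", "contra_only", "bilateral_independent",
              "bilateral_excitatory", "bilateral_suppressive")
  if (!label %in% labels) {
    stop("unknown archetype label '", label, "'", call. = FALSE)
  }
  stopifnot(baseline_rate >= 0, transient_width > 0,
            on_latency > 0, off_latency > 0)
  conds <- c("contra", "ipsi", "bilateral")
  on_amp <- on_amp[conds]
  off_amp <- off_amp[conds]
  if (anyNA(on_amp) || anyNA(off_amp)) {
    stop("on_amp and off_amp must be named for contra, ipsi and bilateral",
         call. = FALSE)
  }
  structure(list(label = label, baseline_rate = baseline_rate,
                 on_amp = on_amp, off_amp = off_amp,
                 on_latency = on_latency, off_latency = off_latency,
                 transient_width = transient_width),
            class = "unit_archetype")
}

#' Instantaneous firing rate of an archetype
#'
#' @param archetype A [unit_archetype()].
#' @param condition One of the protocol's condition labels.
#' @param t Time(s) in seconds relative to stimulus onset; vectorised.
#' @param protocol A [stim_protocol()] (supplies the stimulus duration that
#'   anchors the OFF transient).
#' @return Rate(s) in Hz, clipped at zero.
#' @export
rate_function <- function(archetype, condition, t, protocol = stim_protocol()) {
  a <- archetype
  g <- function(x, mu) exp(-((x - mu)^2) / (2 * a$transient_width^2))
  lam <- a$baseline_rate +
    a$on_amp[[condition]] * g(t, a$on_latency) +
    a$off_amp[[condition]] * g(t - protocol$stim_duration, a$off_latency)
  pmax(lam, 0)
}

#' Simulate one unit's spike trains
#'
#' Draws an inhomogeneous Poisson process per trial and condition by
#' Lewis-Shedler thinning: candidate spikes from a homogeneous process at the
#' majorant rate `baseline + max(0, on_amp) + max(0, off_amp)` are kept with
#' probability `rate(t) / majorant`. Trials are independent; output times are
#' sorted within trial.
#'
#' @param archetype A [unit_archetype()].
#' @param protocol A [stim_protocol()].
#' @param unit_id Identifier stamped on the rows.
#' @return Data frame `unit_id, condition, trial, spike_time_s` (a valid
#'   `spikes` block for [spike_dataset()]).
#' @export
simulate_unit <- function(archetype, protocol = stim_protocol(),
                          unit_id = "u1") {
  lo <- -protocol$pre_window
  hi <- protocol$stim_duration + protocol$post_window
  total <- hi - lo
  out <- vector("list", length(protocol$conditions))
  for (k in seq_along(protocol$conditions)) {
    cond <- protocol$conditions[k]
    lam_max <- archetype$baseline_rate +
      max(0, archetype$on_amp[[cond]]) + max(0, archetype$off_amp[[cond]])
    if (lam_max <= 0) {
      out[[k]] <- data.frame(unit_id = character(), condition = character(),
                             trial = integer(), spike_time_s = numeric())
      next
    }
    counts <- stats::rpois(protocol$n_trials, lam_max * total)
    n <- sum(counts)
    t <- stats::runif(n, lo, hi)
    trial <- rep(seq_len(protocol$n_trials) - 1L, counts)
    keep <- stats::runif(n) < rate_function(archetype, cond, t, protocol) /
      lam_max
    t <- t[keep]
    trial <- trial[keep]
    ord <- order(trial, t)
    out[[k]] <- data.frame(unit_id = rep(unit_id, length(t)),
                           condition = rep(cond, length(t)),
                           trial = trial[ord], spike_time_s = t[ord],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-cell cohort effects
#'
#' Multiplicative and additive modifiers applied to archetype parameters in
#' each (treatment, hemisphere) cell, plus the archetype mixture of the cell.
#' These are the simulator's knobs for injecting treatment, hemisphere and
#' interaction effects with known ground truth.
#'
#' @param baseline_mult,amp_mult Positive multipliers on baseline rate and on
#'   all transient amplitudes.
#' @param latency_shift Additive shift on ON/OFF latencies, seconds
#'   (negative = faster responses).
#' @param mixture Named numeric vector of archetype proportions; must sum
#'   to 1.
#' @return A `cell_effects` list.
#' @export
cell_effects <- function(baseline_mult = 1, amp_mult = 1, latency_shift = 0,
                         mixture = c(contra_only = 0.40,
                                     bilateral_independent = 0.25,
                                     bilateral_excitatory = 0.15,
                                     bilateral_suppressive = 0.10,
                                     nonresponsive = 0.10)) {
  stopifnot(baseline_mult > 0, amp_mult > 0)
  if (abs(sum(mixture) - 1) > 1e-8 || any(mixture < 0)) {
    stop("mixture proportions must be nonnegative and sum to 1",
         call. = FALSE)
  }
  structure(list(baseline_mult = baseline_mult, amp_mult = amp_mult,
                 latency_shift = latency_shift, mixture = mixture),
            class = "cell_effects")
}

#' Default archetype templates
#'
#' Template parameters for the five archetypes, before per-cell scaling and
#' per-unit jitter. Amplitudes are deliberately strong relative to the
#' trial-averaged PSTH noise floor (baseline 4 Hz over 25-ms bins and 40
#' trials gives a per-bin s.e. of 2 Hz, so the 40-Hz contralateral ON
#' transient sits 20 noise s.d. above baseline) and bilateral/contralateral
#' contrasts are at least 50% (excitatory 2x, suppressive 0.4x), the regime
#' in which the classifier is expected to recover ground truth.
#'
#' @param baseline_rate Baseline rate, Hz.
#' @param contra_on,contra_off Contralateral ON/OFF amplitudes, Hz.
#' @param ipsi_on Ipsilateral ON amplitude for bilateral archetypes, Hz.
#' @param excit_gain Bilateral/contralateral ON amplitude ratio for the
#'   excitatory archetype.
#' @param suppress_gain Same ratio for the suppressive archetype.
#' @return Named list of [unit_archetype()] objects.
#' @export
archetype_templates <- function(baseline_rate = 4,
                                contra_on = 40, contra_off = 12,
                                ipsi_on = 20,
                                excit_gain = 2.0, suppress_gain = 0.4) {
  amp <- function(contra, ipsi, bilateral) {
    c(contra = contra, ipsi = ipsi, bilateral = bilateral)
  }
  list(
    nonresponsive = unit_archetype(
      "nonresponsive", baseline_rate, amp(0, 0, 0), amp(0, 0, 0)),
    contra_only = unit_archetype(
      "contra_only", baseline_rate,
      amp(contra_on, 0, contra_on), amp(contra_off, 0, contra_off)),
    bilateral_independent = unit_archetype(
      "bilateral_independent", baseline_rate,
      amp(contra_on, ipsi_on, contra_on),
      amp(contra_off, 0.5 * contra_off, contra_off)),
    bilateral_excitatory = unit_archetype(
      "bilateral_excitatory", baseline_rate,
      amp(contra_on, 0.2 * ipsi_on, excit_gain * contra_on),
      amp(contra_off, 0, contra_off)),
    bilateral_suppressive = unit_archetype(
      "bilateral_suppressive", baseline_rate,
      amp(contra_on, 0.2 * ipsi_on, suppress_gain * contra_on),
      amp(contra_off, 0, suppress_gain * contra_off))
  )
}

#' Default cohort effects preset
#'
#' Encodes the qualitative directions the analysis is designed to detect:
#' light incubation raises baseline activity and response amplitudes in both
#' hemispheres and speeds responses up, while dark-incubated animals carry a
#' right-hemisphere advantage (stronger, faster responses and a higher share
#' of bilaterally integrating units). Magnitudes are the package's own
#' documented choices; they set directions, not fitted values.
#'
#' @return Named list of [cell_effects()], one per
#'   `treatment_hemisphere` cell (`dark_left`, `dark_right`, `light_left`,
#'   `light_right`).
#' @export
default_cohort_effects <- function() {
  mix <- function(bi_shift = 0) {
    m <- c(contra_only = 0.40 - bi_shift,
           bilateral_independent = 0.25 + bi_shift,
           bilateral_excitatory = 0.15,
           bilateral_suppressive = 0.10,
           nonresponsive = 0.10)
    m / sum(m)
  }
  list(
    dark_left = cell_effects(baseline_mult = 1.00, amp_mult = 1.00,
                             latency_shift = 0.000, mixture = mix(0)),
    dark_right = cell_effects(baseline_mult = 1.15, amp_mult = 1.25,
                              latency_shift = -0.025, mixture = mix(0.05)),
    light_left = cell_effects(baseline_mult = 1.50, amp_mult = 1.50,
                              latency_shift = -0.050, mixture = mix(0.05)),
    light_right = cell_effects(baseline_mult = 1.50, amp_mult = 1.40,
                               latency_shift = -0.050, mixture = mix(0))
  )
}

#' Simulation configuration
#'
#' @param protocol A [stim_protocol()].
#' @param n_units_per_cell Units per (treatment, hemisphere) cell.
#' @param templates Archetype templates, see [archetype_templates()].
#' @param effects Per-cell effects, see [default_cohort_effects()].
#' @param jitter_sdlog Log-normal s.d. of per-unit multiplicative jitter on
#'   baseline and amplitudes (0 disables jitter).
#' @param seed Integer seed; fixed seed gives bit-reproducible cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(protocol = stim_protocol(),
                       n_units_per_cell = 50L,
                       templates = archetype_templates(),
                       effects = default_cohort_effects(),
                       jitter_sdlog = 0.25,
                       seed = 1L) {
  stopifnot(n_units_per_cell >= 1L, jitter_sdlog >= 0)
  cells <- c("dark_left", "dark_right", "light_left", "light_right")
  if (!all(cells %in% names(effects))) {
    stop("effects must name all four treatment x hemisphere cells",
         call. = FALSE)
  }
  structure(list(protocol = protocol,
                 n_units_per_cell = as.integer(n_units_per_cell),
                 templates = templates, effects = effects,
                 jitter_sdlog = jitter_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

# Apply cell effects + per-unit jitter to a template archetype.
scale_archetype <- function(template, eff, jitter_sdlog) {
  j_base <- if (jitter_sdlog > 0) stats::rlnorm(1, 0, jitter_sdlog) else 1
  j_amp <- if (jitter_sdlog > 0) stats::rlnorm(1, 0, jitter_sdlog) else 1
  unit_archetype(
    label = template$label,
    baseline_rate = template$baseline_rate * eff$baseline_mult * j_base,
    on_amp = template$on_amp * eff$amp_mult * j_amp,
    off_amp = template$off_amp * eff$amp_mult * j_amp,
    on_latency = max(0.02, template$on_latency + eff$latency_shift),
    off_latency = max(0.02, template$off_latency + eff$latency_shift),
    transient_width = template$transient_width
  )
}

#' Simulate a cohort of units across the four incubation x hemisphere cells
#'
#' For each (treatment, hemisphere) cell, draws archetype labels from the
#' cell's mixture, applies the cell's effects and per-unit log-normal jitter
#' to the template parameters, and simulates spike trains by thinning
#' (see [simulate_unit()]). The drawn archetype label is stored as
#' `ground_truth` in the unit metadata. One simulated subject is assigned
#' per block of 10 units to mimic multi-animal recordings.
#'
#' @param config A [sim_config()].
#' @return A validated [spike_dataset()] with ground truth.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cells <- data.frame(
    cell = c("dark_left", "dark_right", "light_left", "light_right"),
    treatment = c("dark", "dark", "light", "light"),
    hemisphere = c("left", "right", "left", "right"),
    stringsAsFactors = FALSE)
  units <- list()
  spikes <- list()
  for (i in seq_len(nrow(cells))) {
    eff <- config$effects[[cells$cell[i]]]
    labels <- sample(names(eff$mixture), config$n_units_per_cell,
                     replace = TRUE, prob = eff$mixture)
    for (u in seq_len(config$n_units_per_cell)) {
      uid <- sprintf("%s_%03d", cells$cell[i], u)
      arch <- scale_archetype(config$templates[[labels[u]]], eff,
                              config$jitter_sdlog)
      spikes[[uid]] <- simulate_unit(arch, config$protocol, uid)
      units[[uid]] <- data.frame(
        unit_id = uid,
        subject_id = sprintf("%s_chick%02d", cells$cell[i], (u - 1L) %/% 10L + 1L),
        treatment = cells$treatment[i],
        hemisphere = cells$hemisphere[i],
        ground_truth = labels[u],
        stringsAsFactors = FALSE)
    }
  }
  spike_dataset(config$protocol,
                do.call(rbind, units),
                do.call(rbind, spikes))
}
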