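---
title: "Analysing lateralized visual responses in single-unit recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing lateralized visual responses in single-unit recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entolat)
```

## The scientific problem

In birds, visual input from each eye crosses almost completely at the optic
chiasm, and the tectofugal pathway re-crosses part of it on the way to the
entopallium, the primary visual area of the avian telencephalon. A single
entopallial unit can therefore respond to the contralateral eye only, or
integrate input from both eyes. Whether that integration — and visual
responsiveness in general — is lateralized between hemispheres, and how
light exposure of the embryo changes it, is a question asked of single-unit
recordings under three stimulation conditions: a 1-s flash to the
contralateral eye, to the ipsilateral eye, or to both eyes at once, each
repeated 40 times with a 4-s inter-stimulus interval.

`entolat` implements the full analysis chain for such recordings:

1. **PSTH features** — per unit and condition, a 25-ms-bin peristimulus
   time histogram over `[-1, 2]` s around stimulus onset, from which five
   dependent variables are read: the spontaneous rate (baseline window,
   averaged across conditions), the ON and OFF peak rates (maximal bin rate
   during the stimulus second and the second after offset, baseline
   subtracted for the statistics), and the ON and OFF peak latencies
   (center of the peak bin, measured from the start of its window).
2. **Unit selection** — a responsiveness screen (a response-window peak at
   least two-fold above any baseline-window peak, and at least 5 Hz),
   followed by a three-criterion separation of *bilaterally* from
   *contralaterally* responsive units, and excitation/suppression typing of
   the bilateral ones.
3. **Rank-based factorial statistics** — for each dependent variable, a
   Scheirer-Ray-Hare test of treatment (dark vs light incubation) by
   hemisphere (left vs right), Kruskal-Wallis eta-squared effect sizes,
   Dunn post-hoc comparisons of the four cells when the interaction is
   significant, and a pooled two-proportion z test for comparing the
   bilateral share against a reference population.
4. **Simulation** — an inhomogeneous-Poisson cohort generator with known
   ground truth, used to validate the classifier and the statistics by
   parameter recovery.

Because rates, peaks and latencies are analysed with rank statistics, every
result is invariant under monotone transformations of the dependent
variable; no distributional assumption beyond exchangeability under the
null is made.

## Time conventions and binning

Spike times are seconds relative to stimulus onset. The analysis window is
`[-pre_window, stim_duration + post_window]`, by default `[-1, 2]` s; the
baseline window is `[-1, 0)`, the ON window `[0, 1)` and the OFF window
`[1, 2)`, all half-open. Bin membership is `floor((t + pre_window) /
bin_width)`, which is bit-reproducible; a spike exactly on the closed upper
end of the window folds into the last bin so that boundary spikes are never
dropped. With the defaults this gives 120 bins of 25 ms.

Peak latency is the center of the earliest maximal bin, measured from the
start of its own window (ON latencies from onset, OFF latencies from
offset, both on a 0–1 s scale). Ties are broken toward the earliest bin:
the analysis measures response onset, and an earliest-bin rule is
deterministic. Baseline subtraction shifts all bins by the same constant,
so latency is identical whether measured on raw or subtracted rates. A
window with no spikes has no peak; its latency is `NA` and that unit is
dropped from latency statistics only (fabricating a latency for a silent
window would bias the latency distributions toward whatever sentinel was
chosen).

## The selection procedure and its conventions

A unit is **visually responsive** if in at least one condition the raw ON
or OFF peak is at least `responsiveness_fold` (2) times that condition's
own baseline-window peak and at least `min_peak_rate` (5 Hz). Both
thresholds act on raw peaks — the screen precedes baseline subtraction.
The baseline peak is taken per condition rather than pooled; that is the
conservative reading when the criterion refers to "the second before
stimulus presentation".

A responsive unit is **bilateral** if any of six flags fires:

* `ipsi_sigma_ON` / `ipsi_sigma_OFF` — the ipsilateral peak exceeds the
  baseline noise mean by `ipsi_sigma` (4) standard deviations. "Noise" is
  operationalized as the mean and s.d. of the ipsilateral PSTH's
  baseline-window bin rates: the criterion concerns the ipsilateral
  response, and the baseline bins are the only stimulus-free estimate
  available for it. If the baseline is completely silent (s.d. 0), the
  criterion degenerates to requiring a nonzero peak above the 5-Hz floor.
* `peak_wilcoxon_ON` / `peak_wilcoxon_OFF` — per-trial firing rates in the
  condition's own peak bin (located on the trial-averaged PSTH of each
  condition separately) differ between contralateral and bilateral trials
  (rank-sum test with continuity correction, two-sided, `alpha` = 0.05).
* `rate_wilcoxon_ON` / `rate_wilcoxon_OFF` — same test on per-trial mean
  rates over the full 1-s window.

The three criteria are evaluated at `alpha` per test, without correction
across windows or criteria — matching the procedure's "p < 0.05" framing.
The union of six ~5% tests implies a non-trivial false-bilateral rate on
purely contralateral units (empirically ~15–20% at 40 trials; the
documented bound is `2 * alpha * 4`). This is a property of the selection
procedure itself, visible in the type-I simulation tests, not an artifact
of this implementation.

**Integration sign.** For bilateral units, the ON (resp. OFF) integration
is `excitation` or `suppression` when the peak or rate test for that
window is significant, with the direction taken from the median
bilateral-minus-contralateral difference. The significant peak test is
consulted first; because 25-ms peak-bin counts are small integers, their
medians frequently tie, in which case the direction defers to the
significant rate test. Only fully tied medians yield `none`.

## The factorial rank statistics

All `N` observations are ranked jointly with mid-ranks for ties. The
factorial decomposition is computed on the ranks and each effect is tested
with

$$H = \frac{SS_{\text{effect}}}{SS_{\text{total}} / (N - 1)} \sim
\chi^2_{df}.$$

Using the empirical total mean square of the ranks absorbs the tie
correction: with one varying factor the statistic is exactly the
tie-corrected Kruskal-Wallis H (a property the test suite asserts to
1e-9). Real cohorts are unbalanced (each cell contributes however many
units survived selection), so the sums of squares are obtained by model
comparison on the ranks, Type II by default: each main effect is adjusted
for the other, and the interaction for both main effects. Type II is the
standard choice for unbalanced factorial designs in which neither factor
is ordered before the other; sequential (Type I) sums of squares are
available via `ss_type = "I"`. A design that loses a cell (e.g. no
surviving unit in dark-right) cannot estimate the interaction; the
variable is skipped with a warning rather than silently reduced.

Effect sizes use the Kruskal-Wallis eta-squared estimate
$\eta^2 = (H - k + 1)/(n - k)$, with the conventional size labels
(negligible < 0.01 ≤ small < 0.06 ≤ moderate < 0.14 ≤ large). Main effects
use their own level count `k = 2`; for the interaction the four crossed
cells are treated as `k = 4` groups — the formula is defined for a
one-way grouping, and the cells are the natural grouping for an
interaction, a convention this package documents rather than claims as
canonical.

Dunn's post-hoc z statistics compare mean ranks of the four cells with the
tie-corrected variance term, two-sided normal p-values, and a Bonferroni
factor equal to the number of requested comparisons (the four scientific
ones: left vs right within each treatment, dark vs light within each
hemisphere). Post-hocs are computed when the interaction is significant at
`alpha`, mirroring how the factorial tables gate them.

The rank-sum test used throughout is the normal approximation with tie
correction and a 0.5 continuity correction; exact enumeration is used
only as a test oracle at small n, where the documented approximation gap
is a few hundredths at `n = 3` per group and shrinks rapidly with n.

The two-proportion comparison uses the pooled-variance z statistic, with
reference-minus-observed operand order, so an observed share above the
reference yields a negative z.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws each unit's spike trains from an inhomogeneous
Poisson process via Lewis-Shedler thinning with majorant `baseline +
max(0, on_amp) + max(0, off_amp)`. The intensity is a constant baseline
plus unit-peak Gaussian ON and OFF transients with explicit peak
latencies — the simplest shape whose generative latency is directly
comparable to the analysis's "center of the peak bin" estimate. A
Gaussian transient was preferred over an alpha function because its peak
location is a parameter rather than a derived quantity. Suppression is
modeled as a reduced (possibly negative) bilateral amplitude with the
rate clipped at zero.

Five archetypes carry the ground truth: `nonresponsive`, `contra_only`
(bilateral response identical to contralateral), `bilateral_independent`
(adds an ipsilateral response, no contra/bilateral modulation),
`bilateral_excitatory` (bilateral ON amplitude 2x contralateral) and
`bilateral_suppressive` (0.4x). Template magnitudes (4 Hz baseline, 40 Hz
contralateral ON, 12 Hz OFF, 20 Hz ipsilateral ON, 40-ms transient s.d.,
latencies 100/150 ms) put transients an order of magnitude above the
trial-averaged PSTH noise floor — at 4 Hz baseline, 25-ms bins and 40
trials the per-bin s.e. is 2 Hz — so the recovery experiments probe the
procedure's logic, not borderline detection. Per-unit log-normal jitter
(sdlog 0.25 on baseline and amplitudes) spreads the cohort over roughly a
2.5-fold parameter range, which is what makes the recovery numbers
realistic rather than saturated.

The default cohort preset injects directions, not fitted values: light
incubation multiplies baselines by 1.5 and amplitudes by 1.4–1.5 in both
hemispheres and shifts latencies 50 ms earlier; the dark-right cell gets a
1.15x baseline, 1.25x amplitude, 25-ms-faster advantage and a slightly
higher bilateral mixture share. No fitted generative parameter values exist for real cohorts, so these
magnitudes are this package's own fixed, documented choices.

The simulator deliberately omits: correlated noise across units or
trials, refractory periods and bursting, within-unit condition
correlations beyond the shared archetype, subject-level random effects
(units are exchangeable within a cell), and drift across the session.
Passing recovery tests therefore show that the pipeline's inference logic
is sound under its own assumptions — they do not show robustness to
non-Poisson firing or to animal-level clustering in real recordings.

## Problem sizes and numerical choices

The validation experiments run at fixed, documented sizes chosen as the
smallest that make the targeted properties sharp: classifier recovery on
10 cohorts of 200 units per cell at 40 trials (balanced accuracy and
integration-sign accuracy both ≥ 0.90 against ground truth); null
calibration of the factorial test on 2,000 balanced 2x2 replicates of 25
observations per cell (rejection rates within [0.03, 0.07] at the 0.05
level); end-to-end power on 100 cohorts of 40 units per cell (the
injected 1.5x treatment effect on spontaneous rate detected in ≥ 95% of
cohorts); and PSTH consistency at 10,000 trials (empirical rates within
3 s.e. of the bin-averaged intensity). Statistical oracles (brute-force
rank ANOVA, exact rank-sum enumeration, the total-rank-variance identity
for Dunn's variance term) are checked to 1e-9 on 100+ random instances.

Numerical conventions worth knowing: integer percentages round half away
from zero (base R's `round()` rounds half to even, which disagrees with
standard table bookkeeping); sums of squares from model comparison are
clipped at zero to absorb ~1e-12 round-off; an all-tied dependent
variable leaves H undefined (reported `NA`, p = 1) rather than 0/0; and a
fully tied rank-sum comparison returns p = 1.

## Known limitations

* The per-trial "peak sample" for the rank-sum peak criterion is the
  spike count in the condition's peak bin; with 25-ms bins these are
  small integers, so the peak test is heavily tied and conservative. The
  rate test carries most of the power.
* The selection procedure's false-bilateral rate (~15–20% on pure
  contralateral cohorts at `alpha` 0.05) is inherent to the uncorrected
  union of six criteria; balanced accuracy near 0.90 in recovery
  experiments is dominated by that specificity ceiling.
* Eta-squared for interactions (cells-as-groups) and the Bonferroni
  family size (4 per variable) are documented conventions; other choices
  are defensible.
* Units are treated as independent observations; there is no
  subject-level random effect.

## A worked example

```{r example, eval = FALSE}
library(entolat)

ds <- simulate_cohort(sim_config(n_units_per_cell = 50L, seed = 1L))
report <- run_analysis(ds, reference_proportion = c(478, 1544))

report$summary              # responsive-unit bookkeeping table
subset(report$stats, p < 0.05)
report$integration_counts
report$proportion_test$z
```

The `analysis/` directory of the source repository runs this same chain
as four numbered scripts (simulate, features, classify, stats) writing
their tables under `results/`.
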