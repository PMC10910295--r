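# entolat

Analysis of lateralized visual responses in trial-aligned single-unit
spike recordings.

In birds, optic-nerve fibers decussate almost completely, and the
tectofugal pathway re-crosses part of each eye's input on its way to the
entopallium, the primary visual area of the avian telencephalon. A unit
recorded there may respond only to the contralateral eye or integrate
input from both. `entolat` implements the analysis chain used to ask
whether such integration — and visual responsiveness generally — differs
between hemispheres and between dark- and light-incubated animals:

* **PSTH feature extraction** — 25-ms-bin peristimulus time histograms
  over a `[-1, 2]` s window around a 1-s flash (contralateral,
  ipsilateral, or bilateral; 40 trials each); spontaneous rate, ON/OFF
  peak rates (baseline-subtracted for statistics) and peak latencies
  (center of the earliest maximal bin).
* **Unit selection** — visual responsiveness (response peak ≥ 2× any
  baseline peak and ≥ 5 Hz), then bilateral-vs-contralateral separation
  by three criteria applied to ON and OFF windows: ipsilateral peak
  > 4 s.d. above baseline noise, and rank-sum tests (continuity
  corrected, p < 0.05) comparing contralateral vs bilateral per-trial
  peak-bin rates and window firing rates; excitation/suppression typing
  of bilateral units from the direction of significant modulation.
* **Rank-based factorial statistics**, implemented from scratch — the
  Scheirer-Ray-Hare test of treatment × hemisphere on joint ranks,

      H = SS_effect / (SS_total / (N − 1))  ~  χ²(df),

  with Type II sums of squares on ranks for unbalanced designs;
  Kruskal-Wallis effect sizes η² = (H − k + 1)/(n − k) with conventional
  size labels; Dunn post-hoc z tests on mean ranks with tie correction
  and Bonferroni adjustment; Wilcoxon rank-sum with continuity
  correction; and the pooled two-proportion z test

      z = (p̂₁ − p̂₂) / sqrt(p̂(1 − p̂)(1/n₁ + 1/n₂)).

* **A ground-truth simulator** — inhomogeneous-Poisson spike trains
  (Lewis-Shedler thinning) from archetypes with Gaussian ON/OFF
  transients, per-cell treatment/hemisphere effects and per-unit jitter,
  used for parameter-recovery validation of the whole pipeline.

## Worked example

```r
library(entolat)

ds <- simulate_cohort(sim_config(n_units_per_cell = 50L, seed = 1L))
report <- run_analysis(ds, reference_proportion = c(478, 1544))
report$summary
```

```
 treatment hemisphere n_visually_responsive n_bilateral n_contralateral pct_bilateral pct_contralateral
      dark       left                    46          32              14            70                30
      dark      right                    46          36              10            78                22
      dark       both                    92          68              24            74                26
     light       left                    46          33              13            72                28
     light      right                    46          23              23            50                50
     light       both                    92          56              36            61                39
       all       both                   184         124              60            67                33
```

184 of 200 simulated units pass the responsiveness screen; 124 (67%) are
classified bilateral. The factorial layer then reports, per dependent
variable, H statistics, p-values and η² per effect; e.g. the injected
light-incubation effect on spontaneous firing appears as a significant
treatment main effect:

```r
subset(report$stats, variable == "spontaneous_rate" & population == "bilateral")
```

```
 population condition         variable      effect df        H         p     eta2 eta2_label   n
  bilateral       pre spontaneous_rate   treatment  1 46.67601 8.375e-12  0.37439      large 124
  bilateral       pre spontaneous_rate  hemisphere  1  5.04620 2.468e-02  0.03317      small 124
  bilateral       pre spontaneous_rate interaction  1  0.05707 8.112e-01 -0.02452 negligible 124
```

and the cohort's bilateral share is compared against a reference
population (478 of 1544, the thalamofugal figure) with the pooled
two-proportion z test: here `report$proportion_test$z` is −9.80
(p ≈ 1e-22), the observed 67% bilateral share sitting well above the 31%
reference.

The same chain runs as numbered scripts under `analysis/`
(`01_simulate.R`, `02_features.R`, `03_classify.R`, `04_stats.R`), each
writing its tables under `results/`.

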