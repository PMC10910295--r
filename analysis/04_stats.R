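#!/usr/bin/env Rscript
# Step 4 — rank-based factorial statistics and proportion comparison.
#
# Runs the full pipeline end to end: for each dependent variable
# (spontaneous rate; baseline-subtracted ON/OFF peaks; ON/OFF latencies;
# per condition) a Scheirer-Ray-Hare test of treatment x hemisphere with
# Kruskal-Wallis eta-squared effect sizes, Dunn post-hoc comparisons of the
# four cells where the interaction is significant, separately for the
# bilateral and contralateral populations. Also compares the cohort's
# bilateral share against the published thalamofugal (visual Wulst)
# reference counts (478 of 1544).
#
# Writes the full report under results/ (stats_bilateral.csv,
# stats_contralateral.csv, posthoc.csv, proportion_test.csv, manifest.json,
# ...).

suppressMessages(library(entolat))

ds <- read_spike_table("results/data/spikes.csv",
                       "results/data/units.csv",
                       "results/data/protocol.yaml")
report <- run_analysis(ds, reference_proportion = c(478, 1544),
                       out_dir = "results")

cat("\nsignificant effects (p < 0.05):\n")
sig <- report$stats[report$stats$p < 0.05, ]
print(sig[order(sig$population, sig$condition, sig$variable), ],
      row.names = FALSE, digits = 3)

cat("\nbilateral share vs reference population:\n")
cat(sprintf("  observed %.0f%%, reference %.0f%%, z = %.2f, p = %.3g\n",
            100 * report$proportion_test$prop_observed,
            100 * report$proportion_test$prop_reference,
            report$proportion_test$z,
            report$proportion_test$p_two_sided))
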