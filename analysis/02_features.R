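#!/usr/bin/env Rscript
# Step 2 — PSTHs and response features.
#
# Reads the simulated recording back from disk (exactly as a real export
# would be read), computes each unit's 25-ms PSTH per condition, and
# extracts the dependent variables of the factorial analysis: spontaneous
# rate (baseline window, averaged across conditions), raw and baseline-
# subtracted ON/OFF peak rates, and ON/OFF peak latencies (center of the
# earliest maximal bin, measured from window start).
#
# Writes results/features.csv.

suppressMessages(library(entolat))

ds <- read_spike_table("results/data/spikes.csv",
                       "results/data/units.csv",
                       "results/data/protocol.yaml")
features <- extract_features_all(ds)
write.csv(features, "results/features.csv", row.names = FALSE)

cat(sprintf("extracted features for %d units\n", nrow(features)))
for (tr in c("dark", "light")) {
  sel <- features$treatment == tr
  cat(sprintf("  %s: median spontaneous %.2f Hz, median contra ON peak %.1f Hz\n",
              tr, median(features$spontaneous_rate[sel]),
              median(features$contra_on_peak_raw[sel])))
}
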