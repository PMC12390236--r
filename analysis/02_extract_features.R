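#!/usr/bin/env Rscript
# Step 2 — signal conditioning and feature extraction.
#
# Loads the simulated cohort, filters every recording (0.1 Hz gravity
# high-pass on accelerometer axes, 20 Hz low-pass), computes the magnitude
# channel, and extracts the full feature bank per recording: 48 time-domain,
# 128 frequency-domain (4 bands x 4 channels x 8), 80 STFT, 40 windowed
# range/entropy, 24 wavelet-detail and 3 axis-correlation features, plus
# per-examination metadata (one-hot side/handedness/group, age, years since
# diagnosis).
#
# Writes: results/features.csv (+ .info.json provenance sidecar)

library(pdsense)

coh <- read_cohort("results/cohort")
ft <- assemble_feature_table(coh, verbose = TRUE)
write_feature_table(ft, "results/features.csv")

cat("feature table:", nrow(ft$features), "examinations x",
    ncol(ft$features), "features\n")
cat("sensor features per recording block: 323; metadata columns:",
    sum(ft$feature_info$kind == "meta"), "\n")
if (length(ft$excluded))
  cat("excluded (incomplete blocks):", length(ft$excluded), "\n")
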