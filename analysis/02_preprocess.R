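#!/usr/bin/env Rscript
# Step 2: preprocess the raw cohort.
#
# Savitzky-Golay smoothing (window 5, order 3), iterative polynomial
# autofluorescence removal (order 5 in FP, order 1 in HW), SNR quality
# control at the 2940 cm^-1 band, and joint FP+HW unit-area
# normalization.

library(ramanfphw)

set <- read_spectra("scratch/cohort/spectra.csv",
                    "scratch/cohort/manifest.csv")
cat("read", n_spectra(set), "raw spectra\n")

pre <- preprocess_set(set, preprocess_config())
cat(n_spectra(pre$set), "spectra survive quality control;",
    nrow(pre$rejections), "rejected\n")

write_spectra(pre$set, "scratch/processed")
dir.create("results", showWarnings = FALSE)
write.csv(pre$rejections, "results/02_rejections.csv", row.names = FALSE)
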