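#!/usr/bin/env Rscript
# Stage 2: preprocess every recording into 2-s epochs.
#
# Fixed chain: zero-phase 1-40 Hz band-pass with a 50 Hz notch, Hjorth
# nearest-neighbour surface Laplacian (volume-conduction reduction), then
# non-overlapping 2-s segmentation. The synthetic recordings are
# artifact-free, so no component rejection is needed.

library(eegfp)

st <- readRDS("scratch/cohort.rds")
profile <- st$profile

epochs <- list()
for (rec in st$cohort$recordings) {
  epochs <- c(epochs, preprocess_recording(
    rec, low = profile$low, high = profile$high, notch = profile$notch,
    laplacian = profile$laplacian, seg_len_s = profile$seg_len_s))
}
saveRDS(epochs, "scratch/epochs.rds")

per_sess <- floor(profile$duration_s / profile$seg_len_s)
cat("Segmented", length(epochs), "epochs of", profile$seg_len_s, "s (",
    per_sess, "per subject-session ) after 1-40 Hz band-pass, 50 Hz notch",
    "and the Hjorth Laplacian.\n")
cat("Each epoch:", nrow(epochs[[1]]$data), "channels x",
    ncol(epochs[[1]]$data), "samples.\n")
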