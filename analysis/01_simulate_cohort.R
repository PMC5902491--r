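#!/usr/bin/env Rscript
# Step 1 — simulate the study cohorts.
#
# Two synthetic resting-state cohorts of 30 MCI + 30 HC subjects on a
# 60-parcel block atlas (27 voxels per parcel, 229 volumes at TR = 2 s):
#   * effect cohort: ROIs 1-15 have their Hurst exponent reduced by 0.15
#     in the MCI group (baseline H = 0.7, measurement noise SD = 0.1);
#   * null cohort: identical, but delta_H = 0 (the groups share one law).
# Volumes land under scratch/ (binary NIfTI, regenerable); a small text
# summary of the ground truth goes to results/.

library(boldhurst)

base <- function(delta, seed) {
  cohort_spec(n_mci = 30, n_hc = 30, n_rois = 60, voxels_per_roi = 27,
              n_timepoints = 229, tr_seconds = 2.0, baseline_H = 0.7,
              delta_H = delta, affected_rois = 1:15, noise_sd = 0.1,
              seed = seed)
}

dir.create("results", showWarnings = FALSE)
for (kind in c("effect", "null")) {
  spec <- base(if (kind == "effect") -0.15 else 0, seed = 501)
  co <- simulate_cohort(spec)
  out <- file.path("scratch", paste0("cohort_", kind))
  write_cohort(co, out)
  cat(sprintf("%s cohort: %d subjects, %d ROIs x %d voxels, %d volumes -> %s\n",
              kind, nrow(co$participants), spec$n_rois, spec$voxels_per_roi,
              spec$n_timepoints, out))
}

spec <- base(-0.15, 501)
summary <- data.frame(
  roi = seq_len(spec$n_rois),
  affected = seq_len(spec$n_rois) %in% spec$affected_rois,
  H_hc = spec$baseline_H,
  H_mci = ifelse(seq_len(spec$n_rois) %in% spec$affected_rois,
                 spec$baseline_H + spec$delta_H, spec$baseline_H)
)
write.csv(summary, "results/cohort_ground_truth.csv", row.names = FALSE)
cat("ground truth written to results/cohort_ground_truth.csv\n")
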