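#!/usr/bin/env Rscript
# Whole-volume searchlight map of endo-vs-exo decoding for each subject
# (sphere radius 2 voxels = 5 mm on this grid, to keep the neighborhood
# size comparable to the ROI analyses at desk scale), plus a group map of
# voxelwise one-sample t-values against 50% thresholded at p < 0.001
# uncorrected.

source("analysis/00_config.R")

mask <- full_grid_mask(GRID)
maps <- lapply(seq_len(N_SUBJECTS), function(s) {
  sl <- searchlight_map(get_betas(s), mask, "endo_vs_exo", radius_vox = 2)
  cat(sprintf("sub-%02d: peak %.1f%% at voxel (%s)\n", s,
              max(sl$accuracy),
              paste(mask$ijk[which.max(sl$accuracy), ], collapse = ", ")))
  sl
})

acc <- do.call(rbind, lapply(maps, function(m) m$accuracy))
tstat <- apply(acc, 2, function(v) {
  if (sd(v) == 0) 0 else (mean(v) - 50) / (sd(v) / sqrt(nrow(acc)))
})
pvox <- 2 * pt(-abs(tstat), df = nrow(acc) - 1)
sig <- tstat > 0 & pvox < 0.001

group_map <- array(0, GRID$dim)
group_map[mask$lin] <- tstat
dir.create(file.path(RESULTS, "searchlight"), showWarnings = FALSE,
           recursive = TRUE)
tmap <- make_grid(GRID$dim, affine = GRID$affine)
img <- storymvpa:::grid_to_nifti(group_map, tmap)
RNifti::writeNifti(img, file.path(RESULTS, "searchlight", "group_t.nii.gz"))

peak <- which.max(tstat)
peak_mm <- voxel_to_mm(GRID, mask$ijk[peak, ])
cat(sprintf("\nGroup peak: t = %.2f, mean accuracy %.1f%%, at (%.1f, %.1f, %.1f) mm\n",
            tstat[peak], mean(acc[, peak]), peak_mm[1], peak_mm[2],
            peak_mm[3]))
cat(sum(sig), "voxels exceed the descriptive p < 0.001 (uncorrected)",
    "threshold;\nthe embedded signal region is centered at",
    sprintf("(%.1f, %.1f, %.1f) mm\n",
            ROIS$x[ROIS$name == SIGNAL_ROI],
            ROIS$y[ROIS$name == SIGNAL_ROI],
            ROIS$z[ROIS$name == SIGNAL_ROI]))
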