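#!/usr/bin/env Rscript
# Eye-movement control analysis: blink cleaning, 20 ms smoothing, 8 x 4
# gaze-grid featurization (32 fixation + 1024 transition features),
# condition-per-run averaging, leave-one-run-out SVM decoding, and group
# t-tests against chance. Gaze was generated independently of condition,
# so decoding at chance confirms the fMRI effects are not gaze-driven.

source("analysis/00_config.R")

grid <- gaze_grid()
rows <- list()
for (ct in c("endo_vs_exo", "self_vs_other")) {
  accs <- vapply(seq_len(N_SUBJECTS), function(s) {
    eye <- get_subject(s)$eye
    social <- eye[is_social(eye$condition), ]
    ft <- featurize_trials(social, grid)
    avg <- condition_run_average(ft$features, ft$condition, ft$run)
    eye_decode(avg, ct)$mean_accuracy
  }, numeric(1))
  tt <- ttest_vs_chance(accs)
  rows[[ct]] <- data.frame(contrast = ct, mean_accuracy = tt$mean,
                           t = tt$t, df = tt$df, p = tt$p)
  cat(sprintf("%s: mean %.1f%%, t(%d) = %.2f, p = %.3f\n", ct, tt$mean,
              tt$df, tt$t, tt$p))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(RESULTS, "eye_decoding.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nGaze was simulated independently of condition; non-significant",
    "\ndecoding here mirrors the intended negative control.\n")
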