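# Shared configuration for the analysis scripts (desk-scale study).
# Sourced by the numbered drivers; every script is rerunnable and reuses
# cached intermediates under results/cache.

library(storymvpa)

N_SUBJECTS <- 6
N_RUNS <- 6
GRID <- make_grid(c(12, 12, 8))          # 2.5 mm isotropic field of view
ROIS <- synthetic_rois(GRID)             # roiA (signal), roiB (control)
EFFECTS <- effect_spec(attention = 1)    # endo-vs-exo pattern, SNR ~ 1
SIGNAL_ROI <- "roiA"
N_PERM <- 500
N_BOOT <- 2000
MASTER_SEED <- 20260926

RESULTS <- "results"
CACHE <- file.path(RESULTS, "cache")
dir.create(CACHE, showWarnings = FALSE, recursive = TRUE)

CFG <- pipeline_config(n_subjects = N_SUBJECTS, n_runs = N_RUNS,
                       grid_dim = GRID$dim, rois = ROIS, effects = EFFECTS,
                       signal_roi = SIGNAL_ROI, n_perm = N_PERM,
                       n_boot = N_BOOT, seed = MASTER_SEED)

cached <- function(name, fn) {
  path <- file.path(CACHE, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- fn()
  saveRDS(val, path)
  val
}

get_subject <- function(s) {
  cached(sprintf("sub-%02d", s), function() simulate_subject(CFG, s))
}

get_betas <- function(s) {
  cached(sprintf("sub-%02d_betas", s), function() {
    subj <- get_subject(s)
    fit_trial_betas(subj$bold, build_design_matrix(subj$design,
                                                   subj$motion))
  })
}
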