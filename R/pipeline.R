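#' Pipeline configuration
#'
#' One structured configuration for the full analysis. Defaults are a
#' desk-scale study (8 subjects, 6 runs, a small simulated field of view
#' with two spherical ROIs, signal placed in the first) that exercises
#' every stage in minutes; the acquisition parameters themselves (10
#' trials/run, 130 volumes at TR 2 s, 18 s lead-in) follow the scanning
#' protocol. Every random stage consumes a seed derived deterministically
#' from `seed`.
#'
#' @param n_subjects,n_runs cohort and design size.
#' @param grid_dim simulated field-of-view dimensions (2.5 mm voxels).
#' @param rois ROI table (see [default_rois()] format); `NULL` uses two
#'   synthetic spheres inside the simulated field of view.
#' @param effects an [effect_spec()]; its `signal_mask` is overridden by
#'   `signal_roi` when that is set.
#' @param signal_roi name of the ROI carrying the ground-truth pattern
#'   (`NULL` = patterns span the whole grid).
#' @param contrasts binary contrasts to decode and test.
#' @param include_interaction,include_xclass add the interaction difference
#'   score / the left-out cross-classification (on the first ROI).
#' @param gaze_weights condition x cell gaze weights (`NULL` = condition-
#'   independent gaze).
#' @param eye_rate eye-tracker sampling rate, Hz.
#' @param n_perm,n_boot inference iterations.
#' @param seed master seed.
#' @param out_dir output directory (`NULL` = nothing written).
#' @param cache reuse per-subject intermediates found in `out_dir`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 8, n_runs = 6,
                            grid_dim = c(12, 12, 8), rois = NULL,
                            effects = effect_spec(attention = 1),
                            signal_roi = "roiA",
                            contrasts = c("endo_vs_exo", "self_vs_other"),
                            include_interaction = TRUE,
                            include_xclass = FALSE,
                            gaze_weights = NULL, eye_rate = 250,
                            n_perm = 500, n_boot = 1000, seed = 1,
                            out_dir = NULL, cache = TRUE) {
  grid <- make_grid(grid_dim)
  if (is.null(rois)) rois <- synthetic_rois(grid)
  structure(list(n_subjects = n_subjects, n_runs = n_runs, grid = grid,
                 rois = rois, effects = effects, signal_roi = signal_roi,
                 contrasts = contrasts,
                 include_interaction = include_interaction,
                 include_xclass = include_xclass,
                 gaze_weights = gaze_weights, eye_rate = eye_rate,
                 n_perm = n_perm, n_boot = n_boot, seed = seed,
                 out_dir = out_dir, cache = cache),
            class = "pipeline_config")
}

#' Two synthetic spherical ROIs inside a small field of view
#'
#' Stand-ins for real anatomical ROIs when the whole dataset is simulated:
#' two 6-mm spheres placed in opposite corners of the simulated volume.
#'
#' @param grid a `voxel_grid`.
#' @param radius sphere radius in mm.
#' @return ROI table in the [default_rois()] format.
#' @export
synthetic_rois <- function(grid, radius = 6) {
  ext <- (grid$dim - 1) * sqrt(colSums(grid$affine[1:3, 1:3]^2))
  ctr <- voxel_to_mm(grid, (grid$dim - 1) / 2)
  off <- ext / 4
  data.frame(name = c("roiA", "roiB"),
             x = ctr[1] + c(-off[1], off[1]),
             y = ctr[2] + c(-off[2], off[2]),
             z = c(ctr[3], ctr[3]),
             radius = radius, stringsAsFactors = FALSE)
}

# deterministic per-subject, per-stage seeds below 2^31
derive_seed <- function(seed, subject, stage) {
  (as.integer(seed) %% 100000L) * 10000L + subject * 10L + stage
}

#' Simulate one complete subject
#'
#' Design, motion, BOLD, eye samples and behavioral responses under one
#' derived seed set.
#'
#' @param config a `pipeline_config`.
#' @param subject subject number (1-based).
#' @return list with `subject_id`, `design`, `motion`, `bold`, `eye`,
#'   `responses`.
#' @export
simulate_subject <- function(config, subject) {
  effects <- config$effects
  if (!is.null(config$signal_roi)) {
    roi <- config$rois[config$rois$name == config$signal_roi, ]
    stopifnot(nrow(roi) == 1)
    effects$signal_mask <- sphere_voxels(c(roi$x, roi$y, roi$z), roi$radius,
                                         config$grid)
  }
  design <- simulate_design(n_runs = config$n_runs,
                            seed = derive_seed(config$seed, subject, 1))
  motion <- simulate_motion(config$n_runs, design$n_volumes,
                            seed = derive_seed(config$seed, subject, 2))
  bold <- simulate_bold(design, config$grid, effects,
                        seed = derive_seed(config$seed, subject, 3))
  eye <- simulate_eye(design, condition_weights = config$gaze_weights,
                      rate = config$eye_rate,
                      seed = derive_seed(config$seed, subject, 4))
  responses <- simulate_behavior(design,
                                 seed = derive_seed(config$seed, subject, 5))
  list(subject_id = sprintf("sub-%02d", subject), design = design,
       motion = motion, bold = bold, eye = eye, responses = responses)
}

# first-level stage: GLM betas for one subject
subject_betas <- function(subj) {
  dm <- build_design_matrix(subj$design, subj$motion)
  fit_trial_betas(subj$bold, dm)
}

#' Run the full analysis pipeline
#'
#' Simulation, trialwise GLM, ROI extraction, leave-one-run-out decoding,
#' group permutation/bootstrap/FDR inference, eye-movement control
#' analysis and behavioral summary, end to end. Deterministic given the
#' config seed; per-subject intermediates are cached in `out_dir` when
#' caching is enabled, and report tables plus a provenance record are
#' written there.
#'
#' @param config a `pipeline_config`.
#' @return list: `tables` (one ROI x contrast data.frame per contrast,
#'   plus interaction/xclass when enabled), `eye` (per-contrast group
#'   t-tests and per-subject accuracies), `behavior` (per-condition
#'   summary), `inferences` (the raw `group_inference` objects),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  cache_path <- function(name) {
    if (is.null(out_dir)) NULL else file.path(out_dir, paste0(name, ".rds"))
  }
  stage <- function(name, fn) {
    p <- cache_path(name)
    if (config$cache && !is.null(p) && file.exists(p)) return(readRDS(p))
    val <- fn()
    if (!is.null(p)) saveRDS(val, p)
    val
  }

  masks <- roi_masks(config$rois, config$grid)
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    stage(sprintf("sub-%02d_data", s), function() {
      subj <- tryCatch(simulate_subject(config, s), error = function(e) {
        stop("stage simulate, subject ", s, ": ", conditionMessage(e))
      })
      betas <- tryCatch(subject_betas(subj), error = function(e) {
        stop("stage glm, subject ", s, ": ", conditionMessage(e))
      })
      list(subject_id = subj$subject_id,
           patterns = lapply(masks, function(m) extract_patterns(betas, m)),
           eye = subj$eye, responses = subj$responses)
    })
  })

  inferences <- list()
  tables <- list()
  for (ct in config$contrasts) {
    per_roi <- lapply(names(masks), function(rn) {
      group_permutation_test(
        lapply(subjects, function(s) s$patterns[[rn]]),
        contrast = ct, scheme = "loro", n_perm = config$n_perm,
        n_boot = config$n_boot,
        seed = derive_seed(config$seed, match(rn, names(masks)),
                           5 + match(ct, config$contrasts)))
    })
    names(per_roi) <- names(masks)
    inferences[[ct]] <- per_roi
    tables[[ct]] <- decoding_report_table(per_roi)
  }
  if (config$include_interaction) {
    per_roi <- lapply(names(masks), function(rn) {
      group_permutation_test(
        lapply(subjects, function(s) s$patterns[[rn]]),
        scheme = "interaction", n_perm = config$n_perm,
        n_boot = config$n_boot,
        seed = derive_seed(config$seed, match(rn, names(masks)), 8))
    })
    names(per_roi) <- names(masks)
    inferences[["interaction"]] <- per_roi
    tables[["interaction"]] <- decoding_report_table(per_roi)
  }
  if (config$include_xclass) {
    g <- group_permutation_test(
      lapply(subjects, function(s) s$patterns[[1]]),
      scheme = "xclass", n_perm = config$n_perm, n_boot = config$n_boot,
      seed = derive_seed(config$seed, 0, 9))
    inferences[["xclass"]] <- stats::setNames(list(g), names(masks)[1])
    tables[["xclass"]] <- decoding_report_table(inferences[["xclass"]])
  }

  eye_grid <- gaze_grid()
  eye <- lapply(c("endo_vs_exo", "self_vs_other"), function(ct) {
    accs <- vapply(subjects, function(s) {
      ft <- featurize_trials(s$eye[is_social(s$eye$condition), ], eye_grid)
      avg <- condition_run_average(ft$features, ft$condition, ft$run)
      eye_decode(avg, ct)$mean_accuracy
    }, numeric(1))
    c(list(contrast = ct, accuracies = accs), ttest_vs_chance(accs))
  })
  names(eye) <- c("endo_vs_exo", "self_vs_other")

  responses <- do.call(rbind, lapply(subjects, function(s) {
    cbind(s$responses, subject = s$subject_id)
  }))
  behavior <- behavior_summary(responses)

  if (!is.null(out_dir)) {
    for (nm in names(tables)) {
      utils::write.table(tables[[nm]],
                         file.path(out_dir, paste0("table_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(behavior, file.path(out_dir, "behavior_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eff <- config$effects
    provenance <- list(
      seed = config$seed, n_subjects = config$n_subjects,
      n_runs = config$n_runs, n_perm = config$n_perm,
      n_boot = config$n_boot,
      grid_dim = config$grid$dim, contrasts = config$contrasts,
      signal_roi = config$signal_roi,
      effects = list(attention = eff$attention, agent = eff$agent,
                     social = eff$social, interaction = eff$interaction,
                     noise_sd = eff$noise_sd, ar1_rho = eff$ar1_rho,
                     drift_amplitude = eff$drift_amplitude),
      permutation_scheme = "labels shuffled within run within subject",
      normalization = "fold-wise z using training-run statistics",
      classifier = "linear SVM, C = 1",
      hrf = "double-gamma, peak 6 s, undershoot 16 s, ratio 1/6",
      drop_initial_volumes = 3,
      rois = config$rois)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(tables = tables, eye = eye, behavior = behavior,
       inferences = inferences, config = config)
}
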