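#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas HRF: a gamma density peaking near 6 s
#' minus 1/6 of a gamma density peaking near 16 s (both with 1 s dispersion),
#' sampled on `[0, length_s]` at spacing `dt` and normalized to unit peak.
#'
#' @param dt sample spacing in seconds, `0 < dt <= 1`.
#' @param length_s kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma delays in seconds (defaults 6, 16).
#' @param dispersion gamma dispersion in seconds (default 1).
#' @param undershoot_ratio weight of the undershoot term (default 1/6).
#' @return numeric vector of kernel samples, peak value exactly 1.
#' @examples
#' h <- canonical_hrf(0.1)
#' (which.max(h) - 1) * 0.1  # peak near 5 s
#' @export
canonical_hrf <- function(dt, length_s = 32, peak_delay = 6,
                          undershoot_delay = 16, dispersion = 1,
                          undershoot_ratio = 1 / 6) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 || dt > 1) {
    stop("dt must be a single value in (0, 1]")
  }
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay / dispersion,
                    scale = dispersion)
  h / max(h)
}

# Boxcar events convolved with the HRF on an oversampled grid, sampled at
# volume acquisition times (t = (v-1)*tr). Convolution is scaled by dt so
# the result approximates the continuous-time convolution integral.
regressor_timecourse <- function(onsets, durations, n_volumes, tr,
                                 dt = 0.1, hrf = NULL) {
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  run_len <- n_volumes * tr
  if (any(onsets < 0) || any(onsets + durations > run_len + 1e-9)) {
    stop("event onset/offset beyond run duration (", run_len, " s)")
  }
  grid_t <- seq(0, run_len, by = dt)
  box <- numeric(length(grid_t))
  for (e in seq_along(onsets)) {
    box[grid_t >= onsets[e] - 1e-9 & grid_t < onsets[e] + durations[e] - 1e-9] <- 1
  }
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(grid_t)] * dt
  vol_t <- (seq_len(n_volumes) - 1) * tr
  conv[round(vol_t / dt) + 1]
}

#' Smooth random-walk motion regressors
#'
#' Six nuisance time series per run (three translations, three rotations),
#' generated as Gaussian random walks purely to exercise the GLM interface;
#' no head motion is applied to the simulated BOLD data.
#'
#' @param n_runs,n_volumes run count and volumes per run.
#' @param sd_step innovation SD per volume.
#' @param seed optional integer seed.
#' @return list of `n_volumes` x 6 matrices, one per run.
#' @export
simulate_motion <- function(n_runs, n_volumes, sd_step = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    m <- apply(matrix(stats::rnorm(n_volumes * 6, sd = sd_step),
                      n_volumes, 6), 2, cumsum)
    colnames(m) <- paste0("motion_", 1:6)
    m
  })
}

#' First-level design matrix for trialwise (beta-series) estimation
#'
#' One regressor per trial (10 s story boxcar convolved with the canonical
#' HRF), one shared regressor for all 4 s probe phases, one intercept per
#' run, and optionally six motion regressors. Under the default 10-run,
#' 10-trial design this yields 100 + 1 + 10 + 6 = 117 columns. The first
#' `drop_initial` volumes of every run are excluded (non-steady-state
#' magnetization), so rows count `n_volumes - drop_initial` per run.
#'
#' @param design a `story_design`.
#' @param motion optional list of per-run `n_volumes` x 6 matrices
#'   ([simulate_motion()] or read from file); `NULL` omits motion columns.
#' @param dt_oversample convolution grid spacing in seconds (default 0.1).
#' @param drop_initial initial volumes discarded per run (default 3).
#' @param hrf optional kernel sampled at `dt_oversample`; default canonical.
#' @return object of class `design_matrix`: list with `X` (rows = retained
#'   volumes across runs, columns = regressors), `roles` (per-column
#'   data.frame: role, run, trial_index, condition), `runs`, `n_volumes`,
#'   `tr`, `drop_initial`.
#' @export
build_design_matrix <- function(design, motion = NULL, dt_oversample = 0.1,
                                drop_initial = 3, hrf = NULL) {
  stopifnot(inherits(design, "story_design"))
  ev <- design$events
  nv <- design$n_volumes
  tr <- design$tr
  runs <- sort(unique(ev$run))
  keep <- (drop_initial + 1):nv
  nkeep <- length(keep)
  if (is.null(hrf)) hrf <- canonical_hrf(dt_oversample)
  if (!is.null(motion)) {
    stopifnot(length(motion) == length(runs))
    for (m in motion) stopifnot(nrow(m) == nv, ncol(m) == 6)
  }

  n_trials <- nrow(ev)
  n_runs <- length(runs)
  n_motion <- if (is.null(motion)) 0 else 6
  ncols <- n_trials + 1 + n_runs + n_motion
  X <- matrix(0, nkeep * n_runs, ncols)
  trial_cols <- seq_len(n_trials)
  probe_col <- n_trials + 1
  run_cols <- n_trials + 1 + seq_len(n_runs)
  motion_cols <- if (n_motion) n_trials + 1 + n_runs + 1:6 else integer(0)

  for (ri in seq_along(runs)) {
    r <- runs[ri]
    rows <- (ri - 1) * nkeep + seq_len(nkeep)
    rev_ev <- ev[ev$run == r, ]
    for (k in seq_len(nrow(rev_ev))) {
      tc <- regressor_timecourse(rev_ev$story_onset[k],
                                 rev_ev$story_duration[k],
                                 nv, tr, dt_oversample, hrf)
      X[rows, rev_ev$trial_index[k]] <- tc[keep]
    }
    pc <- regressor_timecourse(rev_ev$probe_onset, rev_ev$probe_duration,
                               nv, tr, dt_oversample, hrf)
    X[rows, probe_col] <- pc[keep]
    X[rows, run_cols[ri]] <- 1
    if (n_motion) X[rows, motion_cols] <- motion[[ri]][keep, ]
  }

  roles <- data.frame(
    role = c(rep("trial", n_trials), "probe",
             rep("run_intercept", n_runs), rep("motion", n_motion)),
    run = c(ev$run, NA, runs, rep(NA, n_motion)),
    trial_index = c(ev$trial_index, rep(NA, 1 + n_runs + n_motion)),
    condition = c(ev$condition, rep(NA, 1 + n_runs + n_motion)),
    stringsAsFactors = FALSE)
  colnames(X) <- c(sprintf("trial_%03d", ev$trial_index), "probe",
                   sprintf("run_%02d", runs),
                   if (n_motion) paste0("motion_", 1:6))
  structure(list(X = X, roles = roles, runs = runs, n_volumes = nv, tr = tr,
                 drop_initial = drop_initial),
            class = "design_matrix")
}

# Moore-Penrose pseudoinverse via SVD (used only for rank-deficient designs)
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Trialwise beta estimation by ordinary least squares
#'
#' Fits the full least-squares-all model (all trial regressors jointly, plus
#' nuisance columns) voxel-wise by OLS and returns the trial-regressor
#' coefficients as a beta series. The first `drop_initial` volumes of each
#' run (as recorded in the design matrix) are excluded from the BOLD data
#' before fitting. A rank-deficient design is solved by pseudoinverse with a
#' warning naming the collinear columns.
#'
#' @param bold a `bold_sim` (from [simulate_bold()]) or any list with
#'   `runs` (per-run volumes x voxels matrices) and `grid`.
#' @param design_matrix a `design_matrix` from [build_design_matrix()].
#' @param mask optional `voxel_mask` restricting the fit to its voxels;
#'   `NULL` fits all grid voxels.
#' @return object of class `beta_series`: list with `betas` (trials x
#'   voxels, rows ordered by run then within-run trial order), `condition`,
#'   `run`, `trial_index`, `voxels` (1-based linear grid indices of the
#'   columns), `grid`.
#' @export
fit_trial_betas <- function(bold, design_matrix, mask = NULL) {
  stopifnot(inherits(design_matrix, "design_matrix"))
  X <- design_matrix$X
  keep <- (design_matrix$drop_initial + 1):design_matrix$n_volumes
  Y <- do.call(rbind, lapply(bold$runs, function(m) m[keep, , drop = FALSE]))
  voxels <- seq_len(ncol(Y))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voxel_mask"))
    voxels <- mask$lin
    if (any(voxels > ncol(Y))) stop("mask lies outside the BOLD grid")
    Y <- Y[, voxels, drop = FALSE]
  }
  if (nrow(X) != nrow(Y)) {
    stop("design matrix rows (", nrow(X), ") do not match retained volumes (",
         nrow(Y), ")")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("design matrix is rank deficient; solving by pseudoinverse. ",
            "Collinear columns: ", paste(dropped, collapse = ", "))
    B <- pinv(X) %*% Y
  } else {
    B <- qr.coef(qx, Y)
  }
  trial_rows <- which(design_matrix$roles$role == "trial")
  ord <- order(design_matrix$roles$trial_index[trial_rows])
  trial_rows <- trial_rows[ord]
  structure(list(betas = unname(B[trial_rows, , drop = FALSE]),
                 condition = design_matrix$roles$condition[trial_rows],
                 run = design_matrix$roles$run[trial_rows],
                 trial_index = design_matrix$roles$trial_index[trial_rows],
                 voxels = voxels, grid = bold$grid),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("beta_series:", nrow(x$betas), "trials x", ncol(x$betas), "voxels (",
      length(unique(x$run)), "runs )\n")
  invisible(x)
}

#' Subset a beta series to a set of conditions
#'
#' @param beta_series a `beta_series`.
#' @param conditions condition labels to keep.
#' @return a `beta_series` with the matching rows.
#' @export
subset_conditions <- function(beta_series, conditions) {
  keep <- beta_series$condition %in% conditions
  out <- beta_series
  out$betas <- beta_series$betas[keep, , drop = FALSE]
  out$condition <- beta_series$condition[keep]
  out$run <- beta_series$run[keep]
  out$trial_index <- beta_series$trial_index[keep]
  out
}
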