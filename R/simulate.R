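#' Ground-truth effect specification for the BOLD simulator
#'
#' Pattern separation is a unitless scalar per contrast: the amplitude of a
#' contrast-specific multivoxel pattern (drawn once per subject from a
#' standard normal over voxels and fixed across runs) added with opposite
#' sign to the two classes of the contrast. `0` makes the two classes of
#' that contrast identically distributed (label-exchangeable data).
#'
#' @param attention,agent,social,interaction pattern separation per contrast
#'   (endo-vs-exo, self-vs-other, social-vs-nonsocial, attention x agent).
#' @param noise_sd marginal SD of the AR(1) noise, signal units (>= 0).
#' @param ar1_rho AR(1) autocorrelation, in `[0, 1)`.
#' @param drift_amplitude SD of the random slow cosine-drift coefficients.
#' @param base_amplitude shared evoked response amplitude for every trial.
#' @param probe_amplitude amplitude of the probe-phase response.
#' @param signal_mask optional `voxel_mask`: restrict all contrast patterns
#'   to these voxels (ground-truth signal region); `NULL` = whole grid.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(attention = 0, agent = 0, social = 0, interaction = 0,
                        noise_sd = 1, ar1_rho = 0.3, drift_amplitude = 0.5,
                        base_amplitude = 1, probe_amplitude = 0.5,
                        signal_mask = NULL) {
  stopifnot(noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1, drift_amplitude >= 0)
  structure(list(attention = attention, agent = agent, social = social,
                 interaction = interaction, noise_sd = noise_sd,
                 ar1_rho = ar1_rho, drift_amplitude = drift_amplitude,
                 base_amplitude = base_amplitude,
                 probe_amplitude = probe_amplitude,
                 signal_mask = signal_mask),
            class = "effect_spec")
}

# +/-1 factor codes per condition; nonsocial codes 0 on attention/agent/
# interaction and -1 on social.
condition_codes <- function(condition) {
  att <- ifelse(condition_attention(condition) == "endo", 1, -1)
  att[is.na(att)] <- 0
  ag <- ifelse(condition_agent(condition) == "self", 1, -1)
  ag[is.na(ag)] <- 0
  soc <- ifelse(is_social(condition), 1, -1)
  cbind(attention = att, agent = ag, social = soc, interaction = att * ag)
}

#' Simulate multivoxel BOLD runs for a timed design
#'
#' Generative model, per voxel v and run:
#' `signal(t) = sum_trials a(cond, v) * (boxcar(story) (*) HRF)(t)
#'  + probe_amplitude * (boxcar(probes) (*) HRF)(t) + drift(t) + AR(1) noise`,
#' where the amplitude map is
#' `a(cond, v) = base_amplitude + 0.5 * sum_c sep_c * code_c(cond) * w_c(v)`
#' over the four contrasts c, with `w_c ~ N(0, 1)` per voxel drawn once per
#' subject and fixed across runs (so leave-one-run-out generalization is the
#' quantity under test). Drift is a slow cosine basis (periods > 128 s);
#' noise is Gaussian AR(1) with marginal SD `noise_sd`.
#'
#' @param design a `story_design`.
#' @param grid a `voxel_grid` (the simulated field of view).
#' @param effects an [effect_spec()].
#' @param seed optional integer seed; output is deterministic given it.
#' @return object of class `bold_sim`: list with `runs` (per-run
#'   `n_volumes` x `n_voxels` matrices, voxels in linear grid order),
#'   `grid`, `amplitudes` (condition x voxel ground-truth map), `patterns`
#'   (the `w_c` vectors), `effects`.
#' @export
simulate_bold <- function(design, grid, effects = effect_spec(), seed = NULL) {
  stopifnot(inherits(design, "story_design"), inherits(grid, "voxel_grid"),
            inherits(effects, "effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  nv <- design$n_volumes
  tr <- design$tr
  n_vox <- prod(grid$dim)
  conds <- CONDITIONS[CONDITIONS %in% unique(design$events$condition)]
  if (length(conds) == 0) conds <- unique(design$events$condition)

  sep <- c(attention = effects$attention, agent = effects$agent,
           social = effects$social, interaction = effects$interaction)
  if (effects$noise_sd <= 0 && all(sep == 0)) {
    warning("noise_sd = 0 with all pattern separations 0: voxels are ",
            "degenerate (constant across conditions)")
  }
  W <- matrix(stats::rnorm(4 * n_vox), 4, n_vox,
              dimnames = list(names(sep), NULL))
  if (!is.null(effects$signal_mask)) {
    keep <- logical(n_vox)
    keep[effects$signal_mask$lin] <- TRUE
    W[, !keep] <- 0
  }
  codes <- condition_codes(conds)
  A <- effects$base_amplitude + 0.5 * (codes %*% (sep * W))
  rownames(A) <- conds

  hrf <- canonical_hrf(0.1)
  runs <- sort(unique(design$events$run))
  n_drift <- 3
  drift_basis <- sapply(seq_len(n_drift), function(k) {
    cos(pi * k * ((seq_len(nv) - 0.5) / nv))
  })

  out <- lapply(runs, function(r) {
    ev <- design$events[design$events$run == r, ]
    Xt <- vapply(seq_len(nrow(ev)), function(k) {
      regressor_timecourse(ev$story_onset[k], ev$story_duration[k],
                           nv, tr, 0.1, hrf)
    }, numeric(nv))
    probe <- regressor_timecourse(ev$probe_onset, ev$probe_duration,
                                  nv, tr, 0.1, hrf)
    sig <- Xt %*% A[ev$condition, , drop = FALSE] +
      effects$probe_amplitude * probe
    if (effects$drift_amplitude > 0) {
      coef <- matrix(stats::rnorm(n_drift * n_vox,
                                  sd = effects$drift_amplitude),
                     n_drift, n_vox)
      sig <- sig + drift_basis %*% coef
    }
    if (effects$noise_sd > 0) {
      innov_sd <- effects$noise_sd * sqrt(1 - effects$ar1_rho^2)
      eps <- matrix(stats::rnorm(nv * n_vox, sd = innov_sd), nv, n_vox)
      if (effects$ar1_rho > 0) {
        eps <- apply(eps, 2, function(e) {
          as.numeric(stats::filter(e, effects$ar1_rho, method = "recursive"))
        })
      }
      sig <- sig + eps
    }
    unname(sig)
  })
  structure(list(runs = out, grid = grid, amplitudes = A, patterns = W,
                 effects = effects),
            class = "bold_sim")
}

#' @export
print.bold_sim <- function(x, ...) {
  cat("bold_sim:", length(x$runs), "runs,", nrow(x$runs[[1]]),
      "volumes x", ncol(x$runs[[1]]), "voxels\n")
  invisible(x)
}

#' Simulate probe-phase behavioral responses
#'
#' One true/false response per trial: correctness is Bernoulli with
#' probability `p_correct` (scalar, or a named vector per condition) and
#' latency is Gaussian, truncated to the 4 s probe window.
#'
#' @param design a `story_design`.
#' @param p_correct probability of a correct response (scalar or named by
#'   condition), in `[0, 1]`.
#' @param latency_mean_ms,latency_sd_ms latency distribution parameters.
#' @param seed optional integer seed.
#' @return data.frame: `run`, `trial_index`, `condition`, `correct`
#'   (logical), `latency_ms` (bounded by the 4000 ms probe window).
#' @export
simulate_behavior <- function(design, p_correct = 0.9,
                              latency_mean_ms = 2000, latency_sd_ms = 400,
                              seed = NULL) {
  stopifnot(all(p_correct >= 0), all(p_correct <= 1))
  if (!is.null(seed)) set.seed(seed)
  ev <- design$events
  p <- if (length(p_correct) == 1) rep(p_correct, nrow(ev)) else {
    unname(p_correct[ev$condition])
  }
  lat <- stats::rnorm(nrow(ev), latency_mean_ms, latency_sd_ms)
  lat <- pmin(pmax(lat, 1), 1000 * ev$probe_duration)
  data.frame(run = ev$run, trial_index = ev$trial_index,
             condition = ev$condition,
             correct = stats::runif(nrow(ev)) < p,
             latency_ms = round(lat, 1), stringsAsFactors = FALSE)
}

#' Descriptive per-condition behavioral summary
#'
#' Mean and SEM of response accuracy (%) and latency (ms) per condition —
#' the descriptive shape of a behavioral summary table. When `responses`
#' pools several subjects (a `subject` column), subject means are summarized
#' instead of trials.
#'
#' @param responses data.frame from [simulate_behavior()], optionally with a
#'   `subject` column.
#' @return data.frame: condition, n, accuracy_pct, accuracy_sem,
#'   latency_ms, latency_sem.
#' @export
behavior_summary <- function(responses) {
  if (!is.null(responses$subject)) {
    per <- stats::aggregate(
      cbind(acc = 100 * responses$correct, lat = responses$latency_ms),
      by = list(condition = responses$condition, subject = responses$subject),
      FUN = mean)
  } else {
    per <- data.frame(condition = responses$condition,
                      acc = 100 * responses$correct,
                      lat = responses$latency_ms)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- function(f) stats::aggregate(cbind(acc, lat) ~ condition, per, f)
  m <- agg(mean)
  s <- agg(sem)
  data.frame(condition = m$condition,
             n = as.vector(table(per$condition)[m$condition]),
             accuracy_pct = round(m$acc, 1), accuracy_sem = round(s$acc, 2),
             latency_ms = round(m$lat, 0), latency_sem = round(s$lat, 1),
             stringsAsFactors = FALSE)
}
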