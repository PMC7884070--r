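# Shared fixtures and independent brute-force oracles.

# A desk-scale synthetic subject: design + motion + BOLD + GLM betas.
small_subject <- function(seed = 1, n_runs = 4, grid_dim = c(8, 8, 4),
                          effects = effect_spec(attention = 1),
                          with_motion = TRUE) {
  set.seed(seed)
  design <- simulate_design(n_runs = n_runs)
  grid <- make_grid(grid_dim)
  bold <- simulate_bold(design, grid, effects)
  motion <- if (with_motion) simulate_motion(n_runs, design$n_volumes) else NULL
  dm <- build_design_matrix(design, motion)
  list(design = design, grid = grid, bold = bold, motion = motion, dm = dm,
       betas = fit_trial_betas(bold, dm))
}

# Labeled pattern-set built directly from per-condition mean vectors:
# x_trial = mu[condition, ] + N(0, noise_sd). Two trials per condition per
# run, social conditions only unless mu has a nonsocial row.
make_patterns <- function(mu, n_runs = 6, per_run = 2, noise_sd = 0.1,
                          seed = 1) {
  set.seed(seed)
  conds <- rownames(mu)
  cond <- rep(rep(conds, each = per_run), n_runs)
  run <- rep(seq_len(n_runs), each = per_run * length(conds))
  x <- mu[cond, , drop = FALSE] +
    matrix(rnorm(length(cond) * ncol(mu), sd = noise_sd),
           length(cond), ncol(mu))
  structure(list(x = unname(x), condition = cond, run = run,
                 trial_index = seq_along(cond)),
            class = "pattern_set")
}

# Hand-built beta_series over a grid (bypasses the GLM) for searchlight
# and extraction tests.
make_beta_series <- function(betas, condition, run, grid) {
  structure(list(betas = betas, condition = condition, run = run,
                 trial_index = seq_along(condition),
                 voxels = seq_len(ncol(betas)), grid = grid),
            class = "beta_series")
}

# --- independent oracles ----------------------------------------------------

# OLS by explicit normal equations
ols_brute <- function(X, Y) solve(crossprod(X), crossprod(X, Y))

# Benjamini-Hochberg step-up, straight from the definition:
# adj_i = min_{j: rank_j >= rank_i} p_(j) * m / rank_j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(ranked)))
  adj <- numeric(m)
  adj[ord] <- pmin(adj_sorted, 1)
  adj
}

# sphere membership by scanning every voxel of the grid
sphere_brute <- function(center_mm, radius_mm, grid) {
  all_ijk <- as.matrix(expand.grid(i = 0:(grid$dim[1] - 1),
                                   j = 0:(grid$dim[2] - 1),
                                   k = 0:(grid$dim[3] - 1)))
  mm <- t(grid$affine %*% rbind(t(all_ijk), 1))[, 1:3, drop = FALSE]
  keep <- rowSums(sweep(mm, 2, center_mm)^2) <= radius_mm^2 + 1e-9
  ijk <- all_ijk[keep, , drop = FALSE]
  ijk[order(ijk[, 3], ijk[, 2], ijk[, 1]), , drop = FALSE]
}
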