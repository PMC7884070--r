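test_that("canonical HRF has the expected double-gamma shape", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(t[which.max(h)], 5.0, tolerance = 0.1 + 1e-9)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # late undershoot dips below zero
  expect_true(min(h) < 0)
  expect_error(canonical_hrf(0), "dt")
  expect_error(canonical_hrf(-0.1), "dt")
  expect_error(canonical_hrf(2), "dt")
})

test_that("the full design matrix has the protocol's regressor structure", {
  des <- simulate_design(seed = 3)
  motion <- simulate_motion(10, 130, seed = 3)
  dm <- build_design_matrix(des, motion)
  expect_equal(ncol(dm$X), 100 + 1 + 10 + 6)
  expect_equal(sum(dm$roles$role == "trial"), 100)
  expect_equal(sum(dm$roles$role == "probe"), 1)
  expect_equal(sum(dm$roles$role == "run_intercept"), 10)
  expect_equal(sum(dm$roles$role == "motion"), 6)
  # first three volumes of each run discarded
  expect_equal(nrow(dm$X), 10 * (130 - 3))
  # run-intercept columns are disjoint 0/1 blocks
  ri <- dm$X[, dm$roles$role == "run_intercept"]
  expect_true(all(ri %in% c(0, 1)))
  expect_true(all(rowSums(ri) == 1))
})

test_that("trial regressors are causal and block-structured across runs", {
  seq2 <- data.frame(run = rep(1:2, each = 2), trial = rep(1:2, 2),
                     condition = rep(c("endo_self", "exo_self"), 2))
  # 2 trials/run: 18 + 2*14 + 1*10 + 12 = 68 s -> 34 volumes at TR 2
  des <- assign_timing(seq2, n_volumes = 34, seed = 5)
  # force identical event times in both runs
  des$events[des$events$run == 2,
             c("story_onset", "probe_onset")] <-
    des$events[des$events$run == 1, c("story_onset", "probe_onset")]
  dm <- build_design_matrix(des, drop_initial = 0)
  nvol <- des$n_volumes
  # zero before onset (causal kernel)
  on <- des$events$story_onset[1]
  pre <- which((seq_len(nvol) - 1) * des$tr < on)
  expect_lt(max(abs(dm$X[pre, 1])), 1e-10)  # FFT convolution noise floor
  expect_true(any(dm$X[, 1] != 0))
  # run-2 trial columns are the run-1 columns shifted by one run block
  expect_equal(dm$X[nvol + seq_len(nvol), 3], dm$X[seq_len(nvol), 1])
  expect_equal(dm$X[nvol + seq_len(nvol), 4], dm$X[seq_len(nvol), 2])
  expect_true(all(dm$X[seq_len(nvol), 3:4] == 0))
  # onset beyond the run errors
  bad <- des
  bad$events$story_onset[1] <- 400
  expect_error(build_design_matrix(bad), "beyond run duration")
})

test_that("OLS betas agree with an explicit normal-equations solve", {
  subj <- small_subject(seed = 11, n_runs = 3, grid_dim = c(5, 5, 3))
  keep <- (subj$dm$drop_initial + 1):subj$design$n_volumes
  Y <- do.call(rbind, lapply(subj$bold$runs, function(m) m[keep, ]))
  B <- ols_brute(subj$dm$X, Y)
  trial_rows <- which(subj$dm$roles$role == "trial")
  expect_lt(max(abs(B[trial_rows, ] - subj$betas$betas)), 1e-8)
})

test_that("noiseless simulation recovers the generating amplitudes", {
  eff <- effect_spec(attention = 1.5, agent = 0.8, noise_sd = 0,
                     drift_amplitude = 0)
  subj <- small_subject(seed = 2, n_runs = 3, grid_dim = c(5, 5, 3),
                        effects = eff)
  truth <- subj$bold$amplitudes[subj$betas$condition, ]
  expect_lt(max(abs(subj$betas$betas - truth)), 1e-6)
})

test_that("beta estimation is linear and maps zero signal to zero betas", {
  subj <- small_subject(seed = 4, n_runs = 3, grid_dim = c(4, 4, 2))
  doubled <- subj$bold
  doubled$runs <- lapply(doubled$runs, function(m) 2 * m)
  b2 <- fit_trial_betas(doubled, subj$dm)
  expect_equal(b2$betas, 2 * subj$betas$betas, tolerance = 1e-10)
  zero <- subj$bold
  zero$runs <- lapply(zero$runs, function(m) m * 0)
  b0 <- fit_trial_betas(zero, subj$dm)
  expect_true(all(b0$betas == 0))
})

test_that("the endo/exo beta subset of the full design has 80 rows", {
  des <- simulate_design(seed = 6)
  grid <- make_grid(c(3, 3, 2))
  bold <- list(runs = lapply(1:10, function(r) matrix(0, 130, 18)),
               grid = grid)
  dm <- build_design_matrix(des)
  bs <- fit_trial_betas(bold, dm)
  expect_equal(nrow(bs$betas), 100)
  social_att <- subset_conditions(bs, c("endo_self", "endo_other",
                                        "exo_self", "exo_other"))
  expect_equal(nrow(social_att$betas), 80)
  expect_equal(social_att$run, sort(social_att$run))
})

test_that("rank-deficient designs fall back to a pseudoinverse with a warning", {
  subj <- small_subject(seed = 8, n_runs = 3, grid_dim = c(3, 3, 2),
                        with_motion = FALSE)
  motion <- simulate_motion(3, 130, seed = 8)
  motion <- lapply(motion, function(m) { m[, 6] <- m[, 5]; m })
  dm <- build_design_matrix(subj$design, motion)
  expect_warning(b <- fit_trial_betas(subj$bold, dm),
                 "rank deficient.*motion")
  expect_true(all(is.finite(b$betas)))
})
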