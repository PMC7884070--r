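test_that("fold normalization uses training statistics only", {
  train <- matrix(c(0, 2, 4, 1, 1, 1), 3, 2)  # col 2 has zero variance
  test <- matrix(c(4, 6, 5, 5), 2, 2)
  z <- zscore_fold(train, test)
  # (4 - 2) / 2 = 1 for a train column with mean 2, SD 2
  expect_equal(z$test[1, 1], 1)
  expect_equal(colMeans(z$train), c(0, 0), tolerance = 1e-12)
  expect_equal(sd(z$train[, 1]), 1, tolerance = 1e-12)
  # zero-variance column zeroed in both sets
  expect_true(all(z$train[, 2] == 0))
  expect_true(all(z$test[, 2] == 0))
  # leakage guard: perturbing test rows leaves the train transform unchanged
  z2 <- zscore_fold(train, test * 1000 + 7)
  expect_identical(z$train, z2$train)
})

test_that("leave-one-run-out decoding is perfect on wide-margin patterns", {
  mu <- rbind(endo_self = c(rep(5, 10), rep(0, 10)),
              exo_self = c(rep(0, 10), rep(5, 10)))
  pat <- make_patterns(mu, n_runs = 10, noise_sd = 0.2, seed = 3)
  res <- loro_decode(pat, classes = c("endo_self", "exo_self"))
  expect_equal(res$mean_accuracy, 100)
  expect_equal(res$n_folds, 10)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracies))
  expect_equal(res$chance, 50)
})

test_that("decoding validates run structure", {
  mu <- rbind(endo_self = rep(0, 4), exo_self = rep(1, 4))
  pat <- make_patterns(mu, n_runs = 3, seed = 1)
  # remove one class from run 2
  drop <- !(pat$run == 2 & pat$condition == "exo_self")
  expect_error(
    loro_decode(pat$x[drop, ], pat$condition[drop], pat$run[drop],
                classes = c("endo_self", "exo_self")),
    "run 2 is missing class 'exo_self'")
  one_run <- pat$run == 1
  expect_error(
    loro_decode(pat$x[one_run, ], pat$condition[one_run], pat$run[one_run],
                classes = c("endo_self", "exo_self")),
    ">= 2 runs")
})

test_that("cross-classification tracks the shared attention axis", {
  v1 <- c(rep(3, 8), rep(0, 8))
  v2 <- c(rep(0, 8), rep(3, 8))
  shared <- rbind(endo_self = v1, exo_self = -v1,
                  endo_other = v1, exo_other = -v1)
  orthogonal <- rbind(endo_self = v1, exo_self = -v1,
                      endo_other = v2, exo_other = -v2)
  flipped <- rbind(endo_self = v1, exo_self = -v1,
                   endo_other = -v1, exo_other = v1)
  pat_s <- make_patterns(shared, n_runs = 6, noise_sd = 0.3, seed = 2)
  pat_o <- make_patterns(orthogonal, n_runs = 6, noise_sd = 0.3, seed = 2)
  pat_f <- make_patterns(flipped, n_runs = 6, noise_sd = 0.3, seed = 2)
  within <- loro_decode(pat_s, classes = c("endo_self", "exo_self"))
  cc_s <- cross_classify(pat_s)
  cc_o <- cross_classify(pat_o)
  cc_f <- cross_classify(pat_f)
  # same axis: cross accuracy matches within-agent accuracy
  expect_equal(cc_s$mean_accuracy, within$mean_accuracy, tolerance = 5)
  expect_gt(cc_s$mean_accuracy, 90)
  # orthogonal axis: chance; opposite axis: systematically below chance
  expect_lt(abs(cc_o$mean_accuracy - 50), 15)
  expect_lt(cc_f$mean_accuracy, 20)
  expect_equal(cc_s$n_folds, 6)
})

test_that("interaction score is antisymmetric and signs follow the signal", {
  v <- c(rep(4, 6), rep(0, 6))
  self_only <- rbind(endo_self = v, exo_self = -v,
                     endo_other = rep(0, 12), exo_other = rep(0, 12))
  pat <- make_patterns(self_only, n_runs = 6, noise_sd = 0.5, seed = 9)
  sc <- interaction_score(pat)
  expect_gt(sc$score, 20)
  expect_equal(sc$score, sc$self_accuracy - sc$other_accuracy)
  # swap the agent roles: score negates exactly
  swap <- c(endo_self = "endo_other", exo_self = "exo_other",
            endo_other = "endo_self", exo_other = "exo_self")
  pat2 <- pat
  pat2$condition <- unname(swap[pat$condition])
  sc2 <- interaction_score(pat2)
  expect_equal(sc2$score, -sc$score)
})

test_that("searchlight localizes an embedded cluster and respects geometry", {
  grid <- make_grid(c(6, 6, 3), voxel_mm = 2.5)
  n_vox <- prod(grid$dim)
  set.seed(5)
  n_runs <- 4
  cond <- rep(rep(c("endo_self", "exo_self"), each = 2), n_runs)
  run <- rep(seq_len(n_runs), each = 4)
  betas <- matrix(rnorm(length(cond) * n_vox, sd = 0.5),
                  length(cond), n_vox)
  # signal cluster: voxel (2,2,1) and neighbors
  cluster_ijk <- rbind(c(2, 2, 1), c(3, 2, 1), c(1, 2, 1),
                       c(2, 3, 1), c(2, 1, 1))
  cl <- storymvpa:::voxel_linear_index(grid, cluster_ijk)
  sgn <- ifelse(cond == "endo_self", 3, -3)
  betas[, cl] <- betas[, cl] + sgn
  bs <- make_beta_series(betas, cond, run, grid)
  sl <- searchlight_map(bs, full_grid_mask(grid), "endo_vs_exo",
                        radius_vox = 1)
  # argmax lies in or adjacent to the signal cluster (accuracy can tie at
  # 100% for any center whose sphere touches the cluster)
  best <- full_grid_mask(grid)$ijk[which.max(sl$accuracy), ]
  dist_to_cluster <- min(apply(cluster_ijk, 1, function(cv) {
    max(abs(best - cv))
  }))
  expect_lte(dist_to_cluster, 1)
  expect_equal(sl$radius_vox, 1)
  expect_equal(dim(sl$map), grid$dim)
  expect_equal(sl$map[cbind(full_grid_mask(grid)$ijk + 1)],
               sl$accuracy)
})

test_that("a single-voxel searchlight decodes a separable voxel perfectly", {
  grid <- make_grid(c(3, 3, 1), voxel_mm = 2.5)
  cond <- rep(rep(c("endo_self", "exo_self"), each = 2), 3)
  run <- rep(1:3, each = 4)
  set.seed(8)
  betas <- matrix(rnorm(12 * 9, sd = 0.1), 12, 9)
  betas[, 5] <- ifelse(cond == "endo_self", 10, -10)
  bs <- make_beta_series(betas, cond, run, grid)
  sl <- searchlight_map(bs, full_grid_mask(grid), "endo_vs_exo",
                        radius_vox = 0)
  target <- which(full_grid_mask(grid)$lin == 5)
  expect_equal(sl$accuracy[target], 100)
})

test_that("social-vs-nonsocial contrasts decode with two trials per class per run", {
  mu <- rbind(endo_self = c(rep(3, 6), rep(0, 6)),
              exo_self = c(rep(3, 6), rep(0, 6)),
              endo_other = c(rep(3, 6), rep(0, 6)),
              exo_other = c(rep(3, 6), rep(0, 6)),
              nonsocial = c(rep(0, 6), rep(3, 6)))
  pat <- make_patterns(mu, n_runs = 4, noise_sd = 0.3, seed = 17)
  y <- contrast_labels(pat$condition, "endo_self_vs_nonsocial")
  expect_equal(levels(y), c("endo_self", "nonsocial"))
  expect_equal(sum(!is.na(y)), 4 * 4)  # 2 + 2 trials per run
  res <- decode_contrast(pat, "endo_self_vs_nonsocial")
  expect_equal(res$mean_accuracy, 100)
  expect_equal(res$n_folds, 4)
  expect_error(contrast_labels(pat$condition, "endo_vs_banana"),
               "unknown contrast")
})

test_that("univariate ROI contrast measures the mean amplitude difference", {
  grid <- make_grid(c(3, 3, 2), voxel_mm = 2.5)
  cond <- rep(rep(c("endo_self", "exo_self"), each = 2), 2)
  run <- rep(1:2, each = 4)
  base <- matrix(rep(1:18, each = 8), 8, 18)
  betas <- base + ifelse(cond == "endo_self", 0.75, 0)
  bs <- make_beta_series(betas, cond, run, grid)
  mask <- full_grid_mask(grid)
  expect_equal(roi_univariate_contrast(bs, mask, "endo_vs_exo"), 0.75)
  expect_equal(roi_univariate_contrast(bs, mask,
                                       c("exo_self", "endo_self")), -0.75)
})
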