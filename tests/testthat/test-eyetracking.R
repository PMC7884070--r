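eye_trial <- function(n_ms = 1000, x = 600, y = 500, pupil = 1000) {
  data.frame(time_ms = seq_len(n_ms) - 1, x = x, y = y, pupil = pupil)
}

test_that("blink cleaning flags the blink plus symmetric padding", {
  tr <- eye_trial(1000)
  expect_true(all(clean_blinks(tr)$valid))
  # constructed 100 ms blink at 400-499 ms, pad 50 each side
  tr$pupil[tr$time_ms >= 400 & tr$time_ms < 500] <- NA
  cleaned <- clean_blinks(tr, pad_ms = 50)
  expect_equal(sum(!cleaned$valid), 200)
  expect_true(all(!cleaned$valid[tr$time_ms >= 350 & tr$time_ms <= 549]))
  expect_error(clean_blinks(tr, pad_ms = -1), ">= 0")
})

test_that("moving-average smoothing matches its windowed-mean definition", {
  tr <- eye_trial(200, x = 7, y = -3)
  tr$valid <- TRUE
  expect_equal(smooth_gaze(tr)$x, tr$x)  # constant signal unchanged
  # unit step in x: linear ramp spanning the 20 ms window around the step
  step <- eye_trial(200, x = 0)
  step$x[step$time_ms >= 100] <- 1
  step$valid <- TRUE
  sm <- smooth_gaze(step, window_ms = 20)
  # pointwise oracle: mean over samples within +/- 10 ms
  oracle <- vapply(step$time_ms, function(t0) {
    mean(step$x[abs(step$time_ms - t0) <= 10])
  }, numeric(1))
  expect_equal(sm$x, oracle, tolerance = 1e-12)
  expect_true(all(diff(sm$x[sm$time_ms >= 85 & sm$time_ms <= 115]) >= 0))
  # an isolated valid sample between blinks equals itself
  iso <- eye_trial(61, x = rnorm(61))
  iso$valid <- FALSE
  iso$valid[31] <- TRUE
  expect_equal(smooth_gaze(iso, 20)$x[31], iso$x[31])
  expect_error(smooth_gaze(tr, 0), "> 0")
})

test_that("grid cell assignment matches a brute-force rectangle scan", {
  g <- gaze_grid(c(0, 80, 0, 40))
  set.seed(6)
  x <- runif(500, -10, 90)
  y <- runif(500, -5, 45)
  got <- grid_cell(g, x, y)
  for (i in seq_along(x)) {
    hit <- NA_integer_
    for (row in 0:3) for (col in 0:7) {
      x0 <- col * 10; y0 <- row * 10
      xin <- x[i] >= x0 & (x[i] < x0 + 10 | (col == 7 & x[i] == 80))
      yin <- y[i] >= y0 & (y[i] < y0 + 10 | (row == 3 & y[i] == 40))
      if (xin && yin) hit <- row * 8L + col + 1L
    }
    expect_identical(got[i], hit)
  }
  # max edges belong to the last cell
  expect_equal(grid_cell(g, 80, 40), 32L)
})

test_that("gaze-grid features have the documented 1056-dimensional layout", {
  g <- gaze_grid(c(0, 80, 0, 40))
  one <- eye_trial(500, x = 5, y = 5)
  one$valid <- TRUE
  f <- grid_featurize(one, g)
  expect_length(f, 1056)
  expect_equal(f[1], 1)       # all dwell time in cell 1
  expect_equal(sum(f[1:32]), 1)
  expect_true(all(f[33:1056] == 0))
  # alternation A,B,A,B over 4 samples: 3 transitions, 2 A->B and 1 B->A
  ab <- data.frame(time_ms = 0:3, x = c(5, 15, 5, 15), y = 5,
                   pupil = 1, valid = TRUE)
  fab <- grid_featurize(ab, g)
  expect_equal(fab[1:2], c(0.5, 0.5))
  trans <- matrix(fab[33:1056], 32, 32, byrow = TRUE)
  expect_equal(trans[1, 2], 2 / 3)
  expect_equal(trans[2, 1], 1 / 3)
  expect_equal(sum(trans), 1)
  expect_true(all(diag(trans) == 0))
  # counts mode
  fc <- grid_featurize(ab, g, counts = TRUE)
  expect_equal(matrix(fc[33:1056], 32, 32, byrow = TRUE)[1, 2], 2)
  # all samples invalid -> error
  dead <- eye_trial(100)
  dead$valid <- FALSE
  expect_error(grid_featurize(dead, g), "no valid")
})

test_that("transitions never span blink gaps or leave the grid", {
  g <- gaze_grid(c(0, 80, 0, 40))
  tr <- data.frame(time_ms = 0:5, x = c(5, 15, 15, 25, 500, 35), y = 5,
                   pupil = 1, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  f <- grid_featurize(tr, g)
  trans <- matrix(f[33:1056], 32, 32, byrow = TRUE)
  # only 1->2 survives: 2-3 blocked by invalid, 4-5/5-6 blocked off-grid
  expect_equal(trans[1, 2], 1)
  expect_equal(sum(trans > 0), 1)
})

test_that("condition-run averaging is an element-wise mean per cell", {
  v <- c(1, 2, 3); w <- c(5, 6, 7)
  # run 1: endo = {v, v} (identical vectors), exo = {v, w}
  # run 2: endo = {w, w}, exo = {v, w}
  feats <- rbind(v, v, v, w, w, w, v, w)
  cond <- rep(c("endo_self", "endo_self", "exo_self", "exo_self"), 2)
  run <- rep(1:2, each = 4)
  avg <- condition_run_average(feats, cond, run,
                               conditions = c("endo_self", "exo_self"))
  expect_equal(nrow(avg$features), 4)
  # two identical trial vectors average to themselves
  expect_equal(avg$features[avg$condition == "endo_self" & avg$run == 1, ],
               v, ignore_attr = TRUE)
  # v and w average element-wise
  expect_equal(avg$features[avg$condition == "exo_self" & avg$run == 2, ],
               (v + w) / 2, ignore_attr = TRUE)
  expect_error(
    condition_run_average(feats, cond, run,
                          conditions = c("endo_self", "nonsocial")),
    "nonsocial")
})

test_that("the default design yields 40 condition-run eye vectors", {
  des <- simulate_design(seed = 21)
  eye <- simulate_eye(des, rate = 100, seed = 21)
  social <- eye[is_social(eye$condition), ]
  ft <- featurize_trials(social, gaze_grid())
  expect_equal(nrow(ft$features), 80)
  avg <- condition_run_average(ft$features, ft$condition, ft$run)
  expect_equal(nrow(avg$features), 40)  # 4 conditions x 10 runs
  # fixation proportions sum to 1 for every trial
  expect_equal(rowSums(ft$features[, 1:32]), rep(1, 80), tolerance = 1e-12)
  # transition proportions sum to 1 or are all zero
  ts <- rowSums(ft$features[, 33:1056])
  expect_true(all(abs(ts - 1) < 1e-12 | ts == 0))
})

test_that("simulated eye streams are reproducible, blink-marked and decodable", {
  des <- simulate_design(n_runs = 4, seed = 5)
  e1 <- simulate_eye(des, rate = 250, seed = 9)
  e2 <- simulate_eye(des, rate = 250, seed = 9)
  expect_identical(e1, e2)
  expect_true(anyNA(e1$pupil))  # blink segments exist at the default rate
  # condition-biased gaze is decodable above chance
  des6 <- simulate_design(n_runs = 6, seed = 5)
  eye <- simulate_eye(des6, condition_weights = biased_gaze_weights(6),
                      rate = 250, seed = 10)
  social <- eye[is_social(eye$condition), ]
  ft <- featurize_trials(social, gaze_grid())
  avg <- condition_run_average(ft$features, ft$condition, ft$run)
  res <- eye_decode(avg, "endo_vs_exo")
  expect_gt(res$mean_accuracy, 75)
  expect_equal(res$n_folds, 6)
})
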