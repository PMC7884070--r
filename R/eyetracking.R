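#' Gaze grid over the story display area
#'
#' The screen region within which the stories are presented, divided into
#' an 8 x 4 grid of 32 equally sized cells (roughly eight words on each of
#' four lines). Cells partition the bounds exactly with half-open edges
#' (the right/top boundary belongs to the last cell).
#'
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)` in screen units.
#' @param n_cols,n_rows grid shape (defaults 8 x 4).
#' @return object of class `gaze_grid`.
#' @export
gaze_grid <- function(bounds = c(460, 1460, 390, 690), n_cols = 8,
                      n_rows = 4) {
  stopifnot(length(bounds) == 4, bounds[2] > bounds[1], bounds[4] > bounds[3],
            n_cols >= 1, n_rows >= 1)
  structure(list(bounds = bounds, n_cols = n_cols, n_rows = n_rows,
                 n_cells = n_cols * n_rows),
            class = "gaze_grid")
}

#' Grid cell of gaze positions
#'
#' Cell indices run 1..`n_cells`, row-major from the (xmin, ymin) corner:
#' `cell = row * n_cols + col + 1` with 0-based `col`/`row`. Positions
#' outside the bounds give `NA`; positions exactly on the max edge fall in
#' the last column/row.
#'
#' @param grid a `gaze_grid`.
#' @param x,y numeric vectors of screen coordinates.
#' @return integer vector of cell indices (`NA` off-grid).
#' @export
grid_cell <- function(grid, x, y) {
  b <- grid$bounds
  cw <- (b[2] - b[1]) / grid$n_cols
  ch <- (b[4] - b[3]) / grid$n_rows
  col <- floor((x - b[1]) / cw)
  row <- floor((y - b[3]) / ch)
  col[x == b[2]] <- grid$n_cols - 1
  row[y == b[4]] <- grid$n_rows - 1
  off <- is.na(x) | is.na(y) | col < 0 | col >= grid$n_cols | row < 0 |
    row >= grid$n_rows
  cell <- as.integer(row * grid$n_cols + col + 1)
  cell[off] <- NA_integer_
  cell
}

#' Flag blink-contaminated eye samples
#'
#' Samples with missing pupil mark blinks; these, plus `pad_ms` on each
#' side, are flagged invalid (no interpolation is performed). Any existing
#' `valid` flags are combined.
#'
#' @param stream data.frame with at least `time_ms` (strictly increasing
#'   within a trial) and `pupil` (`NA` = missing).
#' @param pad_ms padding applied on both sides of each blink (default 50).
#' @return the stream with a logical `valid` column.
#' @export
clean_blinks <- function(stream, pad_ms = 50) {
  if (pad_ms < 0) stop("pad_ms must be >= 0")
  t <- stream$time_ms
  blink <- is.na(stream$pupil)
  valid <- !blink
  if (any(blink) && pad_ms > 0) {
    r <- rle(blink)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      lo <- t[starts[k]] - pad_ms
      hi <- t[ends[k]] + pad_ms
      valid[t >= lo & t <= hi] <- FALSE
    }
  }
  if (!is.null(stream$valid)) valid <- valid & stream$valid
  stream$valid <- valid
  stream
}

#' Moving-average smoothing of gaze position
#'
#' Centered moving average of `x` and `y` over valid samples within
#' `window_ms / 2` on each side of every sample (inclusive). Invalid
#' samples keep their values and stay invalid; they contribute nothing to
#' the averages of their neighbors.
#'
#' @param stream data.frame with `time_ms`, `x`, `y` and (optionally)
#'   `valid`; run [clean_blinks()] first to derive validity.
#' @param window_ms window width in ms (default 20; must be > 0).
#' @return the stream with smoothed `x`, `y`.
#' @export
smooth_gaze <- function(stream, window_ms = 20) {
  if (window_ms <= 0) stop("window_ms must be > 0")
  t <- stream$time_ms
  valid <- if (is.null(stream$valid)) rep(TRUE, nrow(stream)) else {
    stream$valid
  }
  half <- window_ms / 2
  lo <- findInterval(t - half - 1e-9, t) + 1
  hi <- findInterval(t + half + 1e-9, t)
  vx <- ifelse(valid, stream$x, 0)
  vy <- ifelse(valid, stream$y, 0)
  cx <- c(0, cumsum(vx))
  cy <- c(0, cumsum(vy))
  cn <- c(0, cumsum(as.numeric(valid)))
  n <- cn[hi + 1] - cn[lo]
  sx <- (cx[hi + 1] - cx[lo]) / n
  sy <- (cy[hi + 1] - cy[lo]) / n
  upd <- valid & n > 0
  stream$x[upd] <- sx[upd]
  stream$y[upd] <- sy[upd]
  stream
}

#' Gaze-grid feature vector of one trial
#'
#' The 1056 eye-movement features of a trial: the proportion of valid
#' in-grid time spent in each of the 32 grid cells (fixation features),
#' followed by the 32 x 32 = 1024 directional cell-transition features. A
#' transition is counted whenever two consecutive valid samples fall in
#' different cells; pairs spanning an invalid (blink) gap or leaving the
#' grid are not counted, and same-cell pairs are not transitions (the
#' diagonal stays zero). Transitions are reported as proportions of all
#' transitions (all zero if none occurred) unless `counts = TRUE`.
#'
#' @param samples data.frame of one trial: `time_ms`, `x`, `y`, `valid`
#'   (from [clean_blinks()]; all-`TRUE` assumed if absent).
#' @param grid a `gaze_grid`.
#' @param counts report raw transition counts instead of proportions.
#' @return numeric vector of length `32 + 1024 = 1056` (fixation features
#'   first, then the row-major from-to transition matrix).
#' @export
grid_featurize <- function(samples, grid, counts = FALSE) {
  valid <- if (is.null(samples$valid)) rep(TRUE, nrow(samples)) else {
    samples$valid
  }
  cell <- grid_cell(grid, samples$x, samples$y)
  ok <- valid & !is.na(cell)
  if (!any(ok)) stop("no valid in-grid samples in this trial")
  nc <- grid$n_cells
  fix <- tabulate(cell[ok], nbins = nc)
  fix <- fix / sum(fix)
  from <- cell[-length(cell)]
  to <- cell[-1]
  pair_ok <- ok[-length(ok)] & ok[-1] & from != to
  trans <- matrix(0, nc, nc)
  if (any(pair_ok)) {
    tt <- table(factor(from[pair_ok], levels = 1:nc),
                factor(to[pair_ok], levels = 1:nc))
    trans <- matrix(as.numeric(tt), nc, nc)
    if (!counts) trans <- trans / sum(trans)
  }
  c(fix, as.vector(t(trans)))
}

#' Featurize every trial of an eye-tracking stream
#'
#' Splits a stream by `trial_index` and applies [grid_featurize()] to each
#' trial. A trial with no valid in-grid sample raises an error naming it.
#'
#' @param stream data.frame from [simulate_eye()] or [read_eye_csv()]:
#'   `time_ms`, `x`, `y`, `pupil`, `run`, `trial_index`, `condition`.
#' @param grid a `gaze_grid`.
#' @param pad_ms blink padding forwarded to [clean_blinks()].
#' @param window_ms smoothing window forwarded to [smooth_gaze()].
#' @param ... forwarded to [grid_featurize()].
#' @return list: `features` (trials x 1056 matrix), `condition`, `run`,
#'   `trial_index`.
#' @export
featurize_trials <- function(stream, grid, pad_ms = 50, window_ms = 20,
                             ...) {
  idx <- split(seq_len(nrow(stream)), stream$trial_index)
  feats <- lapply(names(idx), function(ti) {
    tr <- stream[idx[[ti]], ]
    tr <- clean_blinks(tr, pad_ms)
    tr <- smooth_gaze(tr, window_ms)
    tryCatch(grid_featurize(tr, grid, ...),
             error = function(e) stop("trial ", ti, ": ",
                                      conditionMessage(e)))
  })
  first <- vapply(idx, `[`, integer(1), 1)
  list(features = do.call(rbind, feats),
       condition = stream$condition[first],
       run = stream$run[first],
       trial_index = as.integer(names(idx)))
}

#' Average trial feature vectors per condition per run
#'
#' Element-wise arithmetic mean of the trial vectors of every
#' (condition, run) cell — one eye-movement feature vector per condition
#' per run. An empty cell raises an error naming it.
#'
#' @param features trials x features matrix.
#' @param condition,run per-trial labels.
#' @param conditions conditions to include (default the four social ones).
#' @return list: `features` (cells x 1056), `condition`, `run`.
#' @export
condition_run_average <- function(features, condition, run,
                                  conditions = SOCIAL_CONDITIONS) {
  runs <- sort(unique(run))
  cells <- expand.grid(condition = conditions, run = runs,
                       stringsAsFactors = FALSE)
  avg <- t(vapply(seq_len(nrow(cells)), function(i) {
    sel <- condition == cells$condition[i] & run == cells$run[i]
    if (!any(sel)) stop("no trials for condition '", cells$condition[i],
                        "' in run ", cells$run[i])
    colMeans(features[sel, , drop = FALSE])
  }, numeric(ncol(features))))
  list(features = avg, condition = cells$condition, run = cells$run)
}

#' Eye-movement decoding of a contrast
#'
#' Leave-one-run-out linear SVM (C = 1) on condition-per-run averaged
#' gaze-grid feature vectors, with the same fold-wise z-normalization as
#' the fMRI decoder. Group-level inference over subjects uses one-sample
#' t-tests against chance ([ttest_vs_chance()]).
#'
#' @param vectors output of [condition_run_average()] (or a list with
#'   `features`, `condition`, `run`).
#' @param contrast `"endo_vs_exo"`, `"self_vs_other"`, or a length-2 class
#'   vector.
#' @param cost SVM regularization.
#' @param subject_id carried into the result.
#' @return a `decoding_result`.
#' @export
eye_decode <- function(vectors, contrast = "endo_vs_exo", cost = 1,
                       subject_id = NULL) {
  y <- contrast_labels(vectors$condition, contrast)
  res <- loro_decode(vectors$features, y, vectors$run, classes = levels(y),
                     cost = cost, subject_id = subject_id)
  res$contrast <- if (length(contrast) == 2) {
    paste(contrast, collapse = " vs ")
  } else contrast
  res
}

#' Simulate eye-tracking samples for a timed design
#'
#' Gaze is generated as a sequence of fixations during each 10 s story
#' window: fixation target cells are drawn from per-condition cell weights
#' (uniform by default, i.e. gaze independent of condition), dwell times
#' are exponential, position is the cell center plus Gaussian jitter, and
#' blinks (missing pupil) arrive as a Poisson process. Samples are emitted
#' at `rate` Hz with strictly increasing within-trial timestamps.
#'
#' @param design a `story_design`.
#' @param grid a `gaze_grid` (display geometry of the story area).
#' @param condition_weights optional conditions x 32 matrix of cell-
#'   occupancy weights (rownames = condition labels); `NULL` = uniform.
#' @param fixation_mean_ms mean fixation dwell time (default 250).
#' @param jitter_sd positional jitter SD around cell centers, screen units.
#' @param blink_rate_per_min blink events per minute (default 15).
#' @param blink_dur_ms blink duration range, ms.
#' @param rate sampling rate in Hz (default 1000).
#' @param seed optional integer seed.
#' @return data.frame: `run`, `trial_index`, `condition`, `time_ms`
#'   (within-trial), `x`, `y`, `pupil` (`NA` during blinks).
#' @export
simulate_eye <- function(design, grid = gaze_grid(),
                         condition_weights = NULL, fixation_mean_ms = 250,
                         jitter_sd = 15, blink_rate_per_min = 15,
                         blink_dur_ms = c(100, 300), rate = 1000,
                         seed = NULL) {
  stopifnot(inherits(design, "story_design"), inherits(grid, "gaze_grid"))
  if (!is.null(seed)) set.seed(seed)
  b <- grid$bounds
  if (b[2] <= b[1] || b[4] <= b[3]) stop("empty story window")
  cw <- (b[2] - b[1]) / grid$n_cols
  ch <- (b[4] - b[3]) / grid$n_rows
  centers_x <- b[1] + (((1:grid$n_cells - 1) %% grid$n_cols) + 0.5) * cw
  centers_y <- b[3] + (((1:grid$n_cells - 1) %/% grid$n_cols) + 0.5) * ch
  ev <- design$events
  step <- 1000 / rate
  trials <- lapply(seq_len(nrow(ev)), function(i) {
    dur <- ev$story_duration[i] * 1000
    tt <- seq(0, dur - step, by = step)
    n <- length(tt)
    w <- if (is.null(condition_weights)) rep(1, grid$n_cells) else {
      condition_weights[ev$condition[i], ]
    }
    x <- numeric(n)
    y <- numeric(n)
    pos <- 1
    while (pos <= n) {
      cell <- sample.int(grid$n_cells, 1, prob = w)
      dwell <- max(80, stats::rexp(1, 1 / fixation_mean_ms))
      len <- min(n - pos + 1, max(1, round(dwell / step)))
      span <- pos:(pos + len - 1)
      x[span] <- centers_x[cell] + stats::rnorm(1, sd = jitter_sd) +
        stats::rnorm(len, sd = 2)
      y[span] <- centers_y[cell] + stats::rnorm(1, sd = jitter_sd) +
        stats::rnorm(len, sd = 2)
      pos <- pos + len
    }
    pupil <- 1000 + stats::rnorm(n, sd = 10)
    n_blink <- stats::rpois(1, blink_rate_per_min * dur / 60000)
    if (n_blink > 0) {
      starts <- stats::runif(n_blink, 0, dur)
      lens <- stats::runif(n_blink, blink_dur_ms[1], blink_dur_ms[2])
      for (k in seq_len(n_blink)) {
        pupil[tt >= starts[k] & tt <= starts[k] + lens[k]] <- NA
      }
    }
    data.frame(run = ev$run[i], trial_index = ev$trial_index[i],
               condition = ev$condition[i], time_ms = tt, x = x, y = y,
               pupil = pupil, stringsAsFactors = FALSE)
  })
  do.call(rbind, trials)
}

#' Condition-biased gaze weights
#'
#' A conditions x cells weight matrix in which each social condition
#' prefers its own block of 8 grid cells by a factor `1 + strength`
#' (nonsocial stays uniform). `strength = 0` restores condition-independent
#' gaze.
#'
#' @param strength preference strength (>= 0).
#' @param grid a `gaze_grid`.
#' @return matrix with rownames [CONDITIONS].
#' @export
biased_gaze_weights <- function(strength = 2, grid = gaze_grid()) {
  w <- matrix(1, length(CONDITIONS), grid$n_cells,
              dimnames = list(CONDITIONS, NULL))
  block <- floor(grid$n_cells / 4)
  for (i in 1:4) {
    cells <- ((i - 1) * block + 1):(i * block)
    w[SOCIAL_CONDITIONS[i], cells] <- 1 + strength
  }
  w
}
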