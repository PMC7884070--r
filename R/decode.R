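#' Fold-wise z-normalization
#'
#' Per-feature mean and SD are computed on the training rows only, and the
#' same transformation is applied to the held-out test rows — never the
#' reverse, so no test information leaks into training statistics.
#' Zero-variance training features are set to 0 in both sets.
#'
#' @param train,test numeric matrices with identical columns.
#' @return list with transformed `train` and `test`.
#' @export
zscore_fold <- function(train, test) {
  stopifnot(ncol(train) == ncol(test))
  n <- nrow(train)
  m <- colMeans(train)
  s <- sqrt(pmax(colSums(train^2) - n * m^2, 0) / (n - 1))
  bad <- !is.finite(s) | s < 1e-12
  s[bad] <- 1
  train <- sweep(sweep(train, 2, m), 2, s, "/")
  test <- sweep(sweep(test, 2, m), 2, s, "/")
  if (any(bad)) {
    train[, bad] <- 0
    test[, bad] <- 0
  }
  list(train = train, test = test)
}

# Leave-one-run-out folds with fold-wise normalization, prepared once.
# Normalization and the linear-kernel Gram matrices depend only on run
# membership (not labels), so folds can be precomputed and reused across
# the thousands of label permutations of the group inference.
prepare_loro_folds <- function(x, runs) {
  lapply(sort(unique(runs)), function(r) {
    tr <- runs != r
    z <- zscore_fold(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    list(run = r, train = z$train, test = z$test,
         train_idx = which(tr), test_idx = which(!tr),
         gram = tcrossprod(z$train), cross = tcrossprod(z$train, z$test))
  })
}

# Fold accuracies (%) for a given label vector on prepared folds.
# Ties (decision value exactly 0) go to the first class level.
decode_folds <- function(folds, y, cost = 1) {
  ycode <- as.integer(y)  # 1 = class A (positive), 2 = class B
  yi_all <- c(1L, -1L)[ycode]
  vapply(folds, function(f) {
    yi <- yi_all[f$train_idx]
    fit <- svm_gram_fit(f$gram, yi, cost, 1e-3, 100000L)
    score <- drop(crossprod(f$cross, fit$alpha * yi)) + fit$b
    100 * mean((1L + (score < 0)) == ycode[f$test_idx])
  }, numeric(1))
}

new_decoding_result <- function(contrast, fold_accuracies, runs,
                                subject_id = NULL) {
  structure(list(subject_id = subject_id, contrast = contrast,
                 fold_accuracies = stats::setNames(fold_accuracies,
                                                   paste0("run_", runs)),
                 mean_accuracy = mean(fold_accuracies),
                 n_folds = length(fold_accuracies), chance = 50),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result [%s]: mean accuracy %.1f%% over %d folds\n",
              x$contrast, x$mean_accuracy, x$n_folds))
  invisible(x)
}

#' Leave-one-run-out SVM decoding
#'
#' For each fold one run is held out; features are z-normalized with
#' training-run statistics ([zscore_fold()]), a linear SVM (C = `cost`) is
#' trained on the remaining runs and tested on the held-out run. Fold
#' accuracy is the percentage of correctly classified held-out trials;
#' the result is the arithmetic mean over folds (run-average accuracy),
#' chance level 50%.
#'
#' @param x trials x features matrix, or a `pattern_set`.
#' @param labels per-trial labels (ignored when `x` is a `pattern_set` and
#'   `contrast` is given); trials with `NA` labels are dropped.
#' @param runs per-trial run indices.
#' @param classes optional length-2 vector naming the two classes (first =
#'   class A); default: the two levels present.
#' @param cost SVM regularization (default 1).
#' @param subject_id carried into the result.
#' @return a `decoding_result`.
#' @export
loro_decode <- function(x, labels, runs, classes = NULL, cost = 1,
                        subject_id = NULL) {
  if (inherits(x, "pattern_set")) {
    runs <- x$run
    labels <- if (missing(labels)) x$condition else labels
    x <- x$x
  }
  if (is.null(classes)) {
    classes <- levels(factor(labels[!is.na(labels)]))
    if (length(classes) != 2) stop("need exactly two classes, got ",
                                   length(classes))
  }
  y <- factor(labels, levels = classes)
  keep <- !is.na(y)
  x <- as.matrix(x)[keep, , drop = FALSE]
  y <- y[keep]
  runs <- runs[keep]
  urun <- sort(unique(runs))
  if (length(urun) < 2) stop("leave-one-run-out needs >= 2 runs")
  for (r in urun) {
    tab <- table(factor(y[runs == r], levels = classes))
    if (any(tab == 0)) {
      stop("run ", r, " is missing class '",
           classes[which(tab == 0)[1]], "'")
    }
  }
  folds <- prepare_loro_folds(x, runs)
  acc <- decode_folds(folds, y, cost)
  new_decoding_result(paste(classes, collapse = " vs "), acc, urun,
                      subject_id)
}

#' Decode a named contrast from a pattern set
#'
#' Maps conditions to binary labels via [contrast_labels()] and runs
#' [loro_decode()].
#'
#' @param patterns a `pattern_set`.
#' @param contrast contrast name (see [contrast_labels()]).
#' @param cost SVM regularization.
#' @param subject_id carried into the result.
#' @return a `decoding_result`.
#' @export
decode_contrast <- function(patterns, contrast, cost = 1, subject_id = NULL) {
  stopifnot(inherits(patterns, "pattern_set"))
  y <- contrast_labels(patterns$condition, contrast)
  res <- loro_decode(patterns$x, y, patterns$run, classes = levels(y),
                     cost = cost, subject_id = subject_id)
  res$contrast <- if (length(contrast) == 2) {
    paste(contrast, collapse = " vs ")
  } else contrast
  res
}

#' Two-way cross-classification of attention type across agents
#'
#' One classifier is trained to discriminate endogenous vs exogenous
#' self-stories and tested on other-stories, a second is trained on
#' other-stories and tested on self-stories; the two run-average accuracies
#' are averaged. Folds are leave-one-run-out on the *test* agent: training
#' uses the train agent's trials from all other runs (normalization fitted
#' on those training trials only), testing the held-out run's trials of the
#' test agent. Setting `train_all_runs = TRUE` instead trains on all runs
#' of the train agent.
#'
#' @param x trials x features matrix, or a `pattern_set`.
#' @param condition per-trial condition labels (the four social conditions
#'   must all be present in every run).
#' @param runs per-trial run indices.
#' @param cost SVM regularization.
#' @param train_all_runs if `TRUE`, do not hold the test run out of the
#'   training agent's trials.
#' @return list with `mean_accuracy` (%), the two directional run-average
#'   accuracies (`self_to_other`, `other_to_self`) and `n_folds`.
#' @export
cross_classify <- function(x, condition, runs, cost = 1,
                           train_all_runs = FALSE) {
  if (inherits(x, "pattern_set")) {
    condition <- x$condition
    runs <- x$run
    x <- x$x
  }
  x <- as.matrix(x)
  keep <- is_social(condition)
  x <- x[keep, , drop = FALSE]
  condition <- condition[keep]
  runs <- runs[keep]
  urun <- sort(unique(runs))
  for (r in urun) {
    miss <- setdiff(SOCIAL_CONDITIONS, condition[runs == r])
    if (length(miss)) stop("run ", r, " is missing condition '", miss[1], "'")
  }
  att <- factor(condition_attention(condition), levels = c("endo", "exo"))
  agent <- condition_agent(condition)
  direction <- function(train_agent, test_agent) {
    acc <- vapply(urun, function(r) {
      tr <- agent == train_agent & (train_all_runs | runs != r)
      te <- agent == test_agent & runs == r
      z <- zscore_fold(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      fit <- svm_train(z$train, att[tr], cost = cost)
      100 * mean(predict(fit, z$test) == att[te])
    }, numeric(1))
    mean(acc)
  }
  s2o <- direction("self", "other")
  o2s <- direction("other", "self")
  list(mean_accuracy = (s2o + o2s) / 2, self_to_other = s2o,
       other_to_self = o2s, n_folds = length(urun))
}

#' Attention-by-agent interaction difference score
#'
#' Difference, in percentage points, between attention decoding within self
#' stories and within other stories:
#' `loro(endo_self vs exo_self) - loro(endo_other vs exo_other)`.
#' Swapping the roles of self and other negates the score exactly.
#'
#' @inheritParams cross_classify
#' @return list with `score` (points), `self_accuracy`, `other_accuracy`.
#' @export
interaction_score <- function(x, condition, runs, cost = 1) {
  if (inherits(x, "pattern_set")) {
    condition <- x$condition
    runs <- x$run
    x <- x$x
  }
  a_self <- loro_decode(x, condition, runs,
                        classes = c("endo_self", "exo_self"), cost = cost)
  a_other <- loro_decode(x, condition, runs,
                         classes = c("endo_other", "exo_other"), cost = cost)
  list(score = a_self$mean_accuracy - a_other$mean_accuracy,
       self_accuracy = a_self$mean_accuracy,
       other_accuracy = a_other$mean_accuracy)
}

#' Whole-grid searchlight decoding map
#'
#' For every voxel of `mask`, leave-one-run-out decoding is run on the
#' spherical neighborhood of radius `radius_vox` (Euclidean distance in
#' voxel units) intersected with the mask — partial spheres at the mask
#' edge are allowed — and the run-average accuracy is stored at the center
#' voxel.
#'
#' @param beta_series a `beta_series` covering the grid.
#' @param mask a `voxel_mask` (analysis mask, e.g. the simulated brain).
#' @param contrast contrast name or length-2 class vector
#'   (see [contrast_labels()]).
#' @param radius_vox sphere radius in voxels (default 4, i.e. 10 mm on a
#'   2.5 mm grid); recorded in the output.
#' @param cost SVM regularization.
#' @return list of class `searchlight_map`: `accuracy` (per mask voxel, in
#'   mask order), `mask`, `radius_vox`, `map` (3D array, `NA` outside the
#'   mask).
#' @export
searchlight_map <- function(beta_series, mask, contrast, radius_vox = 4,
                            cost = 1) {
  stopifnot(inherits(beta_series, "beta_series"),
            inherits(mask, "voxel_mask"), radius_vox >= 0)
  if (mask$n_voxels == 0) stop("empty searchlight mask")
  y <- contrast_labels(beta_series$condition, contrast)
  keep <- !is.na(y)
  xall <- beta_series$betas[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  runs <- beta_series$run[keep]

  r <- max(0, floor(radius_vox))
  off <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
  off <- off[rowSums(off^2) <= radius_vox^2 + 1e-9, , drop = FALSE]
  in_mask <- logical(prod(mask$grid$dim))
  in_mask[mask$lin] <- TRUE
  col_of <- match(mask$lin, beta_series$voxels)
  if (anyNA(col_of)) stop("mask voxels missing from the beta series")
  col_lookup <- integer(prod(mask$grid$dim))
  col_lookup[mask$lin] <- col_of

  acc <- vapply(seq_len(mask$n_voxels), function(v) {
    nb <- sweep(off, 2, mask$ijk[v, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < mask$grid$dim[1] &
      nb[, 2] >= 0 & nb[, 2] < mask$grid$dim[2] &
      nb[, 3] >= 0 & nb[, 3] < mask$grid$dim[3]
    lin <- voxel_linear_index(mask$grid, nb[ok, , drop = FALSE])
    lin <- lin[in_mask[lin]]
    cols <- col_lookup[lin]
    res <- loro_decode(xall[, cols, drop = FALSE], y, runs,
                       classes = levels(y), cost = cost)
    res$mean_accuracy
  }, numeric(1))

  map <- array(NA_real_, mask$grid$dim)
  map[mask$lin] <- acc
  structure(list(accuracy = acc, mask = mask, radius_vox = radius_vox,
                 map = map),
            class = "searchlight_map")
}

#' Univariate ROI contrast
#'
#' Mean over mask voxels of (mean beta of class A - mean beta of class B):
#' the simple amplitude-difference counterpart of the pattern analyses.
#' Antisymmetric in its classes. Group inference against zero is done
#' downstream (e.g. [ttest_vs_chance()] with `chance = 0`).
#'
#' @param beta_series a `beta_series`.
#' @param mask a `voxel_mask`.
#' @param contrast contrast name or length-2 class vector.
#' @return scalar mean contrast value (signal units).
#' @export
roi_univariate_contrast <- function(beta_series, mask, contrast) {
  pat <- extract_patterns(beta_series, mask)
  y <- contrast_labels(pat$condition, contrast)
  lev <- levels(y)
  a <- y == lev[1] & !is.na(y)
  b <- y == lev[2] & !is.na(y)
  if (!any(a) || !any(b)) stop("both contrast classes must be present")
  mean(colMeans(pat$x[a, , drop = FALSE]) -
         colMeans(pat$x[b, , drop = FALSE]))
}
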