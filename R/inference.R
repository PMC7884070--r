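#' Permutation p-value
#'
#' `p = (1 + #\{null > true\}) / (1 + N)`: the strict-inequality count, so
#' ties do not count as exceeding and the smallest attainable p is
#' `1/(N + 1)` (0.0001 for the usual 10,000 iterations).
#'
#' @param true_stat observed group statistic.
#' @param null_stats vector of permuted statistics (non-empty).
#' @return p-value in `[1/(N+1), 1]`.
#' @export
permutation_pvalue <- function(true_stat, null_stats) {
  if (length(null_stats) == 0) stop("empty null distribution")
  stopifnot(is.finite(true_stat), all(is.finite(null_stats)))
  (1 + sum(null_stats > true_stat)) / (1 + length(null_stats))
}

# Shuffle labels independently within each run (preserves per-run class
# counts and therefore run balance and fold structure).
permute_within_run <- function(labels, runs) {
  out <- labels
  for (r in unique(runs)) {
    idx <- which(runs == r)
    out[idx] <- labels[idx[sample.int(length(idx))]]
  }
  out
}

#' Percentile bootstrap confidence interval for a group mean
#'
#' Resamples individual-subject values with replacement `n_boot` times and
#' returns the percentile interval of the bootstrap means.
#'
#' @param values per-subject statistics (non-empty).
#' @param n_boot bootstrap iterations (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return length-2 numeric `(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed = NULL) {
  n <- length(values)
  if (n == 0) stop("no values to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  if (n == 1) {
    warning("bootstrap CI of a single value is degenerate")
    return(c(values, values))
  }
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  means <- rowMeans(matrix(values[idx], n_boot, n))
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate across a
#' family of tests (here, the six ROIs), in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order, capped at 1.
#' @export
fdr_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' One-sample t-test against chance
#'
#' Two-sided one-sample t-test of per-subject values against a chance level
#' (50% for binary decoding accuracies, 0 for difference scores).
#'
#' @param values per-subject statistics (>= 2, nonzero variance).
#' @param chance null-hypothesis mean (default 50).
#' @return list: `t`, `df`, `p` (two-sided), `mean`.
#' @export
ttest_vs_chance <- function(values, chance = 50) {
  if (length(values) < 2) stop("need >= 2 subjects")
  if (stats::sd(values) == 0) stop("zero variance across subjects")
  tt <- stats::t.test(values, mu = chance)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(values))
}

# Per-subject statistic dispatch used by group_permutation_test. Each
# returns a function of a condition-label vector so label permutations can
# be re-evaluated cheaply.
subject_statistic <- function(x, condition, runs, contrast, scheme, cost) {
  if (scheme == "loro") {
    y0 <- contrast_labels(condition, contrast)
    keep <- !is.na(y0)
    x <- as.matrix(x)[keep, , drop = FALSE]
    y0 <- droplevels(y0[keep])
    runs <- runs[keep]
    urun <- sort(unique(runs))
    if (length(urun) < 2) stop("leave-one-run-out needs >= 2 runs")
    for (r in urun) {
      tab <- table(y0[runs == r])
      if (any(tab == 0)) stop("run ", r, " is missing a contrast class")
    }
    folds <- prepare_loro_folds(x, runs)  # label-independent: cache
    list(true = function() mean(decode_folds(folds, y0, cost)),
         permuted = function() {
           mean(decode_folds(folds, permute_within_run(y0, runs), cost))
         })
  } else if (scheme == "interaction") {
    keep <- is_social(condition)
    x <- as.matrix(x)[keep, , drop = FALSE]
    cond <- condition[keep]
    runs <- runs[keep]
    list(true = function() interaction_score(x, cond, runs, cost)$score,
         permuted = function() {
           interaction_score(x, permute_within_run(cond, runs), runs,
                             cost)$score
         })
  } else if (scheme == "xclass") {
    keep <- is_social(condition)
    x <- as.matrix(x)[keep, , drop = FALSE]
    cond <- condition[keep]
    runs <- runs[keep]
    list(true = function() cross_classify(x, cond, runs, cost)$mean_accuracy,
         permuted = function() {
           cross_classify(x, permute_within_run(cond, runs), runs,
                          cost)$mean_accuracy
         })
  } else stop("unknown scheme: ", scheme)
}

#' Group-level permutation test on decoding statistics
#'
#' The observed group statistic is the mean over subjects of a per-subject
#' decoding statistic. Its null distribution is built by repeating the
#' identical analysis with condition labels shuffled independently within
#' each run within each subject (the most conservative exchangeable scheme
#' that preserves run balance and the leave-one-run-out fold structure);
#' iteration i pools the i-th permuted statistic from every subject into
#' one null group mean. The p-value follows [permutation_pvalue()]; a
#' percentile bootstrap CI over subjects accompanies it.
#'
#' Schemes: `"loro"` (run-average two-class accuracy, the binary class
#' labels of `contrast` are permuted among that analysis' trials),
#' `"interaction"` (difference score, 4-way social labels permuted),
#' `"xclass"` (two-way cross-classification accuracy, 4-way social labels
#' permuted).
#'
#' @param subjects list of per-subject `pattern_set`s (or lists with `x`,
#'   `condition`, `run`).
#' @param contrast contrast name or length-2 class vector (used by the
#'   `"loro"` scheme).
#' @param scheme statistic to test (see above).
#' @param n_perm permutation iterations (default 10000; must be >= 1).
#' @param n_boot bootstrap iterations for the CI.
#' @param cost SVM regularization.
#' @param seed optional integer seed.
#' @return object of class `group_inference`: `true_mean`,
#'   `subject_values`, `null_means`, `p_uncorrected`, `ci95`, `chance`,
#'   `n_perm`, `n_boot`, `n_subjects`, `contrast`, `scheme`; `p_fdr` is
#'   added by [decoding_report_table()].
#' @export
group_permutation_test <- function(subjects, contrast = "endo_vs_exo",
                                   scheme = c("loro", "interaction",
                                              "xclass"),
                                   n_perm = 10000, n_boot = 10000, cost = 1,
                                   seed = NULL) {
  scheme <- match.arg(scheme)
  if (length(subjects) < 2) stop("need >= 2 subjects")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stats_fns <- lapply(seq_along(subjects), function(s) {
    subj <- subjects[[s]]
    tryCatch(
      subject_statistic(subj$x, subj$condition, subj$run, contrast, scheme,
                        cost),
      error = function(e) stop("subject ", s, ": ", conditionMessage(e)))
  })
  subject_values <- vapply(seq_along(stats_fns), function(s) {
    tryCatch(stats_fns[[s]]$true(),
             error = function(e) stop("subject ", s, ": ",
                                      conditionMessage(e)))
  }, numeric(1))
  true_mean <- mean(subject_values)
  null_means <- vapply(seq_len(n_perm), function(it) {
    mean(vapply(seq_along(stats_fns), function(s) {
      tryCatch(stats_fns[[s]]$permuted(),
               error = function(e) stop("permutation ", it, ", subject ", s,
                                        ": ", conditionMessage(e)))
    }, numeric(1)))
  }, numeric(1))
  chance <- if (scheme == "interaction") 0 else 50
  contrast_label <- if (scheme != "loro") {
    scheme
  } else if (length(contrast) == 2) {
    paste(contrast, collapse = " vs ")
  } else contrast
  structure(list(contrast = contrast_label,
  scheme = scheme, true_mean = true_mean,
  subject_values = subject_values, null_means = null_means,
  p_uncorrected = permutation_pvalue(true_mean, null_means),
  ci95 = bootstrap_ci(subject_values, n_boot),
  chance = chance, n_perm = n_perm, n_boot = n_boot,
  n_subjects = length(subjects)),
  class = "group_inference")
}

#' @export
print.group_inference <- function(x, ...) {
  cat(sprintf(
    "group_inference [%s, %s]: mean %.2f (95%% CI %.2f-%.2f), p = %.4f (%d perms, %d subjects)\n",
    x$contrast, x$scheme, x$true_mean, x$ci95[1], x$ci95[2],
    x$p_uncorrected, x$n_perm, x$n_subjects))
  invisible(x)
}

#' ROI x contrast report table with FDR correction
#'
#' Assembles per-ROI group inferences for one contrast into a table shaped
#' like a standard ROI decoding summary: mean accuracy, 95% CI,
#' uncorrected permutation p, BH-FDR-adjusted p across the ROIs, and a
#' significance flag requiring both corrected p < 0.05 and a 95% CI that
#' does not cross chance.
#'
#' @param inferences named list of `group_inference` objects (one per ROI).
#' @param alpha significance threshold on the corrected p (default 0.05).
#' @return data.frame: roi, contrast, mean, ci_low, ci_high, p, p_fdr,
#'   significant.
#' @export
decoding_report_table <- function(inferences, alpha = 0.05) {
  stopifnot(length(inferences) >= 1)
  p <- vapply(inferences, function(g) g$p_uncorrected, numeric(1))
  p_fdr <- fdr_bh(p)
  data.frame(
    roi = if (is.null(names(inferences))) {
      paste0("roi_", seq_along(inferences))
    } else names(inferences),
    contrast = vapply(inferences, function(g) g$contrast, character(1)),
    mean = round(vapply(inferences, function(g) g$true_mean, numeric(1)), 2),
    ci_low = round(vapply(inferences, function(g) g$ci95[1], numeric(1)), 2),
    ci_high = round(vapply(inferences, function(g) g$ci95[2], numeric(1)), 2),
    p = p, p_fdr = p_fdr,
    significant = p_fdr < alpha & vapply(inferences, function(g) {
      g$ci95[1] > g$chance | g$ci95[2] < g$chance
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
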