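test_that("permutation p-values follow the add-one strict-exceedance rule", {
  nulls <- rep(0, 10000)
  # nothing exceeds: smallest reportable p = 1/10001
  expect_equal(permutation_pvalue(1, nulls), 1 / 10001)
  # everything exceeds
  expect_equal(permutation_pvalue(-1, rep(1, 500)), 1)
  # ties do not count as exceeding
  expect_equal(permutation_pvalue(0.5, rep(0.5, 500)), 1 / 501)
  expect_error(permutation_pvalue(1, numeric(0)), "empty")
})

test_that("permutation p is monotone non-increasing in the true statistic", {
  set.seed(1)
  for (i in 1:20) {
    nulls <- rnorm(200)
    p <- vapply(sort(rnorm(9)), permutation_pvalue,
                numeric(1), null_stats = nulls)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("bootstrap CI handles degenerate and ordinary inputs", {
  expect_equal(bootstrap_ci(rep(3.5, 8), n_boot = 100, seed = 1),
               c(3.5, 3.5))
  expect_warning(ci1 <- bootstrap_ci(2, n_boot = 10), "degenerate")
  expect_equal(ci1, c(2, 2))
  expect_error(bootstrap_ci(numeric(0)), "no values")
  set.seed(2)
  v <- rnorm(32, mean = 55, sd = 5)
  ci <- bootstrap_ci(v, n_boot = 2000, seed = 3)
  expect_lt(ci[1], ci[2])
  expect_lt(ci[1], mean(v))
  expect_gt(ci[2], mean(v))
  # deterministic given a seed
  expect_identical(ci, bootstrap_ci(v, n_boot = 2000, seed = 3))
})

test_that("BH-FDR reproduces the six-ROI worked examples", {
  # attention-type p-values across the six ROIs
  endo <- c(0.0046, 0.1148, 0.3518, 0.9547, 0.6439, 0.4428)
  expect_equal(fdr_bh(endo)[1], 0.0276)
  # agent p-values: monotonicity enforcement clamps 0.0053 * 6 = 0.0318
  agent <- c(0.0053, 0.1974, 0.0204, 0.1241, 0.0105, 0.0099)
  expect_equal(fdr_bh(agent)[1], 0.0210, tolerance = 1e-12)
  expect_equal(fdr_bh(0.03), 0.03)
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_bh(c(0.1, -0.2)), "\\[0, 1\\]")
})

test_that("BH-FDR equals the brute-force step-up definition", {
  set.seed(4)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_bh(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("one-sample t-test against chance matches the closed form", {
  v <- c(55, 60, 50, 55, 60)
  got <- ttest_vs_chance(v, chance = 50)
  # brute-force formula evaluation
  tval <- (mean(v) - 50) / (sd(v) / sqrt(length(v)))
  expect_equal(got$t, tval, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tval), length(v) - 1), tolerance = 1e-12)
  sym <- ttest_vs_chance(c(48, 52, 49, 51), chance = 50)
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_error(ttest_vs_chance(c(50, 50, 50)), "zero variance")
  expect_error(ttest_vs_chance(55), ">= 2")
})

test_that("group permutation test flags a strong embedded effect", {
  mu <- rbind(endo_self = c(rep(4, 6), rep(0, 6)),
              exo_self = c(rep(0, 6), rep(4, 6)),
              endo_other = c(rep(4, 6), rep(0, 6)),
              exo_other = c(rep(0, 6), rep(4, 6)))
  subs <- lapply(1:4, function(s) {
    make_patterns(mu, n_runs = 4, noise_sd = 0.5, seed = 100 + s)
  })
  g <- group_permutation_test(subs, "endo_vs_exo", n_perm = 199,
                              n_boot = 500, seed = 11)
  # accuracy exceeds every permuted mean: p at the formula floor
  expect_equal(g$true_mean, 100)
  expect_equal(g$p_uncorrected, 1 / 200)
  expect_equal(g$n_perm, 199)
  expect_equal(length(g$null_means), 199)
  expect_equal(g$ci95, c(100, 100))
  expect_error(group_permutation_test(subs, n_perm = 0), "n_perm")
  expect_error(group_permutation_test(subs[1]), ">= 2 subjects")
})

test_that("permutation schemes preserve per-run class balance", {
  labels <- rep(c("endo", "exo"), 10)
  runs <- rep(1:5, each = 4)
  set.seed(3)
  for (i in 1:50) {
    perm <- storymvpa:::permute_within_run(labels, runs)
    for (r in 1:5) {
      expect_equal(sort(perm[runs == r]), sort(labels[runs == r]))
    }
  }
})

test_that("report table assembles CI, FDR and the joint significance rule", {
  mu_sig <- rbind(endo_self = c(rep(3, 8), rep(0, 8)),
                  exo_self = c(rep(0, 8), rep(3, 8)),
                  endo_other = c(rep(3, 8), rep(0, 8)),
                  exo_other = c(rep(0, 8), rep(3, 8)))
  mu_null <- mu_sig * 0
  subs_sig <- lapply(1:4, function(s) make_patterns(mu_sig, n_runs = 4,
                                                    noise_sd = 0.5,
                                                    seed = 200 + s))
  subs_null <- lapply(1:4, function(s) make_patterns(mu_null, n_runs = 4,
                                                     noise_sd = 0.5,
                                                     seed = 300 + s))
  gs <- group_permutation_test(subs_sig, "endo_vs_exo", n_perm = 199,
                               n_boot = 500, seed = 1)
  gn <- group_permutation_test(subs_null, "endo_vs_exo", n_perm = 199,
                               n_boot = 500, seed = 2)
  tab <- decoding_report_table(list(signal = gs, null = gn))
  expect_equal(tab$roi, c("signal", "null"))
  expect_true(all(tab$p_fdr >= tab$p))
  expect_true(tab$significant[1])
  expect_false(tab$significant[2])
})
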