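# Effect sizes, intervals, correlations and JZS Bayes factors.

test_that("d from printed summaries reproduces the published worked examples", {
  expect_equal(round(d_from_summary(-1.83, 2.44), 2), 0.75)
  expect_equal(round(d_from_summary(-1.38, 2.52), 2), 0.55)
  expect_equal(d_from_summary(0, 2), 0)
  expect_error(d_from_summary(1, 0), "positive")
})

test_that("paired_effect matches hand computation and cross-checks t.test", {
  diffs <- c(-2, -1, -3, -2)
  eff <- paired_effect(diffs)
  expect_equal(eff$d, 2 / sd(diffs))
  expect_equal(round(eff$d, 3), 2.449)
  expect_equal(round(eff$t, 3), -4.899)
  tt <- t.test(diffs)
  expect_equal(eff$t, unname(tt$statistic))
  expect_equal(eff$p, tt$p.value)
  expect_error(paired_effect(rep(2, 10)), "zero variance")
  expect_error(paired_effect(c(1, 2)), "n >= 3")
})

test_that("d_from_summary and paired_effect agree on any sample", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1))
    eff <- paired_effect(x)
    expect_equal(eff$d, d_from_summary(mean(x), sd(x)), tolerance = 1e-12)
  }
})

test_that("paired d recovers the planted fear-row parameters by simulation", {
  set.seed(88)
  x <- rnorm(1698, -1.83, 2.44)
  eff <- paired_effect(x)
  d0 <- 1.83 / 2.44
  se_d <- sqrt(1 / 1698 + d0^2 / (2 * 1698))
  expect_lt(abs(eff$d - d0), 3 * se_d)
})

test_that("two-group pooled d reproduces the published group comparisons", {
  # term-mention split, anxiety and sadness rows
  expect_equal(round(two_sample_effect(-1.61, 2.45, 1010, -1.05, 2.57, 688)$d, 2), 0.22)
  expect_equal(round(two_sample_effect(-1.06, 2.70, 1010, -0.59, 2.74, 688)$d, 2), 0.17)
  # cluster age comparison
  age <- two_sample_effect(37.30, 12.08, 740, 35.39, 11.27, 958)
  expect_equal(round(age$d, 2), 0.16)
  expect_equal(round(age$ci_low, 2), 0.04)
  expect_equal(round(age$ci_high, 2), 0.29)
  expect_equal(two_sample_effect(4, 1, 10, 4, 2, 10)$d, 0)
  expect_error(two_sample_effect(1, 0, 10, 2, 1, 10), "positive")
})

test_that("one-sample profile flags the published non-significant cell", {
  ns <- one_sample_profile(-0.09, 1.96, 958, alpha = 0.01)
  expect_false(ns$significant)
  sig <- one_sample_profile(-3.06, 2.13, 740, alpha = 0.01)
  expect_true(sig$significant)
  expect_lt(sig$t, -38)
  zero <- one_sample_profile(0, 1.5, 100)
  expect_equal(zero$t, 0)
  expect_false(zero$significant)
})

test_that("one-sample test rejects at about the nominal 1% under the null", {
  set.seed(7)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i) {
    x <- rnorm(200)
    one_sample_profile(mean(x), sd(x), 200, alpha = 0.01)$significant
  }, logical(1))
  tol <- 3 * sqrt(0.01 * 0.99 / reps)
  expect_lt(abs(mean(rej) - 0.01), tol)
})

test_that("Pearson r with Fisher interval matches cor.test and recovers rho", {
  x <- 1:20
  expect_equal(pearson_r_ci(x, 2 * x + 1)$r, 1)
  set.seed(3)
  a <- rnorm(60); b <- a + rnorm(60)
  expect_equal(pearson_r_ci(a, -b)$r, -pearson_r_ci(a, b)$r)
  ours <- pearson_r_ci(a, b, level = 0.99)
  ct <- cor.test(a, b, conf.level = 0.99)
  expect_equal(ours$r, unname(ct$estimate))
  expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-10)
  # recovery at the planted worry-row correlation
  set.seed(19)
  z <- rnorm(1698); y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(1698)
  r_hat <- pearson_r_ci(z, y)$r
  expect_lt(abs(r_hat - 0.5), 3 * (1 - 0.25) / sqrt(1698))
  expect_error(pearson_r_ci(1:10, rep(2, 10)), "variance")
})

# ---- Bayes factors ---------------------------------------------------------

test_that("data at the null favour H0 for both designs", {
  expect_lt(jzs_bf_one_sample(0, 30)$bf10, 1)
  expect_lt(jzs_bf_two_sample(0, 50, 50)$bf10, 1)
})

test_that("both BF forms match the independent quadrature oracle to 1e-6", {
  for (t in c(0.5, 3, 7)) {
    for (n in c(10, 100, 1000)) {
      got <- jzs_bf_one_sample(t, n)$bf10
      want <- bf_oracle(t, n - 1, n)
      expect_lt(abs(got / want - 1), 1e-6)
    }
  }
  for (t in c(0, 2.5)) {
    got2 <- jzs_bf_two_sample(t, 40, 60)$bf10
    want2 <- bf_oracle(t, 98, 40 * 60 / 100)
    expect_lt(abs(got2 / want2 - 1), 1e-6)
  }
})

test_that("BF10 is strictly increasing in |t| at fixed n", {
  for (n in c(20, 1698)) {
    lb <- vapply(seq(0, 36, by = 2), function(t)
      jzs_bf_one_sample(t, n)$log10_bf10, numeric(1))
    expect_true(all(diff(lb) > 0))
  }
})

test_that("log10 BF stays finite and accurate in the extreme-evidence regime", {
  # paired t near 35 with n = 1698: BF10 overflows but its log must not
  res <- jzs_bf_one_sample(35.14, 1698)
  expect_true(is.finite(res$log10_bf10))
  expect_gt(res$log10_bf10, 190)
  expect_equal(res$bf10, 10^res$log10_bf10) # both Inf or both finite
})

test_that("BF at the printed anger-row statistic lands near the published value", {
  res <- jzs_bf_one_sample(4.2684, 1698)
  expect_gt(res$bf10, 100)
  expect_lt(res$bf10, 400)
})

test_that("two-sample BF at the printed anxiety split is of order 10^3", {
  sp <- sqrt((1009 * 2.45^2 + 687 * 2.57^2) / 1696)
  t9 <- (-1.61 - (-1.05)) / (sp * sqrt(1 / 1010 + 1 / 688))
  res <- jzs_bf_two_sample(t9, 1010, 688)
  expect_gt(res$log10_bf10, 2.5)
  expect_lt(res$log10_bf10, 3.5)
})

test_that("non-finite t is rejected", {
  expect_error(jzs_bf_one_sample(Inf, 30), "finite")
  expect_error(jzs_bf_one_sample(NaN, 30), "finite")
})

test_that("paired_summary mirrors its component statistics on a cohort", {
  pc <- pair_synth_cohort(generate_cohort(synth_config(n_participants = 80,
                                                       seed = 14),
                                          texts = FALSE))
  ps <- paired_summary(pc)
  expect_equal(nrow(ps), 9L)
  expect_equal(ps$emotion, emotion_names())
  i <- which(ps$emotion == "fear")
  eff <- paired_effect(pc$fear_2 - pc$fear_1)
  expect_equal(ps$d[i], eff$d)
  expect_equal(ps$t[i], eff$t)
  expect_equal(ps$log10_bf10[i],
               jzs_bf_one_sample(eff$t, nrow(pc))$log10_bf10)
  expect_equal(ps$r[i], cor(pc$fear_1, pc$fear_2))
  expect_true(all(ps$d_low <= ps$d & ps$d <= ps$d_high))
  expect_true(all(ps$p >= 0 & ps$p <= 1))
})
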