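test_that("bootstrap CIs collapse for constant data and stay seeded", {
  b <- bootstrap_mean_ci(rep(3, 20), n_boot = 50, seed = 1)
  expect_equal(b$mean, 3)
  expect_equal(b$ci_low, 3)
  expect_equal(b$ci_high, 3)

  expect_warning(b1 <- bootstrap_mean_ci(c(1, 2, 3), n_boot = 1, seed = 2),
                 "degenerate")
  expect_equal(b1$ci_low, b1$ci_high)

  x <- rnorm(50)
  expect_identical(bootstrap_mean_ci(x, seed = 9),
                   bootstrap_mean_ci(x, seed = 9))
})

test_that("bootstrap CI width shrinks like 1/sqrt(n)", {
  set.seed(4)
  ns <- c(25, 100, 400, 1600)
  widths <- vapply(ns, function(n) {
    w <- replicate(30, {
      b <- bootstrap_mean_ci(rnorm(n), n_boot = 200)
      b$ci_high - b$ci_low
    })
    mean(w)
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("session permutation test matches its analytic extremes", {
  x <- rnorm(50, 0, 1)
  pr <- session_pair(x, x + 10)  # 10 pooled SDs apart
  pt <- permutation_test(pr, n_iter = 1000, seed = 5)
  expect_equal(pt$p, 1 / 1001)  # the add-one floor
  expect_length(pt$null_diffs, 1000)

  same <- permutation_test(session_pair(x, x), n_iter = 500, seed = 6)
  expect_gt(same$p, 0.5)  # observed difference is exactly 0

  # label swap leaves p unchanged (exactly for equal trial counts)
  y <- rnorm(50, 0.3)
  expect_equal(permutation_test(session_pair(x, y), seed = 7)$p,
               permutation_test(session_pair(y, x), seed = 7)$p)
  y2 <- rnorm(35, 0.3)
  expect_lt(abs(permutation_test(session_pair(x, y2), seed = 7)$p -
                permutation_test(session_pair(y2, x), seed = 7)$p), 0.05)

  expect_warning(permutation_test(session_pair(x, y), n_iter = 50,
                                  seed = 1), "iterations")
})

test_that("the strict permutation variant is also calibrated", {
  set.seed(11)
  rej <- replicate(200, {
    a <- rnorm(20); b <- rnorm(20)
    permutation_test(session_pair(a, b), n_iter = 200,
                     method = "permutation")$p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("across-session variability separates pooled from shifted", {
  set.seed(12)
  same <- lapply(1:6, function(i) rnorm(30, 1, 0.5))
  r <- across_session_sd(same, n_rep = 200, seed = 13)
  expect_gt(r$ratio, 0.5)
  expect_lt(r$ratio, 1.6)

  apart <- list(rnorm(30, 1, 0.05), rnorm(30, 3, 0.05))
  r2 <- across_session_sd(apart, n_rep = 200, seed = 14)
  expect_gt(r2$ratio, 3)

  expect_error(across_session_sd(list(rnorm(10))), "2 sessions")
})

test_that("within/outside-5% flags inflated single-session variability", {
  set.seed(15)
  # identical sessions are not flagged
  x <- rnorm(40)
  w0 <- within_outside_5pct(session_pair(x, x), n_iter = 400, seed = 16)
  expect_false(w0$flag_1)
  expect_false(w0$flag_2)

  # a session with 5x trial noise is flagged
  w1 <- within_outside_5pct(session_pair(rnorm(40, 0, 1), rnorm(40, 0, 5)),
                            n_iter = 400, seed = 17)
  expect_true(w1$flag_2)

  # exchangeable sessions: flag rate per session stays near 5%
  flags <- replicate(60, {
    w <- within_outside_5pct(session_pair(rnorm(25), rnorm(25)),
                             n_iter = 200)
    c(w$flag_1, w$flag_2)
  })
  expect_gte(mean(!flags[1, ]), 0.85)
  expect_gte(mean(!flags[2, ]), 0.85)
})

test_that("waveform similarity is a guarded Pearson correlation", {
  w <- sin(seq(0, 2 * pi, length.out = 40))
  expect_equal(waveform_similarity(w, w), 1)
  expect_equal(waveform_similarity(w, -w), -1)
  set.seed(18)
  noisy <- w + rnorm(40, sd = sd(w) / sqrt(10))  # SNR 10
  expect_gt(waveform_similarity(w, noisy), 0.9)
  expect_error(waveform_similarity(w, w[-1]), "equal length")
  expect_error(waveform_similarity(rep(1, 5), 1:5), "variance")
})

test_that("rank-sum p values match exact enumeration", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)  # 2/20 extremes
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(19)
  expect_lt(rank_sum_test(rnorm(50), rnorm(50, 3)), 1e-6)
})

test_that("baseline matching uses the mm tolerance", {
  pr <- session_pair(rnorm(10, 1), rnorm(10, 1),
                     baseline_1 = 0.71, baseline_2 = 0.75, units = "mm")
  expect_true(baseline_matched(pr))
  pr$baseline_2 <- 0.80
  expect_false(baseline_matched(pr))
})
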