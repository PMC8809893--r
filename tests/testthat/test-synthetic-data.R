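test_that("spike generation respects degenerate configurations", {
  cfg0 <- sim_config(duration = 200, cluster_rate = 0, seed = 1)
  expect_equal(n_spikes(generate_spike_train(cfg0)), 0)

  # geometric parameter 1 forces all cluster sizes to 1: pure Poisson train
  cfg1 <- sim_config(duration = 500, cluster_size_dist = 1, seed = 2)
  st <- generate_spike_train(cfg1)
  expect_true(all(attr(st, "gt_sizes") == 1))
  expect_equal(n_spikes(st), length(attr(st, "gt_onsets")))

  # intra-cluster ISI must stay below the median inter-cluster gap
  expect_error(sim_config(cluster_rate = 2, intra_cluster_isi = 0.5),
               "merge")
})

test_that("cluster counts and sizes follow the generative law", {
  cfg <- sim_config(duration = 10000, cluster_rate = 0.1,
                    cluster_size_dist = 0.55, seed = 31)
  st <- generate_spike_train(cfg)
  n_cl <- length(attr(st, "gt_onsets"))
  expect_lt(abs(n_cl - 1000), 3 * sqrt(1000))

  # chi-square against the geometric pmf, tail pooled
  sizes <- attr(st, "gt_sizes")
  kmax <- 6
  obs <- c(tabulate(pmin(sizes, kmax + 1), nbins = kmax + 1))
  p <- 0.55 * (1 - 0.55)^(0:(kmax - 1))
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)

  # occurrence of sizes decays monotonically
  occ <- tabulate(sizes)
  expect_true(all(diff(occ[1:5]) < 0))
})

test_that("pupil generation reduces to its components", {
  cfg <- sim_config(duration = 100, cluster_rate = 0, gain = 0,
                    noise_sd = 0, drift_sd = 0, seed = 3)
  st <- generate_spike_train(cfg)
  tr <- generate_pupil(st, cfg)
  expect_true(all(tr$values == 0))
  expect_equal(tr$rate, 50)
  expect_equal(length(tr$values), 100 * 50 + 1)

  # a single spike with no noise/drift reproduces the kernel exactly
  cfg1 <- sim_config(duration = 100, cluster_rate = 0, gain = 1,
                     noise_sd = 0, drift_sd = 0)
  one <- spike_train(5, t_end = 100)
  tr1 <- generate_pupil(one, cfg1)
  pk <- triggered_peak(tr1, 5, window = 6)
  expect_equal(pk$latency, cfg1$kernel$peak_latency)
  expect_equal(pk$peak, cfg1$kernel$amplitude)
  t_rel <- trace_times(tr1) - 5
  expect_lt(max(abs(tr1$values - kernel_eval(cfg1$kernel, t_rel))), 1e-9)
})

test_that("zero-gain pupil is uncorrelated with the spike train", {
  cfg <- sim_config(duration = 1000, gain = 0, drift_sd = 0,
                    noise_sd = 1, seed = 17)
  st <- generate_spike_train(cfg)
  tr <- generate_pupil(st, cfg)
  counts <- tabulate(floor(st$times * cfg$rate_hz) + 1L,
                     nbins = length(tr$values))
  cc <- ccf(counts, tr$values, lag.max = 50, plot = FALSE)$acf
  # family-wise 99.9% null bound for the maximum over the tested lags
  bound <- qnorm(1 - 0.0005 / length(cc)) / sqrt(length(tr$values))
  expect_lt(max(abs(cc)), bound)
})

test_that("generation is seed-reproducible", {
  cfg <- sim_config(duration = 300, seed = 99)
  a <- generate_spike_train(cfg)
  b <- generate_spike_train(cfg)
  expect_identical(a$times, b$times)
  expect_identical(generate_pupil(a, cfg)$values,
                   generate_pupil(b, cfg)$values)
})

test_that("session pairs respond to gain and share protocols", {
  stim <- data.frame(onset_s = seq(10, 730, by = 15), pulse_ms = 10,
                     n_pulses = 4L, freq_hz = 10)
  cfg <- sim_config(duration = 750, seed = 5)
  # identical configs and seeds give identical sessions
  pr0 <- generate_session_pair(cfg, cfg, stim)
  expect_identical(pr0$responses_1, pr0$responses_2)

  # doubling the gain roughly doubles the mean evoked peak
  cfg_a <- sim_config(duration = 750, gain = 1, drift_sd = 0.3, seed = 6)
  cfg_b <- sim_config(duration = 750, gain = 2, drift_sd = 0.3, seed = 7)
  pr <- generate_session_pair(cfg_a, cfg_b, stim)
  ratio <- mean(pr$responses_2) / mean(pr$responses_1)
  ci <- bootstrap_mean_ci(pr$responses_2 / mean(pr$responses_1),
                          n_boot = 200, seed = 8)
  expect_gt(ci$ci_high, 2 * 0.8)
  expect_lt(ci$ci_low, 2 * 1.2)
  expect_gt(ratio, 1.4)

  # configs may differ only in gain/noise/seed
  cfg_c <- sim_config(duration = 750, cluster_rate = 0.2, seed = 6)
  expect_error(generate_session_pair(cfg_a, cfg_c, stim), "differ only")
  # overlapping stimulation trials are rejected
  bad <- data.frame(onset_s = c(10, 15), pulse_ms = 10, n_pulses = 4L,
                    freq_hz = 10)
  expect_error(generate_session_pair(cfg_a, cfg_b, bad), "inter-trial")
})

test_that("behavioral sessions hit their outcome rates", {
  tr <- generate_behavior_session(1, 0, 60, seed = 4)
  expect_true(all(tr$outcome[tr$stim_present] == "hit"))
  expect_true(all(tr$outcome[!tr$stim_present] == "cr"))
  expect_equal(trial_licks(tr), sort(tr$onset_s[tr$response] + 0.4))

  tr2 <- generate_behavior_session(0.7, 0.1, 400, seed = 5)
  s <- summarize_behavior(tr2)
  # within the binomial 99% bound
  expect_lt(abs(s$hit_rate - 0.7),
            qnorm(0.995) * sqrt(0.7 * 0.3 / s$n_go))

  s3 <- summarize_behavior(generate_behavior_session(0.5, 0.5, 2000,
                                                     seed = 6))
  expect_lt(abs(s3$bias), 0.15)  # symmetric case: bias near 0

  expect_error(generate_behavior_session(0.5, 0.5, 0), "n_trials")
})
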