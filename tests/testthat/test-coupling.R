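test_that("triggered peaks report the window maximum and latency", {
  v <- numeric(501)  # 10 s at 50 Hz
  v[256] <- 1.7      # t = 5.1 s
  tr <- z_trace(v)
  pk <- triggered_peak(tr, onset = 2, window = 6)
  expect_equal(pk$peak, 1.7)
  expect_equal(pk$latency, 3.1)
  expect_false(pk$excluded)

  # onset too close to the end of the recording is excluded
  expect_true(triggered_peak(tr, onset = 8, window = 6)$excluded)

  # signed maximum by default; absolute switch picks the constriction
  v2 <- numeric(501); v2[150] <- 0.4; v2[200] <- -2
  tr2 <- z_trace(v2)
  expect_equal(triggered_peak(tr2, 0, 6)$peak, 0.4)
  expect_equal(triggered_peak(tr2, 0, 6, absolute = TRUE)$peak, -2)
})

test_that("coupling curves summarize responses by cluster size", {
  peaks <- data.frame(onset_s = 1:8, size = c(1, 1, 1, 2, 2, 3, 3, 3),
                      peak = c(0.2, 0.3, 0.4, 0.5, 0.7, 0.7, 0.8, 0.6),
                      latency = 3, excluded = FALSE)
  cv <- coupling_curve(peaks)
  expect_equal(cv$size, 1:3)
  expect_equal(cv$mean_peak, c(0.3, 0.6, 0.7))
  expect_equal(cv$occurrence, c(3, 2, 3) / 8)
  expect_equal(sum(cv$occurrence), 1)
  expect_equal(cv$sem[1], sd(c(0.2, 0.3, 0.4)) / sqrt(3))
  expect_true(all(cv$low_n))

  # excluded responses are dropped
  peaks$excluded[1] <- TRUE
  expect_equal(coupling_curve(peaks)$n[1], 2)
})

test_that("linear fits reproduce closed-form least squares", {
  cv <- structure(data.frame(size = 1:3, n = 10, mean_peak = 0.25 * (1:3),
                             sem = 0.01, occurrence = 1 / 3, low_n = FALSE),
                  class = c("coupling_curve", "data.frame"))
  fit <- fit_linear(cv)
  expect_equal(fit$slope, 0.25)
  expect_equal(fit$r2, 1)

  cv$mean_peak <- rep(0.4, 3)
  fit0 <- fit_linear(cv)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r2, 0)

  # hand-computed OLS: slope 0.2, r2 = 12/13
  cv$mean_peak <- c(0.3, 0.4, 0.7)
  fit2 <- fit_linear(cv)
  expect_equal(fit2$slope, 0.2)
  expect_equal(fit2$r2, 12 / 13)

  cv2 <- cv[1:2, ]
  class(cv2) <- class(cv)
  expect_error(fit_linear(cv2), "3 distinct")
})

test_that("pre-event spike windows are half-open [-4, -2)", {
  st <- spike_train(c(6.0, 7.0, 8.0, 9.0), t_end = 20)
  # event at 10: window [6, 8): spikes at 6, 7 counted; 8, 9 not
  expect_equal(spikes_before_event(st, 10)$count, 2)
  # spike exactly at event - 2 is outside
  expect_equal(spikes_before_event(st, 10.0)$count, 2)
  expect_equal(spikes_before_event(st, 11)$count, 2)  # window [7, 9)
  # window preceding the recording start is excluded
  ex <- spikes_before_event(st, 3)
  expect_true(ex$excluded)
  expect_true(is.na(ex$count))
})

test_that("event binning is 0.3 SD with an overflow report", {
  counts <- data.frame(amplitude_sd = c(0.31, 0.1, 1.0, 2.95, 3.2, -0.5),
                       count = c(2, 1, 3, 6, 9, 0), excluded = FALSE)
  b <- bin_events(counts)
  expect_equal(nrow(b), 10)
  expect_equal(b$n[b$bin_index == 1], 1)   # 0.31 -> bin 1
  expect_equal(b$n[b$bin_index == 0], 1)
  expect_equal(b$mean_count[b$bin_index == 9], 6)
  expect_equal(attr(b, "overflow"), 1)     # 3.2 excluded but reported
  expect_equal(attr(b, "underflow"), 1)
  expect_equal(sum(b$n), 4)
  expect_equal(sum(b$occurrence), 1)
})

test_that("lick exclusion removes clusters in the closed +/-0.5 s window", {
  st <- spike_train(c(1, 3, 5, 7, 9), t_end = 10)
  cl <- cluster_spikes(st, threshold = 0.5)  # all singles
  expect_equal(nrow(exclude_licking(cl, numeric(0))), 5)
  # lick at 2.5: cluster at 3 is exactly lick + 0.5 -> excluded (closed)
  kept <- exclude_licking(cl, licks = 2.5)
  expect_equal(kept$onset_s, c(1, 5, 7, 9))
  # licks blanketing the session at 0.9-s spacing remove everything
  expect_equal(nrow(exclude_licking(cl, seq(0.5, 9.5, by = 0.9))), 0)
})

test_that("derivative responses peak before the value response", {
  ramp <- fun_trace(function(t) 0.3 * t, dur = 20)
  dr <- derivative_response(ramp, onset = 2, window = 6)
  expect_equal(dr$peak, 0.3, tolerance = 1e-9)

  flat <- fun_trace(function(t) rep(1, length(t)), dur = 20)
  expect_equal(derivative_response(flat, 2, 6)$peak, 0)

  # unimodal kernel: derivative peak earlier than value peak
  cfg <- sim_config(duration = 100, cluster_rate = 0, gain = 1,
                    noise_sd = 0, drift_sd = 0)
  tr <- generate_pupil(spike_train(5, t_end = 100), cfg)
  vp <- triggered_peak(tr, 5, 6)
  dp <- derivative_response(tr, 5, 6)
  expect_lt(dp$latency, vp$latency)
})

test_that("cluster-level slope recovers a linear generative coupling", {
  cfg <- sim_config(duration = 1800, gain = 2, seed = 12)
  st <- generate_spike_train(cfg)
  tr <- generate_pupil(st, cfg)
  pk <- triggered_peaks(tr, cluster_spikes(st))
  sl <- coupling_slope(pk)
  expect_gt(sl$slope, 0)
  expect_gt(sl$slope / sl$se, 3)
  # per-size means rise with size over the well-populated sizes
  cv <- coupling_curve(pk)
  main <- cv[cv$n >= 10, ]
  expect_gt(cor(main$size, main$mean_peak, method = "spearman"), 0.8)
})
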