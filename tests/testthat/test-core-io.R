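test_that("spike files parse per unit, sort and collapse duplicates", {
  p <- tmp_csv(data.frame(unit_id = "u1", time_s = c(0.5, 1.2, 3.4)))
  st <- read_spikes(p)
  expect_length(st, 1)
  expect_equal(st$u1$times, c(0.5, 1.2, 3.4))

  p2 <- tmp_csv(data.frame(unit_id = c("a", "a", "b"),
                           time_s = c(1, 2, 0.5)))
  expect_length(read_spikes(p2), 2)

  # duplicated time collapses to the set of unique times, with a warning
  tt <- c(0.5, 1.2, 1.2, 3.4)
  p3 <- tmp_csv(data.frame(unit_id = "u1", time_s = tt))
  expect_warning(st3 <- read_spikes(p3), "duplicate")
  expect_equal(st3$u1$times, sort(unique(tt)))

  p4 <- tmp_csv(data.frame(unit_id = "u1", time_s = c(3, 1, 2)))
  expect_warning(st4 <- read_spikes(p4), "not sorted")
  expect_equal(st4$u1$times, c(1, 2, 3))

  expect_error(read_spikes(tmp_csv(data.frame(unit_id = "u1", t = 1))),
               "columns")
})

test_that("pupil files snap to the rate grid and interpolate short gaps", {
  t <- seq(0, 2, by = 0.02)
  p <- tmp_csv(data.frame(time_s = t, diameter = sin(t)))
  tr <- read_pupil(p, rate = 50)
  expect_equal(tr$rate, 50)
  expect_equal(tr$values, sin(t))

  # one NaN sample between values 2.0 and 2.1 -> linear midpoint
  tt2 <- seq(1.5, 2.5, by = 0.1)
  d2 <- rep(2.0, 11); d2[6] <- NaN; d2[7:11] <- 2.1
  p2 <- tmp_csv(data.frame(time_s = tt2, diameter = d2))
  expect_message(tr2 <- read_pupil(p2, rate = 10), "interpolated")
  expect_equal(tr2$values[6], 2.05)

  # jitter below half a sample period snaps to the grid, values unchanged
  set.seed(7)
  jit <- t + stats::runif(length(t), -0.009, 0.009)
  jit[1] <- 0
  p3 <- tmp_csv(data.frame(time_s = jit, diameter = sin(t)))
  tr3 <- read_pupil(p3, rate = 50)
  expect_equal(tr3$values, sin(t))

  # non-monotone time errors
  p4 <- tmp_csv(data.frame(time_s = c(0, 0.04, 0.02), diameter = 1:3))
  expect_error(read_pupil(p4, rate = 50), "non-decreasing")

  # > 20% missing errors
  d <- rep(c(NA, 1, 1, 1), 10)
  p5 <- tmp_csv(data.frame(time_s = seq(0, length.out = 40, by = 0.02),
                           diameter = d))
  expect_error(read_pupil(p5, rate = 50), "missing")
})

test_that("spike, pupil and trial tables round-trip through csv", {
  st <- spike_train(c(0.123456789, 2.5, 7.75), unit_id = "u9")
  f <- tempfile(fileext = ".csv")
  write_spikes(st, f)
  expect_equal(read_spikes(f)$u9$times, st$times)

  tr <- z_trace(rnorm(100), rate = 20)
  f2 <- tempfile(fileext = ".csv")
  write_pupil(tr, f2)
  expect_equal(read_pupil(f2, rate = 20, units = "z")$values, tr$values)

  trials <- generate_behavior_session(0.8, 0.2, 30, seed = 3)
  f3 <- tempfile(fileext = ".csv")
  write_trials(trials, f3)
  back <- read_trials(f3)
  expect_equal(back$outcome, trials$outcome)
  expect_equal(back$stim_present, trials$stim_present)

  licks <- c(1.5, 7.25, 9)
  f4 <- tempfile(fileext = ".csv")
  write_licks(licks, f4)
  expect_equal(read_licks(f4), licks)

  stim <- data.frame(onset_s = c(10, 25, 40), pulse_ms = 10,
                     n_pulses = 4L, freq_hz = 10)
  f5 <- tempfile(fileext = ".csv")
  write_stim_trials(stim, f5)
  expect_equal(read_stim_trials(f5)$onset_s, stim$onset_s)
})

test_that("trial and stim tables enforce their invariants", {
  bad <- data.frame(trial_id = 1, stim_present = TRUE, response = TRUE,
                    outcome = "miss")
  expect_error(read_trials(tmp_csv(bad)), "inconsistent")
  stim <- data.frame(onset_s = c(10, 15), pulse_ms = 10, n_pulses = 4,
                     freq_hz = 10)
  expect_error(read_stim_trials(tmp_csv(stim)), "inter-trial")
})

test_that("spike_train and pupil_trace validate their invariants", {
  expect_error(spike_train(c(1, 1, 2)), "strictly increasing")
  expect_error(spike_train(c(1, 2), t_start = 1.5), "within")
  expect_error(pupil_trace(1, rate = 50), "2 samples")
  expect_error(pupil_trace(c(1, NA, 2), rate = 50), "finite")
  expect_error(pupil_trace(1:5, rate = 0), "positive")
})

test_that("config files apply defaults and reject unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(character(0), f)
  cfg <- load_config(f)
  expect_equal(cfg$peak_window, 6)
  expect_equal(cfg$smooth_window, 0.5)
  expect_equal(cfg$slope_step, 0.2)
  expect_equal(cfg$pre_event_window, c(-4, -2))
  expect_equal(cfg$event_bin, 0.3)
  expect_equal(cfg$n_boot, 100)
  expect_equal(cfg$n_perm, 1000)
  expect_equal(cfg$lick_halfwidth, 0.5)
  expect_equal(cfg$auc_threshold, 0.75)

  writeLines("n_boot: 500", f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$n_boot, 500)
  expect_equal(cfg2$n_perm, 1000)

  writeLines("peak_window: -1", f)
  expect_error(load_config(f), "peak_window")

  writeLines("peak_windoww: 6", f)
  expect_error(load_config(f), "unknown config key")
})
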