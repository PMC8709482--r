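test_that("epoch extraction uses half-open windows with nearest-sample rounding", {
  s <- semp_session(list(LSOL = seq_len(2000) * 1.0, force = numeric(2000)),
                    2000, data.frame(),
                    metadata = list(absent_channels = setdiff(EMG_CHANNELS, "LSOL")))
  ep <- extract_epoch(s, "LSOL", 0, c(0, 0.05))
  expect_length(ep, 100)
  expect_equal(ep, seq_len(100) * 1.0)
  expect_error(extract_epoch(s, "LSOL", 0, c(0.01, 0.01)), "zero-length")
  expect_error(extract_epoch(s, "LSOL", 0.99, c(0, 0.05)), "outside")
  expect_equal(extract_epoch(s, "force", 0.1, c(0, 0.02)), rep(0, 40))
})

test_that("peak_to_peak equals max minus min and is shift invariant", {
  expect_equal(peak_to_peak(rep(3.2, 10)), 0)
  expect_equal(peak_to_peak(c(-0.3, 0.0, 0.7)), 1.0)
  x <- rnorm(50)
  expect_equal(peak_to_peak(x + 17.3), peak_to_peak(x))
  expect_error(peak_to_peak(numeric(0)), "empty")
})

test_that("doublet measurement flags floor and R2 > R1 cases", {
  fs <- 2000
  n <- fs * 2
  p1 <- 0.5; p2 <- 0.55
  mk <- function(a1, a2) {
    x <- numeric(n)
    add <- function(x, t0, w) {
      i <- round(t0 * fs) + seq_along(w); x[i] <- x[i] + w; x
    }
    x <- add(x, p1, evoked_waveform(a1, 15, 25, fs))
    add(x, p2, evoked_waveform(a2, 15, 25, fs))
  }
  trial <- data.frame(trial_id = 1L, movement = "plantarflexion",
                      condition = "auditory", phase = "conditioned",
                      cti_ms = 200, cue_time_s = 0.3, pulse1_s = p1, pulse2_s = p2)
  sess <- function(a1, a2) semp_session(
    list(LSOL = mk(a1, a2), force = numeric(n)), fs, data.frame(),
    metadata = list(absent_channels = setdiff(EMG_CHANNELS, "LSOL")))

  d <- measure_doublet(sess(1.0, 0.3), trial, "LSOL")
  expect_equal(d$r1_pp, 1.0, tolerance = 1e-9)
  expect_equal(d$r2_pp, 0.3, tolerance = 1e-9)
  expect_false(d$r1_below_floor); expect_false(d$r2_exceeds_r1)

  expect_true(measure_doublet(sess(0.015, 0.01), trial, "LSOL")$r1_below_floor)
  d3 <- measure_doublet(sess(0.05, 0.06), trial, "LSOL")
  expect_true(d3$r2_exceeds_r1)

  # response window colliding with the next pulse is refused
  wide <- measure_settings(response_window_s = c(0.005, 0.06))
  expect_error(measure_doublet(sess(1, 0.3), trial, "LSOL", wide), "collides")
})

test_that("stimulus-artifact samples never contribute to the amplitudes", {
  p <- tiny_protocol()
  em0 <- quiet_model(artifact_amp_mv = 0)
  em_big <- quiet_model(artifact_amp_mv = 500)
  d0 <- measure_session(simulate_session(p, em0, seed = 4))
  # window opened into the artifact region; blanking must remove it
  st <- measure_settings(response_window_s = c(0.001, 0.045))
  d1 <- measure_session(simulate_session(p, em_big, seed = 4), settings = st)
  expect_equal(d1$r1_pp, d0$r1_pp, tolerance = 1e-9)
  expect_equal(d1$r2_pp, d0$r2_pp, tolerance = 1e-9)
})

test_that("outlier rule: strict 2.5 SD, single pass, SD = 0 keeps all", {
  expect_equal(exclude_outliers(rep(1, 10)), rep(TRUE, 10))
  # direct evaluation of the rule on a skewed set
  x <- c(rep(1, 9), 10)
  keep <- abs(x - mean(x)) <= 2.5 * sd(x)
  expect_equal(exclude_outliers(x), keep)
  # a value exactly at 2.5 SD is kept (rule is strict >):
  # c(rep(0,22), -5,-5,5,5) has mean 0 and sd exactly 2, so 2.5*sd = 5
  y <- c(rep(0, 22), -5, -5, 5, 5)
  expect_equal(sd(y), 2)
  expect_equal(exclude_outliers(y), rep(TRUE, 26))
  expect_warning(mask <- exclude_outliers(c(1, 100)), "fewer than 3")
  expect_equal(mask, c(TRUE, TRUE))
})

test_that("peak_to_peak matches exhaustive enumeration on random epochs", {
  withr::with_seed(99, {
    for (i in 1:200) {
      x <- rnorm(sample(3:60, 1))
      expect_identical(peak_to_peak(x), max(outer(x, x, "-")))
    }
  })
})

test_that("recruitment curve and threshold follow the floor-crossing rule", {
  df <- data.frame(intensity_mA = rep(c(30, 35, 40, 45), each = 3),
                   r1_pp = rep(c(0, 0, 0.05, 0.3), each = 3))
  curve <- build_recruitment_curve(df)
  expect_equal(curve$intensity_mA, c(30, 35, 40, 45))
  expect_equal(curve$mean_r1_pp, c(0, 0, 0.05, 0.3))
  expect_equal(estimate_threshold(curve), 40)

  flat <- build_recruitment_curve(data.frame(intensity_mA = c(30, 35),
                                             r1_pp = c(0, 0)))
  expect_true(is.na(estimate_threshold(flat)))
  # a dip below floor resets the sustained crossing
  dip <- build_recruitment_curve(data.frame(
    intensity_mA = c(30, 35, 40, 45), r1_pp = c(0.03, 0.01, 0.05, 0.3)))
  expect_equal(estimate_threshold(dip), 40)
  expect_error(build_recruitment_curve(data.frame(intensity_mA = 30, r1_pp = 1)),
               "2 intensity")

  # sigmoidal generator: estimate within one 5 mA step of the true crossing
  rec <- simulate_recruitment(seq(30, 70, 5), n_pulses = 3, midpoint_ma = 50,
                              slope_ma = 4, cv = 0.05, seed = 8)
  est <- estimate_threshold(build_recruitment_curve(rec))
  grid <- seq(30, 70, 5)
  true_cross <- min(grid[recruitment_mean(grid, 50, 4) >= 0.02])
  expect_lte(abs(est - true_cross), 5)
})

test_that("force onset detection recovers reaction times", {
  fs <- 2000
  # noiseless step 200 ms after the cue -> RT within one sample
  force <- numeric(3 * fs)
  force[(round(1.2 * fs) + 1):length(force)] <- 10
  rt <- detect_force_onset(force, 1, fs)
  expect_lte(abs(rt - 200), 1000 / fs)
  # flat trace -> no onset
  expect_true(is.na(detect_force_onset(numeric(3 * fs), 1, fs)))
  expect_error(detect_force_onset(force, 0.1, fs), "baseline")

  blk <- simulate_rt_block(50, 219.1, 41.8, seed = 12)
  det <- vapply(blk$traces, detect_force_onset, numeric(1),
                cue_time_s = blk$cue_time_s,
                sampling_rate_hz = blk$sampling_rate_hz)
  expect_true(all(is.finite(det)))
  expect_equal(mean(det), mean(blk$true_rt_ms), tolerance = 0.02)
})
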