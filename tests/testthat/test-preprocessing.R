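# Filtering, event detection, segmentation, CoP repair, averaging.

make_channel_trial <- function(x, fs = 100) {
  n <- length(x)
  chans <- matrix(0, n, length(gait_channels()),
                  dimnames = list(NULL, gait_channels()))
  chans[, "hip_flexion_l"] <- x
  chans[, "grf_y_l"] <- 100   # keep vertical force positive and constant
  chans[, "grf_y_r"] <- 100
  gait_trial((seq_len(n) - 1) / fs, chans, fs)
}

test_that("low-pass filter has unit DC gain and the designed response", {
  n <- 2000; fs <- 100
  # DC channel passes unchanged
  tr <- make_channel_trial(rep(5, n))
  out <- lowpass_filter(tr, 6)
  expect_equal(out$channels[, "hip_flexion_l"], rep(5, n), tolerance = 1e-9)
  # oracle: magnitude response of the designed forward-backward filter,
  # evaluated directly from the transfer-function polynomials
  bf <- signal::butter(4, 6 / (fs / 2), "low")
  hmag <- function(f_hz) {
    z <- exp(-1i * 2 * pi * f_hz / fs)
    num <- sum(bf$b * z^(seq_along(bf$b) - 1))
    den <- sum(bf$a * z^(seq_along(bf$a) - 1))
    Mod(num / den)^2                               # filtfilt = |H|^2
  }
  t <- (seq_len(n) - 1) / fs
  mid <- 500:1500
  for (f_hz in c(30, 1)) {
    tr <- make_channel_trial(sin(2 * pi * f_hz * t))
    out <- lowpass_filter(tr, 6)
    amp <- max(abs(out$channels[mid, "hip_flexion_l"]))
    expect_equal(amp, hmag(f_hz), tolerance = 0.02)
  }
  expect_lt(hmag(30), 0.05)        # strong stopband attenuation
  expect_gt(hmag(1), 0.98)         # passband preserved within 2%
})

test_that("filter rejects cutoffs at or beyond Nyquist and is linear", {
  tr <- make_channel_trial(rnorm(300))
  expect_error(lowpass_filter(tr, 50), "Nyquist")
  t2 <- make_channel_trial(rnorm(300))
  lin <- make_channel_trial(2 * tr$channels[, "hip_flexion_l"] +
                              3 * t2$channels[, "hip_flexion_l"])
  got <- lowpass_filter(lin, 6)$channels[, "hip_flexion_l"]
  want <- 2 * lowpass_filter(tr, 6)$channels[, "hip_flexion_l"] +
    3 * lowpass_filter(t2, 6)$channels[, "hip_flexion_l"]
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("heel strikes are detected, debounced, and boundary-safe", {
  fs <- 100
  # 10 clean stance phases of 0.6 s separated by 0.5 s swings
  f <- rep(c(rep(0, 50), rep(400, 60)), 10)
  hs <- detect_heel_strikes(f, 30, fs)
  expect_length(hs, 10)
  expect_true(all(f[hs] >= 30 & f[hs - 1] < 30))
  # dither around the threshold at one contact: one detection only
  dither <- c(rep(0, 50), 30 + rep(c(1, -1), 10), rep(400, 40), rep(0, 50))
  expect_length(detect_heel_strikes(dither, 30, fs), 1)
  # all-swing trace: empty with warning
  expect_warning(out <- detect_heel_strikes(rep(20, 500), 30, fs),
                 "never crosses")
  expect_length(out, 0)
})

test_that("stride segmentation picks seeded valid windows and keeps durations", {
  tr <- noisy_trial()
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  hs10 <- hs[1:10]
  picks <- vapply(1:20, function(s) {
    ss <- segment_strides(tr, hs10, n_strides = 5, selection_seed = s)
    ss$source_heel_strike_indices[1]
  }, 0L)
  expect_true(all(picks %in% hs10[1:5]))          # one of the 5 valid windows
  expect_gt(length(unique(picks)), 1)
  ss <- segment_strides(tr, hs10, n_strides = 5, selection_seed = 3)
  ss2 <- segment_strides(tr, hs10, n_strides = 5, selection_seed = 3)
  expect_identical(ss$strides, ss2$strides)        # seed-reproducible
  # durations times sampling rate reproduce the heel-strike index gaps
  expect_equal(ss$stride_durations * tr$sampling_rate,
               diff(ss$source_heel_strike_indices), tolerance = 1e-12)
  expect_error(segment_strides(tr, hs10[1:4], n_strides = 5), "at least 6")
})

test_that("time normalization round trip preserves strides", {
  tr <- lowpass_filter(noisy_trial())
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  ss <- segment_strides(tr, hs, n_strides = 3, selection_seed = 2)
  for (i in 1:3) {
    back <- stride_as_trial(ss, i)
    idx <- ss$source_heel_strike_indices[i]:ss$source_heel_strike_indices[i + 1]
    src <- tr$channels[idx, ]
    # compare at common length via the original sample count
    expect_equal(nrow(back$channels), length(idx))
    for (ch in c("hip_flexion_l", "grf_y_l", "knee_flexion_r")) {
      rng <- max(src[, ch]) - min(src[, ch])
      rmse <- sqrt(mean((back$channels[, ch] - src[, ch])^2))
      expect_lt(rmse, 0.005 * rng)
    }
  }
})

test_that("CoP repair leaves stance untouched and bridges swing smoothly", {
  tr <- lowpass_filter(noisy_trial(n_strides = 8, seed = 4))
  rep_tr <- repair_cop(tr, 30)
  for (side in c("l", "r")) {
    stance <- tr$channels[, paste0("grf_y_", side)] >= 30
    expect_identical(rep_tr$channels[stance, paste0("cop_x_", side)],
                     tr$channels[stance, paste0("cop_x_", side)])
    # repaired CoP is continuous (no jumps beyond a plausible slew)
    cop <- rep_tr$channels[, paste0("cop_x_", side)]
    expect_lt(max(abs(diff(cop))), 0.12)
  }
})

test_that("CoP swing interpolant hits the bracketing stance values", {
  n <- 400
  chans <- matrix(0, n, length(gait_channels()),
                  dimnames = list(NULL, gait_channels()))
  fy <- c(rep(400, 100), rep(0, 150), rep(400, 150))
  chans[, "grf_y_l"] <- fy
  chans[, "grf_y_r"] <- 400
  chans[, "cop_x_l"] <- c(rep(0.1, 100), rep(99, 150), rep(0.7, 150))
  tr <- gait_trial((seq_len(n) - 1) / 100, chans, 100)
  out <- repair_cop(tr, 30)
  cop <- out$channels[, "cop_x_l"]
  expect_equal(cop[100], 0.1)
  expect_equal(cop[251], 0.7)
  expect_true(all(cop[101:250] >= 0.1 - 1e-9 & cop[101:250] <= 0.7 + 1e-9))
})

test_that("swing CoP details do not affect the torque effort", {
  tr <- zero_noise_trial()               # swing GRF identically zero
  model <- default_model()
  linear <- tr; cubic <- repair_cop(tr, 30)
  # linear variant: straight-line bridge across each swing gap
  for (side in c("l", "r")) {
    fy <- linear$channels[, paste0("grf_y_", side)]
    cop <- linear$channels[, paste0("cop_x_", side)]
    stance <- fy >= 30
    cop[!stance] <- approx(which(stance), cop[stance], xout = which(!stance),
                           rule = 2)$y
    linear$channels[, paste0("cop_x_", side)] <- cop
  }
  e1 <- torque_effort(inverse_dynamics(linear, model))
  e2 <- torque_effort(inverse_dynamics(cubic, model))
  expect_lt(abs(e1 - e2) / e1, 1e-6)
})

test_that("averaging is an arithmetic mean with the mean period", {
  tr <- noisy_trial()
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  ss <- segment_strides(tr, hs, n_strides = 5, selection_seed = 5)
  # synthetic constant strides: mean of {1, 3} is 2
  fake <- ss
  fake$strides <- list(ss$strides[[1]] * 0 + 1, ss$strides[[1]] * 0 + 3)
  fake$stride_durations <- c(1.0, 1.2)
  avg <- average_gait_pattern(fake)
  expect_true(all(avg$channels == 2))
  expect_equal(avg$period, 1.1)
  # mean durations example
  fake$strides <- rep(fake$strides[1], 5)
  fake$stride_durations <- c(1.0, 1.1, 1.2, 1.0, 1.2)
  expect_equal(average_gait_pattern(fake)$period, 1.1)
  # N identical strides: average equals each stride
  same <- ss
  same$strides <- rep(ss$strides[2], 4)
  same$stride_durations <- rep(ss$stride_durations[2], 4)
  avg2 <- average_gait_pattern(same)
  expect_equal(avg2$channels, ss$strides[[2]], tolerance = 1e-12)
  # point-wise mean identity on the real stride set
  avg3 <- average_gait_pattern(ss)
  expect_equal(avg3$channels, Reduce(`+`, ss$strides) / 5, tolerance = 1e-12)
})

test_that("averaging is idempotent", {
  tr <- noisy_trial()
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  ss <- segment_strides(tr, hs, n_strides = 5, selection_seed = 6)
  avg <- average_gait_pattern(ss)
  twice <- ss
  twice$strides <- list(avg$channels, avg$channels)
  twice$stride_durations <- rep(avg$period, 2)
  expect_equal(average_gait_pattern(twice)$channels, avg$channels)
  expect_equal(average_gait_pattern(twice)$period, avg$period)
})
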