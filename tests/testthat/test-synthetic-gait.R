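# Synthetic template and trial generator.

test_that("template waveforms have the contracted gait shapes", {
  tpl <- default_template(0.8)
  phi <- seq(0, 1, length.out = 2001)[-1]
  v <- tpl$evaluate(phi)
  # vertical GRF: exactly two local maxima per cycle per foot
  for (ch in c("grf_y_l", "grf_y_r")) {
    y <- v[, ch]
    yl <- c(y[length(y)], y[-length(y)]); yr <- c(y[-1], y[1])
    expect_equal(sum(y > yl & y > yr & y > 0), 2)
  }
  # left swing interval identically below the 30 N threshold
  swing <- phi >= tpl$duty & phi < 1
  expect_true(all(v[swing, "grf_y_l"] < 30))
  # braking then propulsion in fore-aft GRF during left stance
  st <- phi < tpl$duty
  expect_lt(min(v[st, "grf_x_l"]), 0)
  expect_gt(max(v[st, "grf_x_l"]), 0)
  # anterior CoP progression relative to the foot through stance
  s <- phi[st] / tpl$duty
  rel_cop <- v[st, "cop_x_l"] + 0.8 * tpl$period * phi[st]
  expect_true(all(diff(rel_cop[order(s)]) > -1e-9))
})

test_that("template period shortens with speed and rejects bad speeds", {
  expect_lt(default_template(1.2)$period, default_template(0.8)$period)
  expect_error(default_template(0.3), "speed")
  expect_error(default_template(2.5), "speed")
})

test_that("cycle-mean total vertical force equals body weight", {
  tpl <- default_template(1.0, mass = 80)
  phi <- seq(0, 1, length.out = 4096 + 1)[-1]
  v <- tpl$evaluate(phi)
  expect_equal(mean(v[, "grf_y_l"] + v[, "grf_y_r"]), 80 * 9.81,
               tolerance = 1e-6)
})

test_that("zero-noise generation is exactly stride-periodic", {
  tr <- zero_noise_trial()
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  expect_true(length(hs) >= 10)
  expect_true(all(diff(hs) == diff(hs)[1]))
  ss <- segment_strides(tr, hs[2:9], n_strides = 5, selection_seed = 1)
  for (i in 2:5)
    expect_identical(ss$strides[[i]], ss$strides[[1]])
})

test_that("same seed reproduces the trial, different seeds differ", {
  tpl <- default_template(1.0)
  a <- generate_trial(tpl, n_strides = 6, seed = 5,
                      variability = default_variability())
  b <- generate_trial(tpl, n_strides = 6, seed = 5,
                      variability = default_variability())
  d <- generate_trial(tpl, n_strides = 6, seed = 6,
                      variability = default_variability())
  expect_identical(a$channels, b$channels)
  expect_false(identical(a$channels, d$channels))
})

test_that("stride-period variability matches the configured sd", {
  tpl <- default_template(1.0)
  cfg <- variability_config(stride_period_sd = 0.02)
  tr <- generate_trial(tpl, n_strides = 202, seed = 11, variability = cfg)
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  durations <- diff(hs) / tr$sampling_rate
  n <- length(durations)
  expect_gte(n, 195)
  # sample sd of sd estimate: sigma / sqrt(2 (n - 1)); allow 3 of them plus
  # the 10 ms sampling quantization variance
  sigma <- sqrt(0.02^2 + (0.01^2) / 12)
  se <- sigma / sqrt(2 * (n - 1))
  expect_lt(abs(sd(durations) - sigma), 3 * se)
})

test_that("amplitude noise increases across-stride kinematic dispersion", {
  tpl <- default_template(1.0)
  peak_sd <- function(amp_sd) {
    tr <- generate_trial(tpl, n_strides = 110, seed = 3,
                         variability = variability_config(amplitude_sd = amp_sd))
    hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
    ss <- segment_strides(tr, hs, n_strides = length(hs) - 1,
                          selection_seed = 1)
    sd(vapply(ss$strides, function(m) max(m[, "ankle_flexion_l"]), 0))
  }
  s0 <- peak_sd(0)
  s1 <- peak_sd(0.03)
  s2 <- peak_sd(0.08)
  expect_lt(s0, s1)
  expect_lt(s1, s2)
})

test_that("generator rejects invalid configurations and templates", {
  expect_error(variability_config(amplitude_sd = -0.1), "amplitude_sd")
  tpl <- default_template(1.0)
  expect_error(generate_trial(tpl, n_strides = 1), "n_strides")
  broken <- list(period = 1.2,
                 evaluate = function(p) {
                   m <- default_template(1.0)$evaluate(p)
                   m[, "hip_flexion_l"] <- m[, "hip_flexion_l"] + (p %% 1)
                   m
                 })
  expect_error(generate_trial(broken, n_strides = 4), "not periodic")
})

test_that("trial invariants hold under noisy generation", {
  tr <- noisy_trial()
  expect_true(all(tr$channels[, "grf_y_l"] >= 0))
  expect_true(all(tr$channels[, "grf_y_r"] >= 0))
  expect_equal(diff(tr$time), rep(0.01, length(tr$time) - 1), tolerance = 1e-9)
  # every stride keeps a swing interval under 30 N
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  for (i in seq_len(min(10, length(hs) - 1))) {
    seg <- tr$channels[hs[i]:hs[i + 1], "grf_y_l"]
    expect_true(any(seg < 30))
  }
})
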