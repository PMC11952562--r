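# Muscle energetics model and the stride-level metabolic composition.

ref_params <- function(ft = 0.5, mm = 0.1, vmax = 12, lopt = 0.1)
  muscle_params("ref", "hip_l", 0.05, 2000, lopt,
                max_contraction_velocity = vmax, fast_twitch_ratio = ft,
                muscle_mass = mm)

state_at <- function(a, l, v, force, n = 3, dur = 0.02) {
  list(time = seq(0, dur, length.out = n),
       activation = rep(a, n), lnorm = rep(l, n),
       vnorm = rep(v, n), force = rep(force, n))
}

test_that("quiescent muscle has zero rates and isometric muscle no velocity terms", {
  p <- ref_params()
  q <- umberger_rate(state_at(0, 1, 0, 0), p)
  expect_equal(unname(q$total_rate), rep(0, 3))
  expect_equal(unname(q$work_rate), rep(0, 3))
  iso <- umberger_rate(state_at(0.6, 1, 0, 1000), p)
  expect_equal(unname(iso$work_rate), rep(0, 3))
  expect_equal(unname(iso$shortening_lengthening_heat_rate), rep(0, 3))
  expect_equal(iso$total_rate,
               iso$activation_heat_rate + iso$maintenance_heat_rate)
})

test_that("rates match an independent transcription at reference states", {
  # reference states spanning shortening, lengthening, short and long
  # fibers, slow and fast mixtures, including the clamp-active regime
  cases <- list(
    list(a = 0.5, l = 1.0, v = 6.0, f = 500, ft = 0.5, mm = 0.1),
    list(a = 1.0, l = 1.0, v = 0.0, f = 2000, ft = 0.5, mm = 0.1),
    list(a = 0.2, l = 0.8, v = 1.5, f = 120, ft = 0.2, mm = 0.3),
    list(a = 0.8, l = 1.2, v = -2.0, f = 900, ft = 0.5, mm = 0.2),
    list(a = 0.3, l = 1.1, v = -6.0, f = 2500, ft = 0.8, mm = 0.15),
    list(a = 0.05, l = 1.0, v = 0.5, f = 30, ft = 0.0, mm = 0.5),
    list(a = 0.95, l = 0.7, v = 9.0, f = 150, ft = 1.0, mm = 0.05),
    list(a = 0.6, l = 1.3, v = -10.0, f = 4000, ft = 0.3, mm = 0.08),
    list(a = 0.4, l = 0.95, v = 3.3, f = 700, ft = 0.6, mm = 0.25),
    list(a = 0.7, l = 1.05, v = -0.4, f = 1200, ft = 0.45, mm = 0.4))
  for (cs in cases) {
    p <- ref_params(ft = cs$ft, mm = cs$mm)
    got <- umberger_rate(state_at(cs$a, cs$l, cs$v, cs$f), p)
    want <- oracle_muscle_rate(cs$a, cs$l, cs$v, cs$f, cs$ft,
                               p$max_contraction_velocity,
                               p$optimal_fiber_length, cs$mm)
    expect_equal(got$total_rate[1], want[["total"]],
                 tolerance = 1e-9)
    expect_equal(got$work_rate[1], want[["work"]], tolerance = 1e-9)
    expect_equal(got$activation_heat_rate[1], want[["activation"]],
                 tolerance = 1e-9)
    expect_equal(got$maintenance_heat_rate[1], want[["maintenance"]],
                 tolerance = 1e-9)
    expect_equal(got$shortening_lengthening_heat_rate[1],
                 want[["shortening_lengthening"]], tolerance = 1e-9)
  }
})

test_that("the four terms sum to the total and the total stays non-negative", {
  set.seed(9)
  p <- ref_params()
  for (k in 1:50) {
    a <- runif(1); l <- runif(1, 0.6, 1.4); v <- runif(1, -12, 12)
    f <- hill_force(l, v, a, p)
    br <- umberger_rate(state_at(a, l, v, f), p)
    expect_equal(br$total_rate,
                 br$work_rate + br$activation_heat_rate +
                   br$maintenance_heat_rate +
                   br$shortening_lengthening_heat_rate,
                 tolerance = 1e-12)
    expect_true(all(br$total_rate >= 0))
    expect_equal(sum(br$integrated[1:4]), br$integrated_cost,
                 tolerance = 1e-12)
  }
  # the unclamped variant can go negative during eccentric absorption
  ec <- umberger_rate(state_at(0.9, 1, -11, 5000), p, clamp_total = FALSE)
  expect_lt(min(ec$total_rate), 0)
})

test_that("total rate is convex in required force in the loaded regime", {
  set.seed(31)
  p <- ref_params()
  v <- 0.5 * p$max_contraction_velocity
  l <- 1.0
  cap <- hill_force(l, v, 1, p)
  rate_at <- function(force) {
    a <- force / cap
    umberger_rate(state_at(a, l, v, force), p)$total_rate[1]
  }
  for (k in 1:100) {
    f1 <- runif(1, 0.3, 0.95) * cap
    f2 <- runif(1, 0.3, 0.95) * cap
    mid <- rate_at((f1 + f2) / 2)
    avg <- (rate_at(f1) + rate_at(f2)) / 2
    expect_lte(mid, avg + 1e-9 * abs(avg))
  }
})

test_that("stride metabolic cost composes the chain deterministically", {
  model <- default_model()
  tr <- lowpass_filter(zero_noise_trial())
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  ss <- segment_strides(tr, hs[2:9], n_strides = 2, selection_seed = 1)
  s1 <- stride_as_trial(ss, 1)
  c1 <- stride_metabolic_cost(s1, model)
  c2 <- stride_metabolic_cost(stride_as_trial(ss, 2), model)
  expect_equal(c1$average_power, c2$average_power, tolerance = 1e-9)
  expect_gt(c1$average_power_per_kg, 0.5)   # walking costs a few W/kg
  expect_lt(c1$average_power_per_kg, 20)
})

test_that("zero-motion zero-load stride costs nothing without basal rate", {
  model <- default_model()
  tr <- standing_trial(model, force = 0, lever = 0, gravity_on = FALSE)
  model$gravity <- 0
  cost <- stride_metabolic_cost(tr, model)
  expect_equal(cost$integrated_cost, 0, tolerance = 1e-9)
})

test_that("inflating torques at fixed kinematics raises the cost", {
  model <- default_model()
  tr <- lowpass_filter(zero_noise_trial())
  hs <- detect_heel_strikes(tr$channels[, "grf_y_l"])
  ss <- segment_strides(tr, hs[2:9], n_strides = 1, selection_seed = 1)
  s1 <- stride_as_trial(ss, 1)
  tq <- inverse_dynamics(s1, model)
  ms <- default_muscle_set()
  cost_for <- function(scale) {
    tq2 <- tq; tq2$torques <- tq$torques * scale
    # scaled-up torques may brush the strength ceiling; that saturation
    # warning is the solver's documented contract, not a failure here
    st <- suppressWarnings(solve_muscle_states(tq2, s1, ms))
    sum(vapply(ms, function(p) umberger_rate(st, p)$integrated_cost, 0))
  }
  expect_gt(cost_for(1.5), cost_for(1))
})
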