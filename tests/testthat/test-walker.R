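# Inverted-pendulum walker: stance energetics, transitions, control, noise.

nominal_gait <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- find_nominal_gait(0.4)
    cache
  }
})

test_that("stance phase conserves energy and matches the closed form", {
  st <- stance_dynamics(0.45, 0.5)
  expect_false(st$fell)
  expect_lt(st$energy_drift, 1e-12)
  alpha <- asin(0.25)
  # mid-stance speed from the conserved energy: v_mid^2 = v0^2 - 2(1-cos a)
  expect_equal(st$mid_stance_speed, sqrt(0.45^2 - 2 * (1 - cos(alpha))),
               tolerance = 1e-12)
  expect_equal(st$end_speed, 0.45, tolerance = 1e-12)
  # insufficient energy to pass vertical is a fall
  grazing <- sqrt(2 * (1 - cos(asin(0.25))))
  expect_true(stance_dynamics(grazing * 0.99, 0.5)$fell)
  # balanced upright rest is degenerate, not a fall
  d <- stance_dynamics(0, 0)
  expect_true(d$degenerate)
  expect_false(d$fell)
})

test_that("stance duration matches adaptive quadrature", {
  for (v0 in c(0.35, 0.5, 0.8)) {
    alpha <- asin(0.25)
    want <- integrate(function(th) 1 / sqrt(v0^2 + 2 * (cos(th) - cos(alpha))),
                      -alpha, alpha, rel.tol = 1e-12)$value
    expect_equal(stance_dynamics(v0, 0.5)$duration, want, tolerance = 1e-8)
  }
})

test_that("step transition composes push-off and heel-strike correctly", {
  # pure heel-strike limit: post = pre * cos(Phi)
  tr0 <- step_transition(0.5, 0, 0.6)
  expect_equal(tr0$post_speed, 0.5 * cos(0.6))
  expect_equal(tr0$pushoff_work, 0)
  # zero inter-leg angle: heel strike removes nothing from the forward speed
  tr1 <- step_transition(0.5, 0.2, 0)
  expect_equal(tr1$post_speed, 0.5)
  expect_equal(tr1$pushoff_work, 0.02)
  expect_error(step_transition(0.5, -0.1, 0.6), "non-negative")
})

test_that("the nominal gait is an exact periodic fixed point", {
  nom <- nominal_gait()
  # periodicity residual of the push-off root
  tr <- step_transition(nom$entry_speed, nom$pushoff, 2 * nom$alpha)
  expect_lt(abs(tr$post_speed - nom$entry_speed), 1e-8)
  # ten noise-free strides reproduce the state each stride
  v0 <- nom$entry_speed
  for (i in 1:10) {
    st <- stance_dynamics(v0, nom$step_length)
    expect_lt(st$energy_drift, 1e-12)
    v0 <- step_transition(st$end_speed, nom$pushoff, 2 * nom$alpha)$post_speed
  }
  expect_lt(abs(v0 - nom$entry_speed), 1e-6)
  # average speed of the nominal gait equals the target
  expect_equal(nom$step_length / nom$step_time, 0.4, tolerance = 1e-9)
})

test_that("the nominal gait is a local cost minimum in step length", {
  nom <- nominal_gait()
  cost_at <- function(alpha) {
    # re-solve the periodic push-off at this step length and target speed
    h <- function(v0) 2 * sin(alpha) / stridecost:::stance_time(alpha, v0) - 0.4
    v0 <- uniroot(h, c(sqrt(2 * (1 - cos(alpha))) * (1 + 1e-9), 10),
                  tol = 1e-13)$root
    t <- stridecost:::stance_time(alpha, v0)
    ((v0 * tan(alpha))^2 / 2 + nom$swing_cost_coefficient / t^4) /
      (2 * sin(alpha))
  }
  c0 <- nom$cost_per_distance
  expect_gt(cost_at(nom$alpha * 1.05), c0)
  expect_gt(cost_at(nom$alpha * 0.95), c0)
  # positive curvature at the optimum (second-order optimality)
  h <- 0.02 * nom$alpha
  curv <- (cost_at(nom$alpha + h) - 2 * c0 + cost_at(nom$alpha - h)) / h^2
  expect_gt(curv, 0)
})

test_that("removing the swing cost drives the optimum to short steps", {
  with_swing <- find_nominal_gait(0.4, 0.001)
  no_swing <- suppressWarnings(find_nominal_gait(0.4, 0))
  expect_lt(no_swing$step_length, 0.25 * with_swing$step_length)
})

test_that("the controller is linear with the contracted signs", {
  nom <- nominal_gait()
  cfg <- walker_config()
  at <- function(dv) feedback_controller(nom$mid_stance_speed + dv, cfg, nom)
  base <- at(0)
  expect_equal(base$step_length, nom$step_length)
  expect_equal(base$pushoff, nom$pushoff)
  expect_gt(at(0.02)$step_length, nom$step_length)   # faster -> longer step
  expect_lt(at(0.02)$pushoff, nom$pushoff)           # faster -> less push-off
  for (dv in c(-0.02, -0.01, 0.01, 0.02)) {
    expect_equal(at(dv)$step_length - nom$step_length,
                 cfg$step_length_gain * dv, tolerance = 1e-12)
    expect_equal(at(dv)$pushoff - nom$pushoff,
                 cfg$pushoff_gain * dv, tolerance = 1e-12)
  }
})

test_that("zero noise reproduces the nominal cost with zero dispersion", {
  run <- run_walker(walker_config(n_strides = 100, seed = 1),
                    nominal_gait())
  expect_false(run$fell)
  expect_equal(run$mean_cost, nominal_gait()$step_cost, tolerance = 1e-6)
  expect_equal(run$sd_cost, 0, tolerance = 1e-12)
  expect_lt(max(run$records$energy_drift), 1e-12)
})

test_that("runs are seed-reproducible", {
  cfg <- walker_config(n_strides = 100, seed = 42,
                       sensory_noise_sd = 0.01,
                       motor_noise_sd_pushoff = 0.01,
                       motor_noise_sd_step = 0.01)
  a <- run_walker(cfg, nominal_gait())
  b <- run_walker(cfg, nominal_gait())
  expect_identical(a$records, b$records)
  cfg$seed <- 43
  expect_false(identical(run_walker(cfg, nominal_gait())$records, a$records))
})

test_that("noise raises both the mean cost and its dispersion", {
  sw <- sweep_noise(walker_config(n_strides = 200), "motor",
                    levels = c(0, 0.01, 0.02), replicates = 12, seed = 3)
  agg <- aggregate(cbind(mean_cost, sd_cost) ~ level, sw, mean)
  expect_true(all(diff(agg$mean_cost) > 0))
  expect_true(all(diff(agg$sd_cost) > 0))
  sw2 <- sweep_noise(walker_config(n_strides = 200), "sensory",
                     levels = c(0, 0.01, 0.02), replicates = 12, seed = 4)
  agg2 <- aggregate(cbind(mean_cost, sd_cost) ~ level, sw2, mean)
  expect_true(all(diff(agg2$mean_cost) > 0))
  expect_true(all(diff(agg2$sd_cost) > 0))
})
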