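# Shared fixtures and independent oracles, built in code at test time.

# Small cached trials so multiple test files reuse the same generation work.
fixture_env <- new.env(parent = emptyenv())

zero_noise_trial <- function(speed = 0.8, n_strides = 12) {
  key <- sprintf("z_%g_%d", speed, n_strides)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_trial(default_template(speed),
                                         n_strides = n_strides, seed = 1)
  fixture_env[[key]]
}

noisy_trial <- function(speed = 0.8, n_strides = 60, seed = 7) {
  key <- sprintf("n_%g_%d_%d", speed, n_strides, seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_trial(default_template(speed),
                                         n_strides = n_strides, seed = seed,
                                         variability = default_variability())
  fixture_env[[key]]
}

default_model <- function() segment_model(72.66, 1.759)

# A constant standing trial: all joint angles zero (legs vertical), constant
# vertical force under each foot at a given CoP lever arm from the ankle.
standing_trial <- function(model, force = 350, lever = 0.08, n = 50,
                           gravity_on = TRUE) {
  h <- model$participant_height
  pel_y <- model$thigh$length + model$shank$length + 0.05
  chans <- matrix(0, n, length(gait_channels()),
                  dimnames = list(NULL, gait_channels()))
  chans[, "pelvis_y"] <- pel_y
  chans[, "grf_y_l"] <- force
  chans[, "grf_y_r"] <- force
  chans[, "cop_x_l"] <- lever   # ankle sits at x = 0 when all angles are 0
  chans[, "cop_x_r"] <- lever
  gait_trial((seq_len(n) - 1) / 100, chans, 100,
             participant_mass = model$participant_mass,
             participant_height = h)
}

# Independent transcription of the muscle energetics equations, written
# directly from the published constants for scalar reference states
# (activation a, normalized length l, normalized velocity v shortening
# positive, explicit fiber force F in newtons). Deliberately scalar and
# formula-by-formula, separate from the vectorized package implementation.
oracle_muscle_rate <- function(a, l, v, force, ft, vmax_fast, lopt, mmass,
                               S = 1.5, clamp = TRUE) {
  vmax_slow <- vmax_fast / 2.5
  h_am_full <- 128 * ft + 25                       # W/kg at a = 1
  f_iso <- exp(-((l - 1) / 0.45)^2)
  desc <- if (l > 1) f_iso else 1
  h_act <- 0.4 * h_am_full * a^0.6 * S
  h_mnt <- 0.6 * h_am_full * a^0.6 * S * desc
  h_sl <- if (v >= 0)
    ((100 / vmax_slow) * (1 - ft) + (153 / vmax_fast) * ft) * v * a^2 * S * desc
  else
    4 * (100 / vmax_slow) * (-v) * a * S * desc
  w <- force * v * lopt / mmass                    # W/kg, shortening positive
  total <- w + h_act + h_mnt + h_sl
  if (clamp && total < 0) { h_sl <- h_sl - total; total <- 0 }
  mmass * c(work = w, activation = h_act, maintenance = h_mnt,
            shortening_lengthening = h_sl, total = total)
}

# Exhaustive grid search oracle for the two-muscle torque-sharing problem:
# minimize a1^2 + a2^2 subject to c1 a1 + c2 a2 = tau, 0 <= a <= 1, scanning
# a1 at the given resolution and solving the constraint for a2.
grid_search_two_muscle <- function(c1, c2, tau, resolution = 1e-3) {
  a1 <- seq(0, 1, by = resolution)
  a2 <- (tau - c1 * a1) / c2
  ok <- a2 >= 0 & a2 <= 1
  if (!any(ok)) return(NULL)
  obj <- a1^2 + a2^2
  obj[!ok] <- Inf
  i <- which.min(obj)
  c(a1[i], a2[i])
}
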