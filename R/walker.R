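# Feedback-controlled point-mass inverted-pendulum (compass-gait) walker.
# Nondimensional units throughout: mass, leg length and gravity are 1, so
# speeds are in sqrt(g L), impulses in m sqrt(g L), energies in m g L and
# times in sqrt(L / g).
#
# Stance is an inverted pendulum theta'' = sin(theta) from -alpha to +alpha
# (alpha = asin(step_length / 2)). Because stance is conservative, the end
# state follows exactly from the energy integral E = v^2/2 - cos(theta)
# (with v = theta' the speed of the point mass), and the stance duration is
# the quadrature t = int d(theta) / v(theta), evaluated with fixed
# Gauss-Legendre nodes. The step-to-step transition applies an impulsive
# push-off P along the trailing leg followed by an inelastic heel-strike
# that redirects the velocity perpendicular to the new stance leg:
# v+ = v- cos(Phi) + P sin(Phi) with Phi the inter-leg angle. Push-off work
# is P^2/2. The stride cost adds an empirical swing cost c1 * f^4 per step
# (f = step frequency).

.walker_env <- new.env(parent = emptyenv())

gl_nodes <- function(n = 48) {
  key <- paste0("gl", n)
  if (is.null(.walker_env[[key]]))
    .walker_env[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .walker_env[[key]]
}

# Stance duration from -alpha to +alpha at entry speed v0 (speed at the
# extreme angles), by Gauss-Legendre quadrature of 1/v(theta).
stance_time <- function(alpha, v0) {
  gl <- gl_nodes()
  th <- alpha * gl$x
  v <- sqrt(pmax(v0^2 + 2 * (cos(th) - cos(alpha)), 0))
  alpha * sum(gl$w / v)
}

#' Walker configuration
#'
#' Parameters of the feedback-controlled inverted-pendulum walker, all
#' nondimensional (leg length, gravity and mass are the units).
#'
#' @param target_speed average walking speed in sqrt(g L) units.
#' @param leg_length,gravity nondimensionalizing constants (kept at 1).
#' @param swing_cost_coefficient coefficient `c1` of the empirical swing
#'   cost `c1 * (step frequency)^4` per step, chosen so the energy-optimal
#'   step length at speed 0.4 is interior to the feasible window (about
#'   0.49 L, with a comfortable mid-stance speed margin).
#' @param step_length_gain,pushoff_gain feedback gains mapping the sensed
#'   mid-stance-speed deviation to the commanded step length and push-off
#'   (defaults give a strongly contracting stride map).
#' @param sensory_noise_sd Gaussian noise sd on the sensed mid-stance speed.
#' @param motor_noise_sd_pushoff,motor_noise_sd_step Gaussian noise sds on
#'   the executed push-off impulse and foot placement.
#' @param n_strides number of recorded strides per run.
#' @param warmup strides discarded before summarizing.
#' @param seed integer seed.
#' @return An object of class `walker_config`.
#' @export
walker_config <- function(target_speed = 0.4, leg_length = 1, gravity = 1,
                          swing_cost_coefficient = 0.001,
                          step_length_gain = 1.0, pushoff_gain = -0.6,
                          sensory_noise_sd = 0, motor_noise_sd_pushoff = 0,
                          motor_noise_sd_step = 0, n_strides = 500,
                          warmup = 10, seed = NULL) {
  check_scalar(target_speed, "target_speed", lower = 0.05, upper = 1.5)
  check_scalar(leg_length, "leg_length", lower = 1e-9)
  check_scalar(gravity, "gravity", lower = 1e-9)
  for (k in c("sensory_noise_sd", "motor_noise_sd_pushoff",
              "motor_noise_sd_step"))
    check_scalar(get(k), k, lower = 0)
  if (n_strides < 1) stopf("'n_strides' must be >= 1")
  structure(list(target_speed = target_speed, leg_length = leg_length,
                 gravity = gravity,
                 swing_cost_coefficient = swing_cost_coefficient,
                 step_length_gain = step_length_gain,
                 pushoff_gain = pushoff_gain,
                 sensory_noise_sd = sensory_noise_sd,
                 motor_noise_sd_pushoff = motor_noise_sd_pushoff,
                 motor_noise_sd_step = motor_noise_sd_step,
                 n_strides = n_strides, warmup = warmup, seed = seed),
            class = "walker_config")
}

#' Inverted-pendulum stance phase
#'
#' Advances the stance leg from the post-heel-strike angle `-alpha` to the
#' pre-transition angle `+alpha` (set by the commanded step length) using
#' the exact energy integral of the pendulum, so stance-phase energy is
#' conserved to machine precision. Reports the mid-stance speed (speed when
#' the leg is vertical) and the stance duration.
#'
#' @param speed entry speed (perpendicular to the leg) at `-alpha`.
#' @param step_length current step length (sets `alpha = asin(s/2)`).
#' @return A list with `end_speed`, `mid_stance_speed`, `duration`,
#'   `alpha`, `energy_drift` (absolute energy change over the stance, zero
#'   up to round-off), and `fell` / `degenerate` flags. `fell` is `TRUE`
#'   when the pendulum cannot pass vertical.
#' @export
stance_dynamics <- function(speed, step_length) {
  check_scalar(step_length, "step_length", lower = 0, upper = 2)
  alpha <- asin(step_length / 2)
  if (speed <= 0 && alpha == 0)
    return(list(end_speed = 0, mid_stance_speed = 0, duration = Inf,
                alpha = 0, energy_drift = 0, fell = FALSE, degenerate = TRUE))
  vmid2 <- speed^2 - 2 * (1 - cos(alpha))
  if (vmid2 <= 1e-14)
    return(list(end_speed = NA_real_, mid_stance_speed = NA_real_,
                duration = NA_real_, alpha = alpha, energy_drift = 0,
                fell = TRUE, degenerate = FALSE))
  e0 <- speed^2 / 2 - cos(alpha)
  end_speed <- sqrt(2 * (e0 + cos(alpha)))   # symmetric geometry: = speed
  list(end_speed = end_speed, mid_stance_speed = sqrt(vmid2),
       duration = stance_time(alpha, speed), alpha = alpha,
       energy_drift = abs((end_speed^2 / 2 - cos(alpha)) - e0),
       fell = FALSE, degenerate = FALSE)
}

#' Step-to-step transition
#'
#' Applies the push-off impulse along the trailing leg immediately before
#' an inelastic heel-strike onto the new stance leg:
#' `post = pre * cos(Phi) + P * sin(Phi)` with `Phi` the inter-leg angle,
#' and push-off work `P^2 / 2`.
#'
#' @param pre_speed speed at the end of stance.
#' @param pushoff push-off impulse (>= 0).
#' @param inter_leg_angle angle between trailing and new stance leg, rad.
#' @return A list with `post_speed` and `pushoff_work`.
#' @export
step_transition <- function(pre_speed, pushoff, inter_leg_angle) {
  if (pushoff < 0) stopf("push-off impulse must be non-negative")
  list(post_speed = pre_speed * cos(inter_leg_angle) +
         pushoff * sin(inter_leg_angle),
       pushoff_work = pushoff^2 / 2)
}

#' Linear mid-stance-speed feedback controller
#'
#' Maps the sensed mid-stance speed to commanded step length and push-off,
#' linear in the deviation from the nominal mid-stance speed: command =
#' nominal + gain * (sensed - nominal speed). Sensor and motor noise are
#' added by [run_walker()], so the controller itself is deterministic.
#'
#' @param sensed_mid_stance_speed sensed (possibly noisy) mid-stance speed.
#' @param config a [walker_config()].
#' @param nominal a [find_nominal_gait()] result.
#' @return A list with `step_length` and `pushoff` commands.
#' @export
feedback_controller <- function(sensed_mid_stance_speed, config, nominal) {
  dv <- sensed_mid_stance_speed - nominal$mid_stance_speed
  list(step_length = nominal$step_length + config$step_length_gain * dv,
       pushoff = nominal$pushoff + config$pushoff_gain * dv)
}

#' Energy-optimal nominal gait
#'
#' Finds the step length minimizing the cost per distance (push-off work
#' plus swing cost per step, divided by step length) at the given average
#' speed, with the push-off fixed by the periodic-gait condition
#' `P = v0 * tan(alpha)` (so that the post-transition state reproduces the
#' pre-stride state exactly).
#'
#' @param target_speed average speed in sqrt(g L) units.
#' @param swing_cost_coefficient swing-cost coefficient `c1`.
#' @param alpha_range search interval for the half inter-leg angle, rad.
#' @return A list of class `walker_gait` with `step_length`, `alpha`,
#'   `pushoff`, `entry_speed` (`v0`), `mid_stance_speed`, `step_time`,
#'   `step_cost` (per step), `cost_per_distance` and the inputs.
#' @export
find_nominal_gait <- function(target_speed, swing_cost_coefficient = 0.001,
                              alpha_range = c(0.03, 1.2)) {
  check_scalar(target_speed, "target_speed", lower = 0.05, upper = 1.5)
  c1 <- swing_cost_coefficient
  v0_for <- function(alpha) {
    # Entry speeds below vlo cannot carry the pendulum past vertical; just
    # above it the stance slows arbitrarily, so the average speed is
    # monotone increasing in v0 on (vlo, inf).
    vlo <- sqrt(2 * (1 - cos(alpha)))
    h <- function(v0) 2 * sin(alpha) / stance_time(alpha, v0) - target_speed
    if (h(10) < 0)
      stopf("no periodic gait reaches speed %g at step length %g",
            target_speed, 2 * sin(alpha))
    lo <- vlo * (1 + 1e-9) + 1e-12
    if (h(lo) >= 0) return(NA_real_)   # quadrature floor: alpha infeasible
    stats::uniroot(h, c(lo, 10), tol = 1e-13)$root
  }
  cost_pd <- function(alpha) {
    v0 <- v0_for(alpha)
    if (is.na(v0)) return(Inf)
    p <- v0 * tan(alpha)
    t <- stance_time(alpha, v0)
    (p^2 / 2 + c1 / t^4) / (2 * sin(alpha))
  }
  # Long steps cannot average the target speed (the pendulum would have to
  # graze the vertical); locate the feasible window on a coarse grid, then
  # refine around its best point.
  grid <- seq(alpha_range[1], alpha_range[2], length.out = 41)
  cg <- vapply(grid, cost_pd, 0)
  if (!any(is.finite(cg)))
    stopf("no feasible periodic gait at speed %g within step lengths [%g, %g]",
          target_speed, 2 * sin(alpha_range[1]), 2 * sin(alpha_range[2]))
  best <- which.min(cg)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(cost_pd, c(lo, hi), tol = 1e-9)
  alpha <- opt$minimum
  if (best == 1 || alpha <= alpha_range[1] + 1e-4)
    warnf("nominal step length is at the short-step search boundary (alpha = %.4f)",
          alpha)
  v0 <- v0_for(alpha)
  t <- stance_time(alpha, v0)
  p <- v0 * tan(alpha)
  structure(list(step_length = 2 * sin(alpha), alpha = alpha, pushoff = p,
                 entry_speed = v0,
                 mid_stance_speed = sqrt(v0^2 - 2 * (1 - cos(alpha))),
                 step_time = t, step_cost = p^2 / 2 + c1 / t^4,
                 cost_per_distance = opt$objective,
                 target_speed = target_speed,
                 swing_cost_coefficient = c1),
            class = "walker_gait")
}

#' @export
print.walker_gait <- function(x, ...) {
  cat(sprintf("<walker_gait> v = %.3f: step %.3f L, push-off %.4f, step time %.3f, cost/step %.5f\n",
              x$target_speed, x$step_length, x$pushoff, x$step_time,
              x$step_cost))
  invisible(x)
}

#' Simulate the noisy feedback-controlled walker
#'
#' Simulates `n_strides + warmup` strides from the nominal gait with seeded
#' sensory noise (on the sensed mid-stance speed) and motor noise (on the
#' executed push-off and foot placement), discards the warm-up, and
#' summarizes the stride costs. A stride's cost is its push-off work plus
#' the swing cost `c1 * f^4`.
#'
#' @param config a [walker_config()].
#' @param nominal optional precomputed [find_nominal_gait()] (recomputed
#'   from the config otherwise).
#' @return An object of class `walker_run`: `records` (a data.frame with
#'   per-stride push-off work, swing cost, total, step length, step time,
#'   mid-stance speed and energy drift), `mean_cost`, `sd_cost`, `fell`,
#'   `n_recorded`, and the `nominal` gait.
#' @export
run_walker <- function(config, nominal = NULL) {
  stopifnot(inherits(config, "walker_config"))
  if (is.null(nominal))
    nominal <- find_nominal_gait(config$target_speed,
                                 config$swing_cost_coefficient)
  c1 <- config$swing_cost_coefficient
  ntot <- config$n_strides + config$warmup
  rec <- matrix(NA_real_, ntot, 7,
                dimnames = list(NULL, c("pushoff_work", "swing_cost", "total",
                                        "step_length", "step_time",
                                        "mid_stance_speed", "energy_drift")))
  fell <- FALSE
  with_seed(config$seed, {
    v0 <- nominal$entry_speed
    alpha <- nominal$alpha
    for (i in seq_len(ntot)) {
      st <- stance_dynamics(v0, 2 * sin(alpha))
      if (isTRUE(st$fell) || isTRUE(st$degenerate)) { fell <- TRUE; break }
      sensed <- st$mid_stance_speed +
        stats::rnorm(1, 0, config$sensory_noise_sd)
      cmd <- feedback_controller(sensed, config, nominal)
      step_next <- cmd$step_length +
        stats::rnorm(1, 0, config$motor_noise_sd_step)
      step_next <- min(1.9, max(0.02, step_next))
      alpha_next <- asin(step_next / 2)
      pushoff <- max(0, cmd$pushoff +
                       stats::rnorm(1, 0, config$motor_noise_sd_pushoff))
      tr <- step_transition(st$end_speed, pushoff, alpha + alpha_next)
      rec[i, ] <- c(tr$pushoff_work, c1 / st$duration^4,
                    tr$pushoff_work + c1 / st$duration^4,
                    2 * sin(alpha), st$duration, st$mid_stance_speed,
                    st$energy_drift)
      if (tr$post_speed <= 1e-9) { fell <- TRUE; break }
      v0 <- tr$post_speed
      alpha <- alpha_next
    }
  })
  keep <- rec[seq_len(ntot) > config$warmup & !is.na(rec[, "total"]), ,
              drop = FALSE]
  structure(list(records = as.data.frame(keep),
                 mean_cost = if (nrow(keep)) mean(keep[, "total"]) else NA_real_,
                 sd_cost = if (nrow(keep) > 1) stats::sd(keep[, "total"]) else NA_real_,
                 fell = fell, n_recorded = nrow(keep),
                 nominal = nominal, config = config),
            class = "walker_run")
}

#' @export
print.walker_run <- function(x, ...) {
  cat(sprintf("<walker_run> %d strides: mean cost %.5f, sd %.2g%s\n",
              x$n_recorded, x$mean_cost, x$sd_cost,
              if (x$fell) " [FELL]" else ""))
  invisible(x)
}

#' Sweep sensory or motor noise levels
#'
#' Runs seeded replicates of the walker at each noise level of one noise
#' type (motor noise is applied to both push-off and foot placement) and
#' returns a tidy table of per-replicate summaries, the raw material for
#' the mean-cost and cost-dispersion versus noise trends.
#'
#' @param config base [walker_config()] (its noise sds are overridden).
#' @param noise_type `"motor"` or `"sensory"`.
#' @param levels numeric vector of noise sds.
#' @param replicates seeded replicates per level.
#' @param seed integer seed for the replicate seeds.
#' @return A data.frame with columns `noise_type`, `level`, `replicate`,
#'   `mean_cost`, `sd_cost`, `fell`, `n_recorded`.
#' @export
sweep_noise <- function(config = walker_config(),
                        noise_type = c("motor", "sensory"),
                        levels = c(0, 0.0025, 0.005, 0.01, 0.02),
                        replicates = 50, seed = 1) {
  noise_type <- match.arg(noise_type)
  nominal <- find_nominal_gait(config$target_speed,
                               config$swing_cost_coefficient)
  rep_seeds <- with_seed(seed,
                         matrix(sample.int(2^30, length(levels) * replicates),
                                nrow = length(levels)))
  out <- vector("list", length(levels) * replicates)
  k <- 0L
  for (li in seq_along(levels)) {
    lev <- levels[li]
    cfg <- config
    if (noise_type == "motor") {
      cfg$motor_noise_sd_pushoff <- lev
      cfg$motor_noise_sd_step <- lev
      cfg$sensory_noise_sd <- 0
    } else {
      cfg$sensory_noise_sd <- lev
      cfg$motor_noise_sd_pushoff <- 0
      cfg$motor_noise_sd_step <- 0
    }
    for (r in seq_len(replicates)) {
      cfg$seed <- rep_seeds[li, r]
      run <- run_walker(cfg, nominal)
      k <- k + 1L
      out[[k]] <- data.frame(noise_type = noise_type, level = lev,
                             replicate = r, mean_cost = run$mean_cost,
                             sd_cost = run$sd_cost, fell = run$fell,
                             n_recorded = run$n_recorded)
    }
  }
  do.call(rbind, out)
}
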