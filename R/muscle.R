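# Hill-type muscle description with constant moment arms and rigid tendon,
# and the per-sample static optimization that distributes joint torques
# across muscles by minimizing the sum of squared activations.

#' Muscle parameters
#'
#' @param name muscle label.
#' @param joint name of the spanned joint coordinate (e.g. `"ankle_l"`).
#' @param moment_arm signed constant moment arm in metres; the sign gives
#'   the direction of the joint moment the muscle produces.
#' @param max_isometric_force maximal isometric fiber force, N.
#' @param optimal_fiber_length optimal fiber length, m.
#' @param max_contraction_velocity maximal shortening velocity in optimal
#'   fiber lengths per second (fast-twitch value; the energetics model
#'   derives the slow-twitch value from it).
#' @param fast_twitch_ratio fraction of fast-twitch fibers in [0, 1].
#' @param muscle_mass muscle mass, kg (scales the metabolic rate).
#' @param nominal_angle joint angle (rad) at which the fiber sits at its
#'   optimal length.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(name, joint, moment_arm, max_isometric_force,
                          optimal_fiber_length,
                          max_contraction_velocity = 12,
                          fast_twitch_ratio = 0.5, muscle_mass,
                          nominal_angle = 0) {
  check_scalar(max_isometric_force, "max_isometric_force", lower = 1e-9)
  check_scalar(optimal_fiber_length, "optimal_fiber_length", lower = 1e-9)
  check_scalar(max_contraction_velocity, "max_contraction_velocity", lower = 1e-9)
  check_scalar(fast_twitch_ratio, "fast_twitch_ratio", lower = 0, upper = 1)
  check_scalar(muscle_mass, "muscle_mass", lower = 1e-9)
  check_scalar(moment_arm, "moment_arm")
  structure(list(name = name, joint = joint, moment_arm = moment_arm,
                 max_isometric_force = max_isometric_force,
                 optimal_fiber_length = optimal_fiber_length,
                 max_contraction_velocity = max_contraction_velocity,
                 fast_twitch_ratio = fast_twitch_ratio,
                 muscle_mass = muscle_mass,
                 nominal_angle = nominal_angle),
            class = "muscle_params")
}

#' Default sagittal muscle set
#'
#' Eight muscles per leg with constant moment arms: iliopsoas and glutei at
#' the hip, rectus femoris and vasti (extensors) and hamstrings (flexor) at
#' the knee, soleus and gastrocnemius (plantarflexors) and tibialis
#' anterior (dorsiflexor) at the ankle. Two-joint muscles are approximated
#' by their dominant single-joint action. Parameter magnitudes are typical
#' literature-scale values; every joint is spanned in both directions.
#'
#' @return A list of [muscle_params()] covering both legs.
#' @export
default_muscle_set <- function() {
  one_leg <- function(side) {
    j <- function(joint) paste0(joint, "_", side)
    list(
      muscle_params(paste0("iliopsoas_", side), j("hip"), 0.055, 2800, 0.10,
                    fast_twitch_ratio = 0.5, muscle_mass = 0.35,
                    nominal_angle = 0.05),
      muscle_params(paste0("glutei_", side), j("hip"), -0.062, 3200, 0.14,
                    fast_twitch_ratio = 0.45, muscle_mass = 0.60,
                    nominal_angle = 0.05),
      muscle_params(paste0("rectus_femoris_", side), j("knee"), -0.045, 1600,
                    0.08, fast_twitch_ratio = 0.6, muscle_mass = 0.30,
                    nominal_angle = 0.30),
      muscle_params(paste0("vasti_", side), j("knee"), -0.042, 6000, 0.09,
                    fast_twitch_ratio = 0.5, muscle_mass = 1.00,
                    nominal_angle = 0.30),
      muscle_params(paste0("hamstrings_", side), j("knee"), 0.038, 3200, 0.10,
                    fast_twitch_ratio = 0.45, muscle_mass = 0.70,
                    nominal_angle = 0.30),
      muscle_params(paste0("soleus_", side), j("ankle"), -0.055, 5200, 0.05,
                    fast_twitch_ratio = 0.2, muscle_mass = 0.45,
                    nominal_angle = 0.0),
      muscle_params(paste0("gastrocnemius_", side), j("ankle"), -0.055, 2600,
                    0.06, fast_twitch_ratio = 0.5, muscle_mass = 0.30,
                    nominal_angle = 0.0),
      muscle_params(paste0("tibialis_anterior_", side), j("ankle"), 0.04, 900,
                    0.07, fast_twitch_ratio = 0.3, muscle_mass = 0.15,
                    nominal_angle = 0.0))
  }
  c(one_leg("l"), one_leg("r"))
}

#' Active force-length curve
#'
#' Gaussian bell centred at the optimal fiber length.
#'
#' @param lnorm normalized fiber length (optimal lengths).
#' @param width curve width parameter.
#' @return Force-length multiplier in (0, 1].
#' @export
force_length <- function(lnorm, width = 0.45) exp(-((lnorm - 1) / width)^2)

#' Force-velocity curve
#'
#' Hill hyperbola on the concentric side (force reaching zero at the
#' maximal shortening velocity) and a saturating inverted hyperbola on the
#' eccentric side (plateau near 1.8 of isometric force). Shortening
#' velocity is positive.
#'
#' @param vnorm normalized fiber velocity in optimal lengths per second,
#'   shortening positive.
#' @param vmax maximal shortening velocity (optimal lengths/s).
#' @return Force-velocity multiplier.
#' @export
force_velocity <- function(vnorm, vmax = 12) {
  v <- vnorm / vmax
  conc <- pmax(0, 1 - v) / (1 + 4 * pmax(v, 0))
  w <- pmax(-v, 0)
  ecc <- 1.8 - 0.8 * (1 + w) / (1 + 13.6 * w)
  ifelse(vnorm >= 0, conc, ecc)
}

#' Hill-type fiber force
#'
#' `force = activation * F_max * f_L(l) * f_V(v)`; no passive element, so
#' zero activation gives zero force and full-speed shortening gives zero
#' force.
#'
#' @param lnorm normalized fiber length.
#' @param vnorm normalized fiber velocity, shortening positive.
#' @param activation activation in [0, 1].
#' @param params a [muscle_params()].
#' @return Fiber force in newtons (non-negative).
#' @export
hill_force <- function(lnorm, vnorm, activation, params) {
  pmax(0, activation * params$max_isometric_force *
         force_length(lnorm) *
         force_velocity(vnorm, params$max_contraction_velocity))
}

# Fiber kinematics from a joint-angle trajectory under the rigid-tendon,
# constant-moment-arm geometry: fiber length change = -r * (angle - nominal).
muscle_fiber_kinematics <- function(theta, theta_dot, params) {
  r <- params$moment_arm
  lopt <- params$optimal_fiber_length
  list(lnorm = 1 - r * (theta - params$nominal_angle) / lopt,
       vnorm = r * theta_dot / lopt)   # shortening positive
}

# Minimize sum(a^2) s.t. sum(c * a) = tau, 0 <= a <= 1, for one joint at one
# sample; `c` are the signed torque capacities a_m -> c_m * a_m. Returns the
# activations and the uncancelled torque residual (zero when feasible).
solve_joint_activations <- function(c_cap, tau) {
  m <- length(c_cap)
  a <- numeric(m)
  if (abs(tau) < 1e-12) return(list(a = a, residual = 0))
  agon <- which(c_cap * tau > 0 & abs(c_cap) > 1e-12)
  if (!length(agon)) return(list(a = a, residual = tau))
  capped <- logical(m)
  repeat {
    free <- agon[!capped[agon]]
    rem <- tau - sum(c_cap[agon][capped[agon]])
    if (!length(free)) return(list(a = a, residual = rem))
    mu <- rem / sum(c_cap[free]^2)
    a_free <- mu * c_cap[free]
    if (all(a_free <= 1 + 1e-12)) {
      a[free] <- pmin(1, pmax(0, a_free))
      return(list(a = a, residual = 0))
    }
    over <- free[a_free > 1]
    a[over] <- 1
    capped[over] <- TRUE
  }
}

#' Static-optimization muscle states along a torque trajectory
#'
#' At every sample, distributes each joint's net moment across the muscles
#' spanning it by minimizing the sum of squared activations subject to the
#' torque equality constraint and activation bounds [0, 1]. Because fiber
#' kinematics are fixed by the joint angles (rigid tendon, constant moment
#' arms), muscle force is linear in activation and the per-joint problem has
#' a closed-form KKT solution with iterative capping at full activation.
#' Torques exceeding the available strength leave a reported residual.
#'
#' @param torques a [inverse_dynamics()] result (columns named by joint).
#' @param kinematics a [gait_trial()] (joint angles are read from its
#'   channels) or a matrix of joint angles with columns named like the
#'   torque joints.
#' @param muscle_set list of [muscle_params()]; every torque joint must be
#'   spanned by at least one muscle of each sign.
#' @return An object of class `muscle_states` with per-muscle `activation`,
#'   `lnorm`, `vnorm`, `force` matrices (samples x muscles), the per-joint
#'   torque `residual`, and the muscle set.
#' @export
solve_muscle_states <- function(torques, kinematics, muscle_set) {
  stopifnot(inherits(torques, "joint_torques"))
  joints <- colnames(torques$torques)
  if (inherits(kinematics, "gait_trial")) {
    ang <- sapply(joints, function(j) {
      side <- sub(".*_", "", j)
      base <- sub("_[lr]$", "", j)
      kinematics$channels[, paste0(base, "_flexion_", side)]
    })
  } else ang <- as.matrix(kinematics)[, joints, drop = FALSE]
  n <- nrow(ang)
  dt <- if (length(torques$time) > 1) diff(torques$time[1:2]) else 1
  mus_joint <- vapply(muscle_set, `[[`, "", "joint")
  for (j in joints) {
    r <- vapply(muscle_set[mus_joint == j], `[[`, 0, "moment_arm")
    if (!any(r > 0) || !any(r < 0))
      stopf("joint '%s' is not spanned by muscles in both directions", j)
  }
  M <- length(muscle_set)
  nm <- vapply(muscle_set, `[[`, "", "name")
  act <- lnorm <- vnorm <- force <- matrix(
    0, n, M, dimnames = list(NULL, nm))
  resid <- matrix(0, n, length(joints), dimnames = list(NULL, joints))
  cap <- matrix(0, n, M)
  for (k in seq_len(M)) {
    p <- muscle_set[[k]]
    th <- ang[, p$joint]
    fk <- muscle_fiber_kinematics(th, central_diff(th, dt), p)
    lnorm[, k] <- fk$lnorm
    vnorm[, k] <- fk$vnorm
    cap[, k] <- p$moment_arm * p$max_isometric_force *
      force_length(fk$lnorm) *
      force_velocity(fk$vnorm, p$max_contraction_velocity)
  }
  for (j in seq_along(joints)) {
    mi <- which(mus_joint == joints[j])
    tau <- torques$torques[, joints[j]]
    for (i in seq_len(n)) {
      sol <- solve_joint_activations(cap[i, mi], tau[i])
      act[i, mi] <- sol$a
      resid[i, j] <- sol$residual
    }
  }
  for (k in seq_len(M))
    force[, k] <- hill_force(lnorm[, k], vnorm[, k], act[, k], muscle_set[[k]])
  if (any(abs(resid) > 1e-9))
    warnf("required torque exceeded muscle strength at %d sample-joint(s); max residual %.2f N m",
          sum(abs(resid) > 1e-9), max(abs(resid)))
  structure(list(time = torques$time, activation = act, lnorm = lnorm,
                 vnorm = vnorm, force = force, residual = resid,
                 muscle_set = muscle_set),
            class = "muscle_states")
}

#' @export
print.muscle_states <- function(x, ...) {
  cat(sprintf("<muscle_states> %d samples x %d muscles; peak activation %.2f\n",
              nrow(x$activation), ncol(x$activation), max(x$activation)))
  invisible(x)
}

#' Read or write a muscle set as a YAML config
#'
#' Serializes a list of [muscle_params()] to a YAML file (one named block
#' per muscle with every parameter field) and reads it back, so muscle sets
#' can be shared and edited outside R.
#'
#' @param muscle_set list of [muscle_params()].
#' @param path YAML file path.
#' @return `write_muscle_set` returns `path` invisibly; `read_muscle_set`
#'   returns the list of [muscle_params()].
#' @export
write_muscle_set <- function(muscle_set, path) {
  entries <- lapply(muscle_set, function(p) unclass(p))
  names(entries) <- vapply(muscle_set, `[[`, "", "name")
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_muscle_set
#' @export
read_muscle_set <- function(path) {
  entries <- yaml::read_yaml(path)
  lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    muscle_params(name = e$name, joint = e$joint, moment_arm = e$moment_arm,
                  max_isometric_force = e$max_isometric_force,
                  optimal_fiber_length = e$optimal_fiber_length,
                  max_contraction_velocity = e$max_contraction_velocity,
                  fast_twitch_ratio = e$fast_twitch_ratio,
                  muscle_mass = e$muscle_mass,
                  nominal_angle = e$nominal_angle)
  })
}
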