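# Reduced planar (sagittal) link-segment model and bottom-up Newton-Euler
# inverse dynamics. Seven segments: head-arms-trunk (HAT) plus bilateral
# thigh, shank and foot, with anthropometric parameters from standard
# segment-proportion tables (de Leva-style mass fractions, segment lengths,
# centre-of-mass offsets and radii of gyration).

#' Anthropometric link-segment model
#'
#' Builds per-segment mass, length, centre-of-mass offset and moment of
#' inertia for a seven-segment sagittal model scaled from body mass and
#' stature using standard proportion tables. Segment masses sum exactly to
#' body mass (the remainder after both legs goes to the HAT segment).
#'
#' @param participant_mass body mass, kg.
#' @param participant_height stature, m.
#' @param gravity gravitational acceleration, m/s^2.
#' @return An object of class `segment_model`; segment entries are lists
#'   with `mass` (kg), `length` (m), `com` (m from the proximal joint) and
#'   `inertia` (kg m^2 about the segment centre of mass). Users may adjust
#'   individual entries (e.g. the foot `com`) before running
#'   [inverse_dynamics()].
#' @export
segment_model <- function(participant_mass, participant_height,
                          gravity = 9.81) {
  check_scalar(participant_mass, "participant_mass", lower = 1)
  check_scalar(participant_height, "participant_height", lower = 0.5)
  m <- participant_mass; h <- participant_height
  seg <- function(mass, length, com_frac, rgyr_frac) {
    list(mass = mass, length = length, com = com_frac * length,
         inertia = mass * (rgyr_frac * length)^2)
  }
  thigh <- seg(0.1416 * m, 0.245 * h, 0.41, 0.329)
  shank <- seg(0.0433 * m, 0.246 * h, 0.44, 0.255)
  foot <- seg(0.0137 * m, 0.152 * h, 0.25, 0.257)
  hat_mass <- m - 2 * (thigh$mass + shank$mass + foot$mass)
  hat <- seg(hat_mass, 0.30 * h, 0.5, 0.4)
  structure(list(participant_mass = m, participant_height = h,
                 gravity = gravity,
                 thigh = thigh, shank = shank, foot = foot, hat = hat),
            class = "segment_model")
}

#' @export
print.segment_model <- function(x, ...) {
  cat(sprintf("<segment_model> mass %.1f kg, height %.2f m\n",
              x$participant_mass, x$participant_height))
  for (s in c("hat", "thigh", "shank", "foot"))
    cat(sprintf("  %-5s m=%6.2f kg  L=%.3f m  com=%.3f m  I=%.4f kg m^2\n",
                s, x[[s]]$mass, x[[s]]$length, x[[s]]$com, x[[s]]$inertia))
  invisible(x)
}

# Newton-Euler step for one segment: given the segment's inertial state and
# the external load applied by the distal neighbour (force `f_dist`, moment
# `m_dist`, applied at `p_dist`), returns the force and moment the proximal
# neighbour applies at `p_prox`. All positional arguments are n x 2
# matrices over time; `acc` is the COM acceleration, `alpha` the angular
# acceleration. An optional ground load (`f_ext` at `p_ext`) supports the
# foot segment.
newton_euler_segment <- function(mass, inertia, com, acc, alpha,
                                 p_prox, gravity,
                                 f_dist = NULL, m_dist = NULL, p_dist = NULL,
                                 f_ext = NULL, p_ext = NULL) {
  n <- nrow(com)
  zero <- matrix(0, n, 2)
  if (is.null(f_dist)) f_dist <- zero
  if (is.null(m_dist)) m_dist <- numeric(n)
  if (is.null(f_ext)) f_ext <- zero
  grav <- cbind(0, rep(-mass * gravity, n))
  f_prox <- mass * acc - f_dist - f_ext - grav
  m_prox <- inertia * alpha - m_dist -
    cross_z(p_prox - com, f_prox) -
    (if (is.null(p_dist)) 0 else cross_z(p_dist - com, f_dist)) -
    (if (is.null(p_ext)) 0 else cross_z(p_ext - com, f_ext))
  list(force = f_prox, moment = m_prox)
}

#' Planar inverse dynamics of a gait trial
#'
#' Computes sagittal ankle, knee and hip flexion moments for both legs by
#' bottom-up Newton-Euler recursion (foot, shank, thigh) from joint angles,
#' pelvis trajectory, ground reaction forces applied at the centre of
#' pressure, and the anthropometric [segment_model()]. Segment kinematics
#' are reconstructed from the angles; linear and angular accelerations come
#' from central differences of the (filtered) signals. A pelvis residual
#' force/moment closing the chain against the HAT segment is also computed
#' but is excluded from any effort summary.
#'
#' @param trial a single- or multi-stride [gait_trial()], filtered.
#' @param model a [segment_model()].
#' @return An object of class `joint_torques`: `time`, a `torques` matrix
#'   with columns `hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r` (N m,
#'   moment applied by the proximal on the distal segment), `joint_names`,
#'   and the pelvis `residual` (n x 3: force x, force y, moment z).
#' @export
inverse_dynamics <- function(trial, model) {
  stopifnot(inherits(trial, "gait_trial"), inherits(model, "segment_model"))
  ch <- trial$channels
  missing <- setdiff(gait_channels(), colnames(ch))
  if (length(missing))
    stopf("trial is missing channel '%s'", missing[1])
  dt <- 1 / trial$sampling_rate
  n <- nrow(ch)
  g <- model$gravity
  tilt <- ch[, "pelvis_tilt"]
  pelvis <- cbind(ch[, "pelvis_x"], ch[, "pelvis_y"])

  leg <- function(side) {
    hipA <- ch[, paste0("hip_flexion_", side)]
    kneeA <- ch[, paste0("knee_flexion_", side)]
    ankleA <- ch[, paste0("ankle_flexion_", side)]
    grf <- cbind(ch[, paste0("grf_x_", side)], ch[, paste0("grf_y_", side)])
    cop <- cbind(ch[, paste0("cop_x_", side)], rep(0, n))
    phi_th <- hipA + tilt          # absolute thigh angle from vertical
    phi_sh <- phi_th - kneeA       # absolute shank angle from vertical
    delta <- phi_sh + ankleA       # absolute foot angle from horizontal
    along <- function(phi) cbind(sin(phi), -cos(phi))   # down the segment
    hip <- pelvis
    knee <- hip + model$thigh$length * along(phi_th)
    ankle <- knee + model$shank$length * along(phi_sh)
    foot_axis <- cbind(cos(delta), sin(delta))
    com_th <- hip + model$thigh$com * along(phi_th)
    com_sh <- knee + model$shank$com * along(phi_sh)
    com_ft <- ankle + model$foot$com * foot_axis
    acc2 <- function(p) cbind(second_diff(p[, 1], dt), second_diff(p[, 2], dt))
    ft <- newton_euler_segment(model$foot$mass, model$foot$inertia, com_ft,
                               acc2(com_ft), second_diff(delta, dt),
                               p_prox = ankle, gravity = g,
                               f_ext = grf, p_ext = cop)
    sh <- newton_euler_segment(model$shank$mass, model$shank$inertia, com_sh,
                               acc2(com_sh), second_diff(phi_sh, dt),
                               p_prox = knee, gravity = g,
                               f_dist = -ft$force, m_dist = -ft$moment,
                               p_dist = ankle)
    th <- newton_euler_segment(model$thigh$mass, model$thigh$inertia, com_th,
                               acc2(com_th), second_diff(phi_th, dt),
                               p_prox = hip, gravity = g,
                               f_dist = -sh$force, m_dist = -sh$moment,
                               p_dist = knee)
    list(ankle = ft$moment, knee = sh$moment, hip = th$moment,
         hip_force = th$force)
  }

  L <- leg("l"); R <- leg("r")
  # Pelvis/HAT residual: what the chain leaves unexplained at the pelvis.
  com_hat <- pelvis + model$hat$com * cbind(sin(tilt + pi), -cos(tilt + pi))
  acc_hat <- cbind(second_diff(com_hat[, 1], dt), second_diff(com_hat[, 2], dt))
  f_res <- model$hat$mass * acc_hat + L$hip_force + R$hip_force -
    cbind(0, rep(-model$hat$mass * g, n))
  m_res <- model$hat$inertia * second_diff(tilt, dt) + L$hip + R$hip
  torques <- cbind(hip_l = L$hip, knee_l = L$knee, ankle_l = L$ankle,
                   hip_r = R$hip, knee_r = R$knee, ankle_r = R$ankle)
  if (any(!is.finite(torques)))
    stopf("inverse dynamics produced non-finite torques")
  structure(list(time = trial$time, torques = torques,
                 joint_names = colnames(torques),
                 n_joints = ncol(torques),
                 residual = cbind(fx = f_res[, 1], fy = f_res[, 2], mz = m_res)),
            class = "joint_torques")
}

#' @export
print.joint_torques <- function(x, ...) {
  cat(sprintf("<joint_torques> %d samples, joints: %s\n",
              length(x$time), paste(x$joint_names, collapse = ", ")))
  rms <- sqrt(colMeans(x$torques^2))
  cat("  RMS [N m]:", paste(sprintf("%s=%.1f", names(rms), rms),
                            collapse = "  "), "\n")
  invisible(x)
}
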