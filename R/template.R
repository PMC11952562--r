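# Nominal single-cycle gait waveforms used as the seed of the synthetic
# trial generator. Shapes are smooth closed-form curves chosen to resemble
# typical sagittal walking kinematics and kinetics: double-humped vertical
# GRF, braking-then-propulsive fore-aft GRF, anterior heel-to-toe CoP
# progression under a foot that translates with the belt, and joint-angle
# curves with the usual stance/swing structure. They are expressed in the
# treadmill (lab) frame, so every channel is periodic in the gait cycle.

#' Nominal single-cycle gait template
#'
#' Builds smooth, physiologically plausible one-cycle waveforms for every
#' trial channel, parameterized by walking speed. Cycle duration shortens and
#' waveform amplitudes grow mildly with speed. The left-foot vertical GRF is
#' identically zero during the constructed swing interval, so it is strictly
#' below any positive heel-strike threshold there, and rises through the
#' stance humps from the cycle origin (the left heel strike).
#'
#' @param speed walking speed in m/s, within 0.5 to 2.0.
#' @param mass participant mass in kg used to scale forces so the cycle-mean
#'   total vertical force equals body weight.
#' @param height participant stature in m used to place the pelvis.
#' @return An object of class `gait_template`: a list with the cycle
#'   `period` (s), left-foot `duty` factor, the `speed`, and `evaluate(phase)`
#'   returning a matrix of all channels at gait-cycle fractions `phase`.
#' @examples
#' tpl <- default_template(1.0)
#' waves <- tpl$evaluate(seq(0, 1, length.out = 201))
#' @export
default_template <- function(speed, mass = 72.66, height = 1.759) {
  check_scalar(speed, "speed", lower = 0.5, upper = 2.0)
  check_scalar(mass, "mass", lower = 20)
  check_scalar(height, "height", lower = 1)
  period <- round(1.9 - 0.6 * speed, 2)        # stride time shortens with speed
  duty <- 0.68 - 0.075 * speed                 # stance fraction per foot
  g <- 9.81
  hip_amp <- 0.28 + 0.08 * speed
  pelvis_y0 <- 0.53 * height
  stride_len <- speed * period

  # Unit-amplitude double-hump vertical GRF over stance fraction s in [0,1].
  vshape <- function(s) sin(pi * s) + 0.35 * sin(3 * pi * s)

  one_foot <- function(phi) {
    phi <- phi %% 1
    st <- phi < duty
    s <- ifelse(st, phi / duty, 0)
    fy <- ifelse(st, vshape(s), 0)
    fx <- ifelse(st, -sin(2 * pi * s), 0)
    # CoP: heel lands ahead of the pelvis, translates backward with the belt
    # while progressing heel to toe; swing ramps linearly to the next strike.
    x_hs <- 0.25 * stride_len
    cop_st <- x_hs + 0.22 * s - speed * phi * period
    cop_to <- x_hs + 0.22 - speed * duty * period
    cop <- ifelse(st, cop_st, cop_to + (x_hs - cop_to) * (phi - duty) / (1 - duty))
    cbind(fy = fy, fx = fx, cop = cop)
  }

  angles <- function(phi) {
    phi <- phi %% 1
    hip <- 0.05 + hip_amp * cos(2 * pi * phi)
    knee <- 0.08 + 0.25 * pbump(phi, 0.15, 0.10) + 1.05 * pbump(phi, 0.72, 0.11)
    ankle <- 0.10 * sin(2 * pi * phi + 0.4) - 0.38 * pbump(phi, 0.62, 0.07)
    cbind(hip = hip, knee = knee, ankle = ankle)
  }

  # Normalize vertical force so the cycle-mean of both feet equals body weight.
  fine <- seq(0, 1, length.out = 4096 + 1)[-1]
  raw <- one_foot(fine)[, "fy"] + one_foot(fine + 0.5)[, "fy"]
  fy_scale <- mass * g / mean(raw)
  fx_scale <- 0.16 * mass * g * (0.5 + 0.5 * speed)

  evaluate <- function(phase) {
    phi <- phase %% 1
    la <- angles(phi); ra <- angles(phi + 0.5)
    lf <- one_foot(phi); rf <- one_foot(phi + 0.5)
    out <- cbind(
      pelvis_tilt = 0.03 + 0.02 * sin(4 * pi * phi),
      pelvis_x = 0.01 * sin(4 * pi * phi),   # step-periodic fore-aft sway
      pelvis_y = pelvis_y0 * (1 + 0.01 * cos(4 * pi * phi - 0.6)),
      hip_flexion_l = la[, "hip"], knee_flexion_l = la[, "knee"],
      ankle_flexion_l = la[, "ankle"],
      hip_flexion_r = ra[, "hip"], knee_flexion_r = ra[, "knee"],
      ankle_flexion_r = ra[, "ankle"],
      grf_x_l = fx_scale * lf[, "fx"], grf_y_l = fy_scale * lf[, "fy"],
      grf_x_r = fx_scale * rf[, "fx"], grf_y_r = fy_scale * rf[, "fy"],
      cop_x_l = lf[, "cop"], cop_x_r = rf[, "cop"])
    out
  }

  structure(list(speed = speed, period = period, duty = duty,
                 mass = mass, height = height, evaluate = evaluate),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf("<gait_template> speed %g m/s, period %g s, duty %.3f\n",
              x$speed, x$period, x$duty))
  invisible(x)
}

# Periodicity check used by the generator on (possibly user-supplied)
# templates: endpoint values must agree to a small fraction of each
# channel's range.
check_template_periodic <- function(template, tol = 1e-3) {
  grid <- seq(0, 1, length.out = 257)
  v <- template$evaluate(grid)
  rng <- apply(v, 2, function(z) max(z) - min(z))
  a <- template$evaluate(0)
  b <- template$evaluate(1 - 1e-9)
  gap <- abs(a - b)
  bad <- which(gap > tol * pmax(rng, 1e-9) + 1e-9)
  if (length(bad))
    stopf("template is not periodic: channel '%s' differs by %g between cycle endpoints",
          colnames(v)[bad[1]], gap[bad[1]])
  invisible(TRUE)
}
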