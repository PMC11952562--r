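# Synthetic multi-stride trial generator. Each stride is a realization of
# the nominal template with a per-stride random period, a shared per-stride
# amplitude factor (so kinematics and kinetics co-vary coherently), a
# per-stride phase offset, a low-order random Fourier series added to the
# angle channels (smooth within-stride waveform noise), and optional white
# measurement noise. Strides are concatenated with a short cosine crossfade
# so the joins are continuous; per stride the total vertical force is
# rescaled so its time average matches body weight.

#' Stride-to-stride variability configuration
#'
#' Collects the standard deviations of every per-stride noise source used by
#' [generate_trial()]. With all values zero the generator emits an exactly
#' stride-periodic trial.
#'
#' @param stride_period_sd sd of the per-stride period draw, seconds.
#' @param amplitude_sd sd of the per-stride multiplicative amplitude factor
#'   (dimensionless fractional scaling, shared across channels).
#' @param phase_sd sd of the per-stride phase offset, fraction of gait cycle.
#' @param additive_smooth_sd sd of smooth within-stride waveform noise added
#'   to the angle channels, radians.
#' @param measurement_noise_sd_angle sd of white measurement noise on angle
#'   channels, radians.
#' @param measurement_noise_sd_force sd of white measurement noise on force
#'   channels, newtons.
#' @param seed optional integer seed; [generate_trial()] uses it when its own
#'   `seed` argument is `NULL`.
#' @return An object of class `variability_config`.
#' @export
variability_config <- function(stride_period_sd = 0, amplitude_sd = 0,
                               phase_sd = 0, additive_smooth_sd = 0,
                               measurement_noise_sd_angle = 0,
                               measurement_noise_sd_force = 0,
                               seed = NULL) {
  sds <- c(stride_period_sd = stride_period_sd, amplitude_sd = amplitude_sd,
           phase_sd = phase_sd, additive_smooth_sd = additive_smooth_sd,
           measurement_noise_sd_angle = measurement_noise_sd_angle,
           measurement_noise_sd_force = measurement_noise_sd_force)
  for (k in names(sds)) check_scalar(sds[[k]], k, lower = 0)
  structure(c(as.list(sds), list(seed = seed)), class = "variability_config")
}

#' Default variability for the synthetic experiment
#'
#' Calibrated so that single-stride cost-estimate percent errors in the
#' default experiment span roughly the low-percent to ~15% range seen in
#' treadmill walking, while stride-period variability stays at the few-percent
#' level typical of steady treadmill gait.
#'
#' @return A [variability_config()].
#' @export
default_variability <- function() {
  variability_config(stride_period_sd = 0.02, amplitude_sd = 0.035,
                     phase_sd = 0.006, additive_smooth_sd = 0.02,
                     measurement_noise_sd_angle = 0.003,
                     measurement_noise_sd_force = 1.5)
}

#' Generate a synthetic multi-stride gait trial
#'
#' Realizes `n_strides` strides of the template with seeded stride-to-stride
#' variability and concatenates them into a continuous trial. Per stride the
#' vertical GRF of both feet is rescaled so its time average equals body
#' weight; the left vertical GRF is below 30 N throughout each swing
#' interval, so heel-strike detection at the conventional threshold
#' segments the trial cleanly.
#'
#' @param template a [default_template()] or a list with elements `period`
#'   (seconds) and `evaluate(phase)` returning a named channel matrix;
#'   the waveforms must be periodic (cycle endpoints agreeing).
#' @param n_strides number of strides to generate (>= 2).
#' @param belt_speed belt speed recorded in the trial metadata, m/s.
#' @param variability a [variability_config()].
#' @param seed integer seed controlling every random draw; two calls with the
#'   same seed return identical trials.
#' @param sampling_rate sampling frequency, Hz.
#' @param participant_mass,participant_height anthropometry, kg and m.
#' @param crossfade duration of the cosine blend across stride joins, s.
#' @return A [gait_trial()].
#' @examples
#' tpl <- default_template(0.8)
#' trial <- generate_trial(tpl, n_strides = 10, seed = 1,
#'                         variability = default_variability())
#' @export
generate_trial <- function(template, n_strides = 60,
                           belt_speed = template$speed,
                           variability = variability_config(), seed = NULL,
                           sampling_rate = 100,
                           participant_mass = 72.66,
                           participant_height = 1.759,
                           crossfade = 0.05) {
  stopifnot(inherits(variability, "variability_config"))
  if (!is.list(template) || is.null(template$evaluate) || is.null(template$period))
    stopf("'template' must provide $period and $evaluate(phase)")
  if (n_strides < 2) stopf("'n_strides' must be >= 2")
  check_template_periodic(template)
  if (is.null(seed)) seed <- variability$seed
  fs <- sampling_rate
  chans <- gait_channels()
  ang <- angle_channels()
  frc <- force_channels()
  g <- 9.81
  bw <- participant_mass * g
  # Cycle means used to apply amplitude scaling about the mean waveform.
  fine <- seq(0, 1, length.out = 1025)[-1]
  base <- template$evaluate(fine)[, chans, drop = FALSE]
  ch_mean <- colMeans(base)

  with_seed(seed, {
    t0 <- template$period
    periods <- t0 + stats::rnorm(n_strides, 0, variability$stride_period_sd)
    periods <- pmax(periods, 0.4 * t0)
    nsamp <- pmax(8L, as.integer(round(periods * fs)))
    amp <- 1 + stats::rnorm(n_strides, 0, variability$amplitude_sd)
    hump <- stats::rnorm(n_strides, 0, variability$amplitude_sd)
    phase_off <- stats::rnorm(n_strides, 0, variability$phase_sd)
    nf <- 3L
    four_a <- four_b <- array(0, c(n_strides, nf, length(ang)))
    if (variability$additive_smooth_sd > 0) {
      sdk <- variability$additive_smooth_sd / sqrt(nf)
      four_a[] <- stats::rnorm(length(four_a), 0, sdk)
      four_b[] <- stats::rnorm(length(four_b), 0, sdk)
    }

    # Channel values of stride i evaluated at within-stride phases p (>= 0;
    # p may exceed 1 when extending a stride past its own join). `fy_scale`
    # is the stride's cached body-weight renormalization factor; when NULL it
    # is computed from this evaluation (full-stride call).
    stride_values <- function(i, p, fy_scale = NULL) {
      m <- template$evaluate((p + phase_off[i]) %% 1)[, chans, drop = FALSE]
      kin <- setdiff(chans, c(frc, "cop_x_l", "cop_x_r"))
      m[, kin] <- sweep(sweep(m[, kin, drop = FALSE], 2, ch_mean[kin], "-") * amp[i],
                        2, ch_mean[kin], "+")
      # Redistribute vertical load between the two humps (shape variability
      # that survives the body-weight renormalization below).
      for (ch in c("grf_y_l", "grf_y_r")) {
        v <- m[, ch]
        m[, ch] <- pmax(0, v * (1 + hump[i] * sin(2 * pi * (p %% 1))))
      }
      m[, c("grf_x_l", "grf_x_r")] <- m[, c("grf_x_l", "grf_x_r")] * amp[i]
      if (variability$additive_smooth_sd > 0) {
        for (k in seq_len(nf)) {
          ck <- cos(2 * pi * k * p); sk <- sin(2 * pi * k * p)
          m[, ang] <- m[, ang] +
            outer(ck, four_a[i, k, ]) + outer(sk, four_b[i, k, ])
        }
      }
      # Per-stride body-weight renormalization of vertical force.
      if (is.null(fy_scale)) {
        tot <- mean(m[, "grf_y_l"] + m[, "grf_y_r"])
        fy_scale <- if (tot > 0) bw / tot else 1
      }
      m[, c("grf_y_l", "grf_y_r")] <- m[, c("grf_y_l", "grf_y_r")] * fy_scale
      attr(m, "fy_scale") <- fy_scale
      m
    }

    blocks <- vector("list", n_strides)
    fy_sc <- numeric(n_strides)
    for (i in seq_len(n_strides)) {
      p <- (seq_len(nsamp[i]) - 1L) / nsamp[i]
      blocks[[i]] <- stride_values(i, p)
      fy_sc[i] <- attr(blocks[[i]], "fy_scale")
    }
    # Cosine crossfade over the first `w` samples of each stride against the
    # previous stride's extension past its own cycle end.
    w <- as.integer(round(crossfade * fs))
    if (w > 0) {
      for (i in 2:n_strides) {
        wk <- min(w, nsamp[i], nsamp[i - 1])
        j <- seq_len(wk)
        p_prev <- 1 + (j - 1L) / nsamp[i - 1]
        prev <- stride_values(i - 1L, p_prev, fy_scale = fy_sc[i - 1L])
        beta <- 0.5 * (1 - cos(pi * j / (wk + 1)))
        blocks[[i]][j, ] <- (1 - beta) * prev + beta * blocks[[i]][j, , drop = FALSE]
      }
    }
    m <- do.call(rbind, blocks)
    if (variability$measurement_noise_sd_angle > 0)
      m[, ang] <- m[, ang] +
        stats::rnorm(length(m[, ang]), 0, variability$measurement_noise_sd_angle)
    if (variability$measurement_noise_sd_force > 0) {
      m[, frc] <- m[, frc] +
        stats::rnorm(length(m[, frc]), 0, variability$measurement_noise_sd_force)
      m[, c("grf_y_l", "grf_y_r")] <- pmax(0, m[, c("grf_y_l", "grf_y_r")])
    }
    time <- (seq_len(nrow(m)) - 1L) / fs
    trial <- gait_trial(time, m, sampling_rate = fs, belt_speed = belt_speed,
                        participant_mass = participant_mass,
                        participant_height = participant_height)
    attr(trial, "stride_starts") <- cumsum(c(1L, nsamp[-n_strides]))
    trial
  })
}
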