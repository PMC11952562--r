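# Data preparation: zero-phase Butterworth filtering, heel-strike detection,
# stride segmentation onto a common gait-cycle grid, CoP swing repair, and
# construction of the ensemble-averaged gait pattern.

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (effective 8th order, zero phase lag) to every kinematic, force and CoP
#' channel. Each channel is de-meaned and mirror-padded before filtering so
#' constant channels pass through exactly and edge transients are confined
#' to the discarded pad.
#'
#' @param trial a [gait_trial()].
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist frequency.
#' @param order filter order before the forward-backward pass.
#' @return The filtered [gait_trial()]. Vertical GRF is clamped at zero to
#'   preserve its non-negativity against small filter undershoot.
#' @export
lowpass_filter <- function(trial, cutoff = 6, order = 4) {
  stopifnot(inherits(trial, "gait_trial"))
  fs <- trial$sampling_rate
  if (cutoff >= fs / 2)
    stopf("cutoff %g Hz is not below the Nyquist frequency %g Hz", cutoff, fs / 2)
  check_scalar(cutoff, "cutoff", lower = 1e-9)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- nrow(trial$channels)
  pad <- min(n - 1L, as.integer(2 * fs))
  out <- trial$channels
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    mu <- mean(x)
    xc <- x - mu
    xp <- c(rev(xc[2:(pad + 1L)]), xc, rev(xc[(n - pad):(n - 1L)]))
    yp <- signal::filtfilt(bf, xp)
    out[, j] <- yp[(pad + 1L):(pad + n)] + mu
  }
  out[, c("grf_y_l", "grf_y_r")] <- pmax(0, out[, c("grf_y_l", "grf_y_r")])
  trial$channels <- out
  trial
}

#' Detect heel strikes from vertical ground reaction force
#'
#' Finds upward crossings of a force threshold: samples `k` with
#' `f[k-1] < threshold <= f[k]`, debounced so two detections are at least
#' `min_gap` seconds apart. Crossings at the series boundary are excluded.
#'
#' @param vertical_grf numeric vector of vertical GRF, newtons.
#' @param threshold detection threshold in newtons (conventionally 30 N).
#' @param sampling_rate sampling frequency, Hz.
#' @param min_gap debounce interval in seconds.
#' @return Integer sample indices of the detected heel strikes; empty (with
#'   a warning) when the force never crosses the threshold.
#' @export
detect_heel_strikes <- function(vertical_grf, threshold = 30,
                                sampling_rate = 100, min_gap = 0.4) {
  check_scalar(threshold, "threshold", lower = 1e-12)
  f <- as.numeric(vertical_grf)
  n <- length(f)
  k <- which(f[-n] < threshold & f[-1] >= threshold) + 1L
  k <- k[k > 1L & k < n]
  if (!length(k)) {
    warnf("vertical GRF never crosses the %g N threshold", threshold)
    return(integer(0))
  }
  gap <- as.integer(round(min_gap * sampling_rate))
  keep <- k[1]
  for (i in k[-1]) if (i - keep[length(keep)] >= gap) keep <- c(keep, i)
  keep
}

#' Segment strides onto a common gait-cycle grid
#'
#' Selects a seeded uniformly random window of `n_strides + 1` consecutive
#' heel strikes, slices each stride (heel strike to next heel strike of the
#' same foot), and resamples every channel onto a common gait-cycle grid of
#' `grid_size` points (0% to 100%) by cubic interpolation.
#'
#' @param trial a [gait_trial()].
#' @param heel_strikes integer sample indices from [detect_heel_strikes()].
#' @param n_strides number of consecutive strides to keep.
#' @param selection_seed integer seed for the random window choice; `NULL`
#'   uses the current RNG stream.
#' @param grid_size number of gait-cycle samples (default 101: 0%,1%,...,100%).
#' @return An object of class `stride_set`: per-stride channel matrices on
#'   the grid, stride durations in seconds, and the heel-strike window used.
#' @export
segment_strides <- function(trial, heel_strikes, n_strides = 5,
                            selection_seed = NULL, grid_size = 101) {
  stopifnot(inherits(trial, "gait_trial"))
  hs <- as.integer(heel_strikes)
  if (length(hs) < n_strides + 1L)
    stopf("need at least %d heel strikes for %d strides, found %d",
          n_strides + 1L, n_strides, length(hs))
  n_windows <- length(hs) - n_strides
  start <- with_seed(selection_seed, sample.int(n_windows, 1L))
  win <- hs[start:(start + n_strides)]
  grid <- seq(0, 1, length.out = grid_size)
  strides <- vector("list", n_strides)
  for (i in seq_len(n_strides)) {
    idx <- win[i]:win[i + 1L]
    u <- (idx - idx[1]) / (idx[length(idx)] - idx[1])
    m <- matrix(0, grid_size, ncol(trial$channels),
                dimnames = list(NULL, colnames(trial$channels)))
    for (j in seq_len(ncol(m)))
      m[, j] <- stats::spline(u, trial$channels[idx, j], xout = grid,
                              method = "fmm")$y
    strides[[i]] <- m
  }
  structure(list(strides = strides,
                 stride_durations = diff(win) / trial$sampling_rate,
                 grid_size = grid_size,
                 source_heel_strike_indices = win,
                 sampling_rate = trial$sampling_rate,
                 belt_speed = trial$belt_speed,
                 participant_mass = trial$participant_mass,
                 participant_height = trial$participant_height),
            class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %d strides on a %d-point gait-cycle grid\n",
              length(x$strides), x$grid_size))
  cat(sprintf("  durations: %s s\n",
              paste(format(x$stride_durations, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Repair centre of pressure during swing
#'
#' The CoP is undefined while a foot is off the ground (vertical force below
#' `stance_threshold`). Swing-phase CoP samples are replaced by a monotone
#' cubic interpolant through the stance-phase CoP samples; stance samples are
#' left untouched. Leading or trailing swing periods hold the nearest stance
#' value. The repair is inconsequential for kinetics because the
#' corresponding forces are essentially zero.
#'
#' @param trial a [gait_trial()].
#' @param stance_threshold vertical force threshold in newtons.
#' @return The repaired [gait_trial()].
#' @export
repair_cop <- function(trial, stance_threshold = 30) {
  stopifnot(inherits(trial, "gait_trial"))
  for (side in c("l", "r")) {
    fy <- trial$channels[, paste0("grf_y_", side)]
    cop <- trial$channels[, paste0("cop_x_", side)]
    stance <- fy >= stance_threshold
    if (!any(stance)) {
      warnf("foot '%s' never exceeds the %g N stance threshold; CoP unchanged",
            side, stance_threshold)
      next
    }
    if (all(stance)) next
    st <- which(stance)
    t <- trial$time
    f <- stats::splinefun(t[st], cop[st], method = "monoH.FC")
    sw <- which(!stance)
    val <- f(t[sw])
    val[t[sw] < t[st[1]]] <- cop[st[1]]
    val[t[sw] > t[st[length(st)]]] <- cop[st[length(st)]]
    cop[sw] <- val
    trial$channels[, paste0("cop_x_", side)] <- cop
  }
  trial
}

#' Ensemble-averaged gait pattern
#'
#' Averages a stride set point-wise over the gait-cycle grid: each grid
#' point of each channel is the arithmetic mean of the source strides at
#' that gait-cycle fraction, and the pattern's period is the mean stride
#' duration.
#'
#' @param strides a [segment_strides()] result.
#' @return An object of class `gait_pattern` with the mean channel matrix,
#'   the mean `period`, and `n_source_strides`.
#' @export
average_gait_pattern <- function(strides) {
  stopifnot(inherits(strides, "stride_set"))
  ns <- length(strides$strides)
  if (ns < 1L) stopf("stride set is empty")
  gs <- vapply(strides$strides, nrow, 0L)
  if (any(gs != strides$grid_size))
    stopf("mismatched gait-cycle grids: %s", paste(unique(gs), collapse = ", "))
  acc <- Reduce(`+`, strides$strides) / ns
  structure(list(channels = acc,
                 period = mean(strides$stride_durations),
                 n_source_strides = ns,
                 grid_size = strides$grid_size,
                 sampling_rate = strides$sampling_rate,
                 belt_speed = strides$belt_speed,
                 participant_mass = strides$participant_mass,
                 participant_height = strides$participant_height),
            class = "gait_pattern")
}

#' @export
print.gait_pattern <- function(x, ...) {
  cat(sprintf("<gait_pattern> mean of %d strides, period %.3f s\n",
              x$n_source_strides, x$period))
  invisible(x)
}

# Materialize a gait-cycle-grid channel matrix as a uniformly sampled
# single-stride gait_trial of the given duration.
grid_to_trial <- function(channels, period, sampling_rate, belt_speed,
                          participant_mass, participant_height) {
  grid_size <- nrow(channels)
  grid <- seq(0, 1, length.out = grid_size)
  n <- max(8L, as.integer(round(period * sampling_rate)) + 1L)
  time <- (seq_len(n) - 1L) / sampling_rate
  u <- pmin(time / period, 1)
  m <- matrix(0, n, ncol(channels), dimnames = list(NULL, colnames(channels)))
  for (j in seq_len(ncol(channels)))
    m[, j] <- stats::spline(grid, channels[, j], xout = u, method = "fmm")$y
  m[, c("grf_y_l", "grf_y_r")] <- pmax(0, m[, c("grf_y_l", "grf_y_r")])
  gait_trial(time, m, sampling_rate = sampling_rate, belt_speed = belt_speed,
             participant_mass = participant_mass,
             participant_height = participant_height)
}

#' Materialize an averaged gait pattern as a single-stride trial
#'
#' Resamples the averaged pattern from the gait-cycle grid onto a uniform
#' time base spanning its mean period, for reuse by the cost operations that
#' consume [gait_trial()] input.
#'
#' @param pattern a [average_gait_pattern()] result.
#' @param sampling_rate target sampling frequency, Hz (default: the source
#'   trial's).
#' @return A single-stride [gait_trial()].
#' @export
pattern_as_trial <- function(pattern, sampling_rate = pattern$sampling_rate) {
  stopifnot(inherits(pattern, "gait_pattern"))
  grid_to_trial(pattern$channels, pattern$period, sampling_rate,
                pattern$belt_speed, pattern$participant_mass,
                pattern$participant_height)
}

#' Materialize one segmented stride as a single-stride trial
#'
#' @param strides a [segment_strides()] result.
#' @param i stride index.
#' @param sampling_rate target sampling frequency, Hz.
#' @return A single-stride [gait_trial()] spanning the stride's own duration.
#' @export
stride_as_trial <- function(strides, i, sampling_rate = strides$sampling_rate) {
  stopifnot(inherits(strides, "stride_set"))
  grid_to_trial(strides$strides[[i]], strides$stride_durations[i],
                sampling_rate, strides$belt_speed, strides$participant_mass,
                strides$participant_height)
}
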