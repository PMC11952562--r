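# The gait_trial container: a multi-stride treadmill-style recording of
# sagittal joint angles, pelvis trajectory, ground reaction forces and
# centre of pressure, uniformly sampled.

# Channel layout shared by the whole package. Angles in radians, positions in
# metres, forces in newtons; "_l"/"_r" suffixes are left/right.
gait_channels <- function() {
  c("pelvis_tilt", "pelvis_x", "pelvis_y",
    "hip_flexion_l", "knee_flexion_l", "ankle_flexion_l",
    "hip_flexion_r", "knee_flexion_r", "ankle_flexion_r",
    "grf_x_l", "grf_y_l", "grf_x_r", "grf_y_r",
    "cop_x_l", "cop_x_r")
}

angle_channels <- function() {
  c("pelvis_tilt",
    "hip_flexion_l", "knee_flexion_l", "ankle_flexion_l",
    "hip_flexion_r", "knee_flexion_r", "ankle_flexion_r")
}

force_channels <- function() c("grf_x_l", "grf_y_l", "grf_x_r", "grf_y_r")

#' Construct a multi-stride gait trial
#'
#' Bundles uniformly sampled time series of sagittal joint angles, pelvis
#' trajectory, per-foot ground reaction forces (GRF) and fore-aft centre of
#' pressure (CoP) together with sampling and participant metadata. All
#' downstream operations (filtering, segmentation, inverse dynamics, cost
#' estimation) consume this container.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing
#'   with constant step `1/sampling_rate`.
#' @param channels numeric matrix with one row per sample and named columns;
#'   must contain every channel in [gait_channels()]. Vertical GRF columns
#'   (`grf_y_l`, `grf_y_r`) must be non-negative.
#' @param sampling_rate sampling frequency in Hz.
#' @param belt_speed treadmill belt speed in m/s.
#' @param participant_mass body mass in kg.
#' @param participant_height stature in m.
#' @return An object of class `gait_trial`.
#' @seealso [generate_trial()], [read_gait_trial()], [lowpass_filter()]
#' @export
gait_trial <- function(time, channels, sampling_rate, belt_speed = NA_real_,
                       participant_mass = NA_real_,
                       participant_height = NA_real_) {
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  channels <- as.matrix(channels)
  if (is.null(colnames(channels)))
    stopf("'channels' must have named columns")
  missing <- setdiff(gait_channels(), colnames(channels))
  if (length(missing))
    stopf("missing required channel(s): %s", paste(missing, collapse = ", "))
  if (nrow(channels) != length(time))
    stopf("channels have %d rows but time has %d samples",
          nrow(channels), length(time))
  dt <- 1 / sampling_rate
  steps <- diff(time)
  bad <- which(abs(steps - dt) > 1e-6 * dt + 1e-12)
  if (length(bad))
    stopf("time is not uniform at step %g s: first bad row %d (step %g s)",
          dt, bad[1] + 1L, steps[bad[1]])
  for (ch in c("grf_y_l", "grf_y_r")) {
    if (any(channels[, ch] < -1e-9))
      stopf("vertical GRF channel '%s' has negative values (min %g N)",
            ch, min(channels[, ch]))
  }
  structure(list(time = as.numeric(time),
                 channels = channels[, gait_channels(), drop = FALSE],
                 sampling_rate = sampling_rate,
                 belt_speed = belt_speed,
                 participant_mass = participant_mass,
                 participant_height = participant_height),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  dur <- x$time[length(x$time)] - x$time[1]
  cat(sprintf("<gait_trial> %d samples @ %g Hz (%.1f s), %d channels\n",
              length(x$time), x$sampling_rate, dur, ncol(x$channels)))
  cat(sprintf("  belt speed %s m/s, mass %s kg, height %s m\n",
              format(x$belt_speed), format(x$participant_mass),
              format(x$participant_height)))
  invisible(x)
}

#' @export
summary.gait_trial <- function(object, threshold = 30, ...) {
  hs <- detect_heel_strikes(object$channels[, "grf_y_l"],
                            threshold = threshold,
                            sampling_rate = object$sampling_rate)
  cat(sprintf("gait_trial: %.1f s at %g Hz, %d left heel strikes (%g N threshold)\n",
              diff(range(object$time)), object$sampling_rate, length(hs),
              threshold))
  if (length(hs) > 1)
    cat(sprintf("  stride period %.3f +/- %.3f s\n",
                mean(diff(hs)) / object$sampling_rate,
                stats::sd(diff(hs)) / object$sampling_rate))
  invisible(object)
}

#' @export
plot.gait_trial <- function(x, channels = c("grf_y_l", "ankle_flexion_l"), ...) {
  op <- graphics::par(mfrow = c(length(channels), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (ch in channels)
    graphics::plot(x$time, x$channels[, ch], type = "l",
                   xlab = "time [s]", ylab = ch, ...)
  invisible(x)
}

#' Write a gait trial to delimited text
#'
#' Writes a wide-format delimited file whose header names the channels with
#' `time` as the first column (tab-separated, the conventional motion-file
#' dialect) or a plain CSV, plus a JSON sidecar (`<path>.json`) carrying the
#' sampling rate, belt speed and participant anthropometry so the file pair
#' round-trips losslessly.
#'
#' @param trial a [gait_trial()].
#' @param path output file path.
#' @param format `"mot"` (tab-separated) or `"csv"`.
#' @param sidecar write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_gait_trial <- function(trial, path, format = c("mot", "csv"),
                             sidecar = TRUE) {
  stopifnot(inherits(trial, "gait_trial"))
  format <- match.arg(format)
  sep <- if (format == "mot") "\t" else ","
  df <- data.frame(time = trial$time, trial$channels, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(sampling_rate = trial$sampling_rate,
                 belt_speed = trial$belt_speed,
                 participant_mass = trial$participant_mass,
                 participant_height = trial$participant_height)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a gait trial from delimited text
#'
#' Accepts the tab-separated motion-file dialect or plain CSV; columns are
#' matched by name so their order is free. Metadata is taken from the JSON
#' sidecar written by [write_gait_trial()] when present.
#'
#' @param path file path.
#' @param sidecar optional explicit sidecar path; default `<path>.json`.
#' @return A [gait_trial()].
#' @export
read_gait_trial <- function(path, sidecar = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!"time" %in% names(df))
    stopf("file '%s' has no 'time' column", path)
  missing <- setdiff(gait_channels(), names(df))
  if (length(missing))
    stopf("file '%s' is missing channel(s): %s", path,
          paste(missing, collapse = ", "))
  time <- df$time
  steps <- diff(time)
  if (any(steps <= 0))
    stopf("non-monotonic time in '%s' at row %d", path, which(steps <= 0)[1] + 1L)
  dt <- stats::median(steps)
  bad <- which(abs(steps - dt) > 1e-6 * dt)
  if (length(bad))
    stopf("time gap in '%s' at row %d (step %g s, expected %g s)",
          path, bad[1] + 1L, steps[bad[1]], dt)
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  meta <- list(sampling_rate = 1 / dt, belt_speed = NA_real_,
               participant_mass = NA_real_, participant_height = NA_real_)
  if (file.exists(sidecar)) {
    got <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (k in names(meta)) if (!is.null(got[[k]])) meta[[k]] <- got[[k]]
  }
  gait_trial(time = time,
             channels = as.matrix(df[, gait_channels(), drop = FALSE]),
             sampling_rate = meta$sampling_rate,
             belt_speed = meta$belt_speed,
             participant_mass = meta$participant_mass,
             participant_height = meta$participant_height)
}
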