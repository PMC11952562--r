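# Three cost-averaging methods and their comparison statistics:
#   method 1 - cost of a single (randomly selected) stride,
#   method 2 - cost of the averaged gait pattern,
#   method 3 - mean of per-stride costs (the gold-standard reference).

#' Torque-effort cost function for a single-stride trial
#'
#' @param model a [segment_model()].
#' @param joint_weights optional per-joint weights for [torque_effort()].
#' @return A function mapping a single-stride [gait_trial()] to its
#'   torque-squared effort (N^2 m^2).
#' @export
torque_cost_fn <- function(model, joint_weights = NULL) {
  force(model); force(joint_weights)
  function(trial) torque_effort(inverse_dynamics(trial, model), joint_weights)
}

#' Muscle-metabolic cost function for a single-stride trial
#'
#' @param model a [segment_model()].
#' @param muscle_set list of [muscle_params()].
#' @param ... passed to [umberger_rate()].
#' @return A function mapping a single-stride [gait_trial()] to its
#'   mass-normalized average metabolic power (W/kg).
#' @export
umberger_cost_fn <- function(model, muscle_set = default_muscle_set(), ...) {
  force(model); force(muscle_set)
  dots <- list(...)
  function(trial) {
    do.call(stride_metabolic_cost,
            c(list(trial, model, muscle_set), dots))$average_power_per_kg
  }
}

#' Compare the three cost-averaging methods on one trial
#'
#' Runs the preparation chain (zero-phase low-pass filter, CoP swing repair,
#' heel-strike detection, seeded stride segmentation), computes the cost of
#' every segmented stride (methods 1 and 3), materializes the ensemble-
#' averaged gait pattern and computes its cost (method 2), and assembles
#' percent errors relative to method 3, the mean of per-stride costs.
#'
#' @param trial a multi-stride [gait_trial()].
#' @param cost_fn function mapping a single-stride [gait_trial()] to a
#'   scalar cost, e.g. [torque_cost_fn()] or [umberger_cost_fn()].
#' @param n_strides number of consecutive strides to use.
#' @param seed integer seed for the stride-window selection and the
#'   method-1 single-stride draw.
#' @param cutoff low-pass cutoff, Hz.
#' @param threshold heel-strike force threshold, N.
#' @param grid_size gait-cycle grid points.
#' @param preprocess apply filtering and CoP repair (set `FALSE` when the
#'   trial is already prepared).
#' @param edge_trim seconds trimmed from both trial ends before stride
#'   selection, so filter edge transients never enter an analysed stride.
#' @return An object of class `cost_comparison` with `method1_costs` (per
#'   stride), `method2_cost`, `method3_cost`, the percent errors
#'   `percent_errors_method1` and `percent_error_method2` (100 * (estimate -
#'   method3) / method3), the index of the seeded single-stride draw, and
#'   stride metadata.
#' @export
compare_methods <- function(trial, cost_fn, n_strides = 5, seed = NULL,
                            cutoff = 6, threshold = 30, grid_size = 101,
                            preprocess = TRUE, edge_trim = 1) {
  stopifnot(inherits(trial, "gait_trial"), is.function(cost_fn))
  if (preprocess) {
    trial <- lowpass_filter(trial, cutoff)
    trial <- repair_cop(trial, threshold)
  }
  hs <- detect_heel_strikes(trial$channels[, "grf_y_l"], threshold,
                            trial$sampling_rate)
  n <- nrow(trial$channels)
  trim <- edge_trim * trial$sampling_rate
  hs <- hs[hs > trim & hs <= n - trim]
  seg_seed <- if (is.null(seed)) NULL else seed
  strides <- segment_strides(trial, hs, n_strides = n_strides,
                             selection_seed = seg_seed,
                             grid_size = grid_size)
  m1 <- vapply(seq_len(n_strides), function(i)
    cost_fn(stride_as_trial(strides, i)), 0)
  pattern <- average_gait_pattern(strides)
  m2 <- cost_fn(pattern_as_trial(pattern))
  m3 <- mean(m1)
  pick <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                    sample.int(n_strides, 1L))
  structure(list(method1_costs = m1,
                 method1_selected = pick,
                 method2_cost = m2,
                 method3_cost = m3,
                 percent_errors_method1 = 100 * (m1 - m3) / m3,
                 percent_error_method2 = 100 * (m2 - m3) / m3,
                 stride_durations = strides$stride_durations,
                 n_strides = n_strides,
                 belt_speed = trial$belt_speed,
                 participant_mass = trial$participant_mass),
            class = "cost_comparison")
}

#' @export
print.cost_comparison <- function(x, ...) {
  cat(sprintf("<cost_comparison> %d strides, speed %s m/s\n",
              x$n_strides, format(x$belt_speed)))
  cat(sprintf("  method 3 (mean of strides): %.6g\n", x$method3_cost))
  cat(sprintf("  method 2 (averaged pattern): %.6g  (%+.2f%%)\n",
              x$method2_cost, x$percent_error_method2))
  cat(sprintf("  method 1 range: %+.2f%% .. %+.2f%% (stride %d drawn)\n",
              min(x$percent_errors_method1), max(x$percent_errors_method1),
              x$method1_selected))
  invisible(x)
}

#' Paired comparison of method-2 and method-3 costs across trials
#'
#' Classical paired t-test on per-trial differences, reported with the mean
#' and standard error of the percent differences. Zero-variance differences
#' are handled explicitly: all-tied pairs give t = 0 and p = 1; a constant
#' non-zero difference is reported as a degenerate certain case (p = 0)
#' with a diagnostic flag.
#'
#' @param method2_costs,method3_costs equal-length numeric vectors, one
#'   entry per trial.
#' @return A list with `n`, `mean_difference`, `t`, `df`, `p`,
#'   `mean_percent`, `se_percent`, and `degenerate` (`"none"`,
#'   `"all_tied"`, or `"constant_difference"`).
#' @export
paired_comparison <- function(method2_costs, method3_costs) {
  if (length(method2_costs) != length(method3_costs))
    stopf("paired samples differ in length (%d vs %d)",
          length(method2_costs), length(method3_costs))
  n <- length(method2_costs)
  if (n < 2) stopf("need at least 2 pairs")
  d <- method2_costs - method3_costs
  pct <- 100 * d / method3_costs
  out <- list(n = n, mean_difference = mean(d),
              mean_percent = mean(pct),
              se_percent = stats::sd(pct) / sqrt(n),
              degenerate = "none")
  scale <- mean(abs(method3_costs))
  if (all(abs(d) <= 1e-9 * scale)) {
    out$t <- 0; out$df <- n - 1; out$p <- 1; out$degenerate <- "all_tied"
    return(out)
  }
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      out$t <- 0; out$df <- n - 1; out$p <- 1; out$degenerate <- "all_tied"
    } else {
      out$t <- sign(mean(d)) * Inf; out$df <- n - 1; out$p <- 0
      out$degenerate <- "constant_difference"
    }
    return(out)
  }
  tt <- stats::t.test(method2_costs, method3_costs, paired = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out
}

#' Speed dependence of cost-estimation errors
#'
#' Ordinary least-squares regression of percent errors on trial speed with
#' a two-sided t-test on the slope. Exactly collinear degenerate inputs are
#' resolved by convention: a perfect non-zero linear fit reports p = 0 and
#' a perfectly constant response reports slope 0 with p = 1.
#'
#' @param percent_errors numeric vector of errors (one per observation).
#' @param speeds matching numeric vector of speeds, m/s; at least two
#'   distinct values.
#' @return A list with `slope`, `se`, `p`, `intercept`, and the `lm` fit.
#' @export
speed_regression <- function(percent_errors, speeds) {
  if (length(percent_errors) != length(speeds))
    stopf("lengths differ (%d vs %d)", length(percent_errors), length(speeds))
  if (length(percent_errors) < 3) stopf("need at least 3 observations")
  if (length(unique(speeds)) < 2) stopf("need at least 2 distinct speeds")
  fit <- stats::lm(percent_errors ~ speeds)
  cf <- stats::coef(fit)
  res_sd <- sqrt(sum(stats::residuals(fit)^2) /
                 max(1, stats::df.residual(fit)))
  if (res_sd < 1e-12 * (1 + max(abs(percent_errors)))) {
    slope <- unname(cf[2])
    return(list(slope = slope, se = 0,
                p = if (abs(slope) < 1e-12) 1 else 0,
                intercept = unname(cf[1]), fit = fit))
  }
  sm <- summary(fit)$coefficients
  list(slope = sm[2, 1], se = sm[2, 2], p = sm[2, 4],
       intercept = sm[1, 1], fit = fit)
}
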