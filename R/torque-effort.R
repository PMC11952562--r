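# Torque-squared effort: squared joint moments, weighted per joint, summed
# over joints and averaged over the trajectory duration.

#' Torque-squared effort cost
#'
#' Evaluates `(1/T) * integral of sum_j a_j * tau_j(t)^2 dt` by trapezoidal
#' quadrature, where `tau_j` are the joint moments, `a_j` non-negative
#' joint-specific weights (default all one) and `T` the trajectory duration.
#' Because the integrand is convex in the torques, the effort of a mean
#' trajectory never exceeds the mean effort of the trajectories averaged
#' (Jensen's inequality) — the mechanism by which averaged gait patterns
#' underestimate effort.
#'
#' @param torques a [inverse_dynamics()] result, or any list with numeric
#'   `time` and a `torques` matrix (samples x joints).
#' @param joint_weights numeric vector of per-joint weights `a_j`
#'   (recycled); default 1 for every joint.
#' @param duration optional explicit duration `T` in seconds; must match the
#'   trajectory span.
#' @return Scalar effort in N^2 m^2.
#' @examples
#' tt <- list(time = seq(0, 1, 0.01),
#'            torques = cbind(j1 = rep(2, 101)))
#' torque_effort(tt)  # 4
#' @export
torque_effort <- function(torques, joint_weights = NULL, duration = NULL) {
  time <- torques$time
  tau <- as.matrix(torques$torques)
  span <- time[length(time)] - time[1]
  if (is.null(duration)) duration <- span
  if (duration <= 0) stopf("duration must be positive (got %g)", duration)
  if (abs(duration - span) > 1e-6 * max(duration, span))
    stopf("duration %g s does not equal the trajectory span %g s",
          duration, span)
  if (is.null(joint_weights)) joint_weights <- rep(1, ncol(tau))
  joint_weights <- rep_len(joint_weights, ncol(tau))
  if (any(joint_weights < 0)) stopf("joint weights must be non-negative")
  integrand <- as.numeric(tau^2 %*% joint_weights)
  trapz_int(time, integrand) / duration
}

#' Mean of torque trajectories on a common time base
#'
#' Point-wise arithmetic mean of several torque trajectories sharing the
#' same time grid; the torque-level counterpart of the averaged gait
#' pattern.
#'
#' @param trajectories list of objects accepted by [torque_effort()], all on
#'   the same time base.
#' @return A list with `time` and the mean `torques` matrix.
#' @export
mean_torque_trajectory <- function(trajectories) {
  if (!length(trajectories)) stopf("empty trajectory list")
  t0 <- trajectories[[1]]$time
  for (tr in trajectories)
    if (length(tr$time) != length(t0) || max(abs(tr$time - t0)) > 1e-9)
      stopf("trajectories are not on a common time base")
  acc <- Reduce(`+`, lapply(trajectories, function(tr) as.matrix(tr$torques)))
  list(time = t0, torques = acc / length(trajectories))
}
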