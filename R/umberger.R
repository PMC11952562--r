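# Umberger-family muscle energetics: total metabolic rate decomposed into
# mechanical work rate of the contractile element plus activation heat,
# maintenance heat, and shortening/lengthening heat, evaluated per muscle
# from activation, normalized fiber length and velocity, and fiber force.
#
# Constants follow the published model this family derives from:
#  - activation + maintenance heat at full activation: 128*ft + 25 W/kg
#    (1.28 per percent fast twitch + 25), split 40% activation / 60%
#    maintenance, the maintenance part scaled by the force-length curve on
#    the descending limb;
#  - activation/maintenance heats scale with activation^0.6, shortening
#    heat with activation^2.0, lengthening heat with activation^1.0;
#  - shortening heat coefficients 100/vmax_ST (slow) and 153/vmax_FT
#    (fast) W s/kg per (optimal length/s), with vmax_ST = vmax_FT/2.5;
#  - lengthening heat coefficient 4 * (slow shortening coefficient);
#  - an aerobic scaling factor S = 1.5;
#  - in the modified form used here by default, the whole-muscle rate is
#    clamped non-negative (eccentric work cannot drive net metabolic
#    absorption); the clamp adjustment is booked into the
#    shortening/lengthening term so the four terms always sum to the total.

#' Constants of the muscle energetics model
#'
#' @param fast_twitch_ratio fraction of fast-twitch fibers.
#' @param vmax_fast maximal shortening velocity of fast fibers
#'   (optimal lengths/s).
#' @param aerobic_scale aerobic scaling factor applied to all heat rates.
#' @return Named list of model coefficients (W/kg scale).
#' @export
umberger_constants <- function(fast_twitch_ratio = 0.5, vmax_fast = 12,
                               aerobic_scale = 1.5) {
  vmax_slow <- vmax_fast / 2.5
  list(h_am = 128 * fast_twitch_ratio + 25,   # W/kg at full activation
       act_frac = 0.4,                         # activation share of h_am
       alpha_s_slow = 100 / vmax_slow,         # W s/kg per lopt/s
       alpha_s_fast = 153 / vmax_fast,
       alpha_l = 4 * (100 / vmax_slow),
       vmax_fast = vmax_fast, vmax_slow = vmax_slow,
       aerobic_scale = aerobic_scale)
}

#' Muscle metabolic rate decomposition
#'
#' Evaluates the four-term metabolic rate of one muscle along a state
#' trajectory: mechanical work rate of the fibers (force times shortening
#' velocity), activation heat, maintenance heat, and shortening/lengthening
#' heat, each in watts (per-kg rates scaled by muscle mass), plus their
#' time integrals.
#'
#' @param states either a [solve_muscle_states()] result (with `muscle`
#'   naming the column to evaluate) or a list with numeric `time`,
#'   `activation`, `lnorm`, `vnorm` (shortening positive) and `force`
#'   vectors.
#' @param params the [muscle_params()] of the muscle.
#' @param muscle muscle name when `states` is a `muscle_states` object.
#' @param clamp_total clamp the total rate at zero per sample (the modified
#'   model form; default `TRUE`). The clamp adjustment is added to the
#'   shortening/lengthening heat term so the decomposition still sums to
#'   the total.
#' @param aerobic_scale aerobic scaling factor for the heat terms.
#' @param include_basal add a constant basal rate.
#' @param basal_rate basal rate in W/kg muscle when `include_basal`.
#' @return An object of class `metabolic_breakdown`: per-sample `work_rate`,
#'   `activation_heat_rate`, `maintenance_heat_rate`,
#'   `shortening_lengthening_heat_rate` and `total_rate` (W), the
#'   trapezoid-integrated energies (`integrated`, J), `integrated_cost`
#'   (total J), and `duration` (s).
#' @export
umberger_rate <- function(states, params, muscle = NULL, clamp_total = TRUE,
                          aerobic_scale = 1.5, include_basal = FALSE,
                          basal_rate = 1.2) {
  if (inherits(states, "muscle_states")) {
    if (is.null(muscle)) muscle <- params$name
    states <- list(time = states$time,
                   activation = states$activation[, muscle],
                   lnorm = states$lnorm[, muscle],
                   vnorm = states$vnorm[, muscle],
                   force = states$force[, muscle])
  }
  a <- pmin(1, pmax(0, states$activation))
  l <- states$lnorm
  v <- states$vnorm        # optimal lengths / s, shortening positive
  f <- states$force
  k <- umberger_constants(params$fast_twitch_ratio,
                          params$max_contraction_velocity, aerobic_scale)
  S <- k$aerobic_scale
  mm <- params$muscle_mass
  fl <- force_length(l)
  long <- l > 1
  # Activation and maintenance heat (activation^0.6 scaling; maintenance
  # follows the force-length curve on the descending limb).
  a_am <- a^0.6
  h_act <- k$act_frac * k$h_am * a_am * S
  h_mnt <- (1 - k$act_frac) * k$h_am * a_am * S * ifelse(long, fl, 1)
  # Shortening / lengthening heat.
  ft <- params$fast_twitch_ratio
  h_short <- (k$alpha_s_slow * (1 - ft) + k$alpha_s_fast * ft) *
    pmax(v, 0) * a^2 * S * ifelse(long, fl, 1)
  h_leng <- k$alpha_l * pmax(-v, 0) * a * S * ifelse(long, fl, 1)
  h_sl <- h_short + h_leng
  # Mechanical work rate of the fibers per kg (positive when shortening).
  w <- f * v * params$optimal_fiber_length / mm
  if (include_basal) h_mnt <- h_mnt + basal_rate
  total <- w + h_act + h_mnt + h_sl
  if (clamp_total) {
    deficit <- pmax(0, -total)
    h_sl <- h_sl + deficit
    total <- total + deficit
  }
  scale <- mm
  out <- list(time = states$time,
              work_rate = w * scale,
              activation_heat_rate = h_act * scale,
              maintenance_heat_rate = h_mnt * scale,
              shortening_lengthening_heat_rate = h_sl * scale,
              total_rate = total * scale)
  dur <- states$time[length(states$time)] - states$time[1]
  out$integrated <- vapply(
    out[c("work_rate", "activation_heat_rate", "maintenance_heat_rate",
          "shortening_lengthening_heat_rate", "total_rate")],
    function(y) trapz_int(states$time, y), 0)
  out$integrated_cost <- out$integrated[["total_rate"]]
  out$duration <- dur
  class(out) <- "metabolic_breakdown"
  out
}

#' @export
print.metabolic_breakdown <- function(x, ...) {
  cat(sprintf("<metabolic_breakdown> %.3f s, total %.3f J (mean %.2f W)\n",
              x$duration, x$integrated_cost,
              if (x$duration > 0) x$integrated_cost / x$duration else NA))
  terms <- x$integrated[names(x$integrated) != "total_rate"]
  cat("  ", paste(sprintf("%s=%.3f J", sub("_rate$", "", names(terms)), terms),
                  collapse = "  "), "\n")
  invisible(x)
}

#' Whole-body metabolic cost of a single stride
#'
#' Composes the full chain on a single-stride trial (a segmented stride or a
#' materialized averaged pattern): planar inverse dynamics, per-sample
#' static optimization of muscle activations, and the muscle energetics
#' model summed over all muscles and integrated over the stride.
#'
#' @param trial a single-stride [gait_trial()], already filtered.
#' @param model a [segment_model()].
#' @param muscle_set list of [muscle_params()]; default [default_muscle_set()].
#' @param ... passed to [umberger_rate()] (e.g. `clamp_total`,
#'   `include_basal`).
#' @return A list of class `stride_cost` with the summed
#'   `metabolic_breakdown` fields, `average_power` (W, integrated cost over
#'   stride time), `average_power_per_kg` (W/kg body mass), the per-muscle
#'   breakdown list, and the muscle `states`.
#' @export
stride_metabolic_cost <- function(trial, model, muscle_set = default_muscle_set(),
                                  ...) {
  stopifnot(inherits(trial, "gait_trial"))
  tq <- inverse_dynamics(trial, model)
  st <- solve_muscle_states(tq, trial, muscle_set)
  per <- lapply(muscle_set, function(p) umberger_rate(st, p, ...))
  names(per) <- vapply(muscle_set, `[[`, "", "name")
  total_rate <- Reduce(`+`, lapply(per, `[[`, "total_rate"))
  integrated <- Reduce(`+`, lapply(per, `[[`, "integrated"))
  dur <- trial$time[length(trial$time)] - trial$time[1]
  avg <- integrated[["total_rate"]] / dur
  structure(list(time = trial$time, total_rate = total_rate,
                 integrated = integrated,
                 integrated_cost = integrated[["total_rate"]],
                 duration = dur, average_power = avg,
                 average_power_per_kg = avg / trial$participant_mass,
                 per_muscle = per, states = st),
            class = "stride_cost")
}

#' @export
print.stride_cost <- function(x, ...) {
  cat(sprintf("<stride_cost> %.3f s stride: %.1f J, %.1f W (%.3f W/kg)\n",
              x$duration, x$integrated_cost, x$average_power,
              x$average_power_per_kg))
  invisible(x)
}
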