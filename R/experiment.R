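# End-to-end synthetic experiment mirroring the multi-participant,
# multi-speed treadmill layout: 8 participants x 3 speeds x 1 trial, five
# analysed strides per trial, both cost models.

#' Experiment layout
#'
#' @param n_participants number of synthetic participants.
#' @param speeds walking speeds in m/s.
#' @param trials_per_speed trials per participant per speed.
#' @param n_strides strides analysed per trial.
#' @param cost_models subset of `c("torque", "umberger")`.
#' @param master_seed integer master seed; per-participant and per-trial
#'   seeds are derived from it by fixed splitting so participants are
#'   independent but reproducible.
#' @return An object of class `experiment_layout`.
#' @export
experiment_layout <- function(n_participants = 8, speeds = c(0.8, 1.0, 1.2),
                              trials_per_speed = 1, n_strides = 5,
                              cost_models = c("torque", "umberger"),
                              master_seed = 1) {
  cost_models <- match.arg(cost_models, c("torque", "umberger"),
                           several.ok = TRUE)
  structure(list(n_participants = n_participants, speeds = speeds,
                 trials_per_speed = trials_per_speed, n_strides = n_strides,
                 cost_models = cost_models, master_seed = master_seed),
            class = "experiment_layout")
}

#' Run the synthetic multi-participant experiment
#'
#' For every participant and speed, draws participant anthropometry from
#' seeded population distributions (mass 72.66 +/- 13.51 kg, height
#' 1.759 +/- 0.061 m), generates a ~2-minute synthetic trial (60 strides)
#' with the given stride-to-stride variability, and runs
#' [compare_methods()] for each requested cost model. Aggregates per-speed
#' and pooled paired comparisons of the averaged-pattern cost (method 2)
#' against the mean per-stride cost (method 3), sign-agreement counts, the
#' pooled single-stride error range, and the speed regression of the
#' errors.
#'
#' @param layout an [experiment_layout()].
#' @param variability a [variability_config()]; default
#'   [default_variability()].
#' @param n_strides_generated strides generated per trial before the
#'   analysis window is selected.
#' @param verbose print progress.
#' @return An object of class `gait_experiment`: `results` (one row per
#'   trial and model), `comparisons` (the `cost_comparison` objects),
#'   `paired` (per model: per-speed and pooled tests), `regression` (per
#'   model), `sign_agreement` (per model), and the resolved layout.
#' @export
run_experiment <- function(layout = experiment_layout(),
                           variability = default_variability(),
                           n_strides_generated = 60, verbose = FALSE) {
  stopifnot(inherits(layout, "experiment_layout"))
  seeds <- with_seed(layout$master_seed, {
    np <- layout$n_participants
    list(anthro = matrix(stats::rnorm(2 * np), np, 2),
         trial = matrix(sample.int(2^30, np * length(layout$speeds) *
                                     layout$trials_per_speed),
                        nrow = np))
  })
  mass <- pmin(110, pmax(45, 72.66 + 13.51 * seeds$anthro[, 1]))
  height <- pmin(2.0, pmax(1.5, 1.759 + 0.061 * seeds$anthro[, 2]))
  rows <- list(); comps <- list()
  col <- 0L
  for (si in seq_along(layout$speeds)) {
    for (tr in seq_len(layout$trials_per_speed)) {
      col <- col + 1L
      for (p in seq_len(layout$n_participants)) {
        speed <- layout$speeds[si]
        seed <- seeds$trial[p, col]
        tpl <- default_template(speed, mass = mass[p], height = height[p])
        trial <- generate_trial(tpl, n_strides = n_strides_generated,
                                variability = variability, seed = seed,
                                participant_mass = mass[p],
                                participant_height = height[p])
        model <- segment_model(mass[p], height[p])
        trial_prep <- repair_cop(lowpass_filter(trial), 30)
        for (cm in layout$cost_models) {
          fn <- if (cm == "torque") torque_cost_fn(model)
                else umberger_cost_fn(model)
          cmp <- compare_methods(trial_prep, fn,
                                 n_strides = layout$n_strides,
                                 seed = seed + 1L, preprocess = FALSE)
          key <- sprintf("p%02d_s%g_t%d_%s", p, speed, tr, cm)
          comps[[key]] <- cmp
          rows[[key]] <- data.frame(
            participant = p, speed = speed, trial = tr, model = cm,
            mass = mass[p], height = height[p],
            method2_cost = cmp$method2_cost, method3_cost = cmp$method3_cost,
            percent_error_method2 = cmp$percent_error_method2,
            max_abs_percent_error_method1 = max(abs(cmp$percent_errors_method1)),
            min_abs_percent_error_method1 = min(abs(cmp$percent_errors_method1)),
            method2_below = cmp$method2_cost < cmp$method3_cost)
        }
        if (verbose)
          message(sprintf("participant %d speed %.1f done", p, speed))
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  paired <- list(); regression <- list(); sign_agreement <- list()
  for (cm in layout$cost_models) {
    r <- results[results$model == cm, ]
    by_speed <- lapply(split(r, r$speed), function(g)
      paired_comparison(g$method2_cost, g$method3_cost))
    pooled <- paired_comparison(r$method2_cost, r$method3_cost)
    paired[[cm]] <- list(by_speed = by_speed, pooled = pooled)
    sign_agreement[[cm]] <- sum(r$method2_below)
    m1err <- unlist(lapply(comps[results$model == cm],
                           `[[`, "percent_errors_method1"))
    m1speed <- rep(r$speed, each = layout$n_strides)
    regression[[cm]] <- if (length(unique(r$speed)) >= 2) list(
      method2 = speed_regression(r$percent_error_method2, r$speed),
      method1 = speed_regression(abs(m1err), m1speed)) else NULL
  }
  structure(list(results = results, comparisons = comps, paired = paired,
                 regression = regression, sign_agreement = sign_agreement,
                 layout = layout, variability = variability,
                 mass = mass, height = height),
            class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  n_trials <- nrow(x$results) / length(x$layout$cost_models)
  cat(sprintf("<gait_experiment> %d trials (%d participants x %d speeds), models: %s\n",
              n_trials, x$layout$n_participants, length(x$layout$speeds),
              paste(x$layout$cost_models, collapse = ", ")))
  for (cm in x$layout$cost_models) {
    pl <- x$paired[[cm]]$pooled
    cat(sprintf("  %s: method 2 vs 3 pooled %+0.2f +/- %0.2f %% (p = %.3g), method 2 lower in %d/%d trials\n",
                cm, pl$mean_percent, pl$se_percent, pl$p,
                x$sign_agreement[[cm]], n_trials))
    for (sp in names(x$paired[[cm]]$by_speed)) {
      b <- x$paired[[cm]]$by_speed[[sp]]
      cat(sprintf("    %s m/s: %+0.2f +/- %0.2f %% (p = %.3g)\n",
                  sp, b$mean_percent, b$se_percent, b$p))
    }
  }
  invisible(x)
}

#' Write experiment outputs to files
#'
#' Writes the per-trial results table (CSV), a JSON summary of the paired
#' tests, sign agreement and regressions, and a short markdown report.
#'
#' @param x a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(x, dir) {
  stopifnot(inherits(x, "gait_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$results, file.path(dir, "results.csv"), row.names = FALSE)
  summ <- list(
    layout = unclass(x$layout),
    sign_agreement = x$sign_agreement,
    paired = lapply(x$paired, function(pp) list(
      pooled = pp$pooled[c("n", "mean_percent", "se_percent", "p")],
      by_speed = lapply(pp$by_speed, `[`,
                        c("n", "mean_percent", "se_percent", "p")))),
    regression = lapply(x$regression, function(rg) list(
      method2 = rg$method2[c("slope", "se", "p")],
      method1 = rg$method1[c("slope", "se", "p")])))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Synthetic stride-variability experiment", "",
          sprintf("- master seed: %d", x$layout$master_seed),
          sprintf("- trials: %d", nrow(x$results) /
                    length(x$layout$cost_models)))
  for (cm in x$layout$cost_models) {
    pl <- x$paired[[cm]]$pooled
    md <- c(md, sprintf("- %s: pooled method2-method3 %+0.2f +/- %0.2f %% (p = %.3g); method 2 lower in %d trials",
                        cm, pl$mean_percent, pl$se_percent, pl$p,
                        x$sign_agreement[[cm]]))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
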