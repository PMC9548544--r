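#' Dose-finding scenario for a typical patient
#'
#' Describes the virtual patient (renal function, body weight, mannitol
#' co-medication) and the simulation settings used for Monte Carlo
#' AUC24-targeted dose selection. Defaults follow the simulation
#' conventions of the analysis: 12-h dosing interval, 1-h infusion, 1000
#' replicates per regimen, 5-mg dose grid.
#'
#' @param egfr eGFR, mL/min.
#' @param wt body weight, kg.
#' @param mannitol logical, mannitol co-medication.
#' @param interval dosing interval, h.
#' @param infusion_duration infusion time, h (must be below `interval`).
#' @param n_sim Monte Carlo replicates.
#' @param seed integer seed.
#' @param dose_grid_step dose grid resolution, mg.
#' @param target_auc target steady-state AUC24, h.mg/L (400 or 600 for the
#'   usual efficacy window).
#' @param high_dose_threshold per-administration dose above which the
#'   recommendation carries an advisory that a low-dose intraventricular
#'   regimen (10-20 mg every 24 h) should be considered instead of
#'   escalating the intravenous dose.
#' @return object of class `dose_scenario`.
#' @export
dose_scenario <- function(egfr, wt, mannitol, interval = 12,
                          infusion_duration = 1, n_sim = 1000, seed = 1,
                          dose_grid_step = 5, target_auc = 400,
                          high_dose_threshold = 2000) {
  stopifnot(egfr > 0, wt > 0, interval > infusion_duration,
            target_auc > 0, n_sim >= 1, dose_grid_step > 0)
  structure(list(egfr = egfr, wt = wt, mannitol = isTRUE(mannitol),
                 interval = interval,
                 infusion_duration = infusion_duration, n_sim = n_sim,
                 seed = seed, dose_grid_step = dose_grid_step,
                 target_auc = target_auc,
                 high_dose_threshold = high_dose_threshold),
            class = "dose_scenario")
}

scenario_cl <- function(scenario, theta) {
  typical_cl(theta, data.frame(egfr = scenario$egfr, wt = scenario$wt,
                               mannitol = scenario$mannitol))
}

#' Monte Carlo distribution of steady-state AUC24 for one dose
#'
#' Draws `n_sim` individual clearances \eqn{CL_i = CL_{typ} e^{\eta_i}},
#' \eqn{\eta_i \sim N(0, \omega^2)}, and computes each subject's
#' steady-state AUC24 = daily dose / CL_i. Residual (assay) error is not
#' added: AUC is a model quantity that depends on clearance only under
#' linear kinetics.
#'
#' @param scenario a [dose_scenario()].
#' @param dose mg per administration.
#' @param theta a [theta_vector()] (e.g. [theta_final()]).
#' @param omega_cl SD of the clearance random effect.
#' @return list: `median`, `lo5`, `hi95` (90% interval), `draws`.
#' @export
simulate_auc24 <- function(scenario, dose, theta, omega_cl) {
  stopifnot(inherits(scenario, "dose_scenario"), dose > 0, omega_cl >= 0)
  cl_typ <- scenario_cl(scenario, theta)
  daily <- dose * 24 / scenario$interval
  draws <- with_preserved_seed(scenario$seed, {
    eta <- rnorm(scenario$n_sim, 0, omega_cl)
    auc24_steady_state(daily, individual_cl(cl_typ, eta))
  })
  list(median = median(draws),
       lo5 = unname(quantile(draws, 0.05)),
       hi95 = unname(quantile(draws, 0.95)),
       draws = draws)
}

#' Recommend the per-administration dose for an AUC24 target
#'
#' Searches the dose grid for the dose whose simulated median AUC24 is
#' closest to the target (ties go to the smaller dose). Because AUC24 is
#' exactly linear in dose, the whole grid shares one set of random draws.
#' The advisory flag is set when the recommended dose exceeds the
#' high-dose threshold.
#'
#' @inheritParams simulate_auc24
#' @return object of class `dose_recommendation`: `dose`, `median_auc24`,
#'   `auc24_lo5`, `auc24_hi95`, `intraventricular_advisory`, plus the
#'   scenario.
#' @export
recommend_dose <- function(scenario, theta, omega_cl) {
  stopifnot(inherits(scenario, "dose_scenario"))
  cl_typ <- scenario_cl(scenario, theta)
  per_mg <- with_preserved_seed(scenario$seed, {
    eta <- rnorm(scenario$n_sim, 0, omega_cl)
    (24 / scenario$interval) / individual_cl(cl_typ, eta)
  })
  med_per_mg <- median(per_mg)
  step <- scenario$dose_grid_step
  grid <- seq(step, by = step,
              length.out = ceiling(2 * scenario$target_auc /
                                     (med_per_mg * step)))
  med <- grid * med_per_mg
  if (med[length(med)] < scenario$target_auc)
    stop(sprintf("dose grid cannot bracket the target; feasible median AUC24 up to %.1f",
                 med[length(med)]))
  best <- which.min(abs(med - scenario$target_auc))
  dose <- grid[best]
  structure(list(dose = dose, median_auc24 = med[best],
                 auc24_lo5 = dose * unname(quantile(per_mg, 0.05)),
                 auc24_hi95 = dose * unname(quantile(per_mg, 0.95)),
                 intraventricular_advisory =
                   dose > scenario$high_dose_threshold,
                 scenario = scenario),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "eGFR %g mL/min, BW %g kg, mannitol %s: %g mg every %g h (target AUC24 %g)\n",
    s$egfr, s$wt, if (s$mannitol) "yes" else "no", x$dose, s$interval,
    s$target_auc))
  cat(sprintf("  simulated AUC24 median %.2f (90%% interval %.2f-%.2f)\n",
              x$median_auc24, x$auc24_lo5, x$auc24_hi95))
  if (x$intraventricular_advisory)
    cat("  NOTE: high intravenous dose; consider a low-dose intraventricular regimen (10-20 mg q24h)\n")
  invisible(x)
}

#' Dose-recommendation table over a patient grid
#'
#' Evaluates [recommend_dose()] over the cross of eGFR, body weight,
#' mannitol status and AUC24 target, reproducing the familiar dose-table
#' layout. Each cell gets its own derived seed so the table is
#' reproducible cell by cell.
#'
#' @param theta a [theta_vector()].
#' @param omega_cl SD of the clearance random effect.
#' @param egfr,wt,mannitol,targets grid axes.
#' @param interval,n_sim,seed,dose_grid_step,high_dose_threshold passed to
#'   [dose_scenario()].
#' @return data frame, one row per grid cell: scenario columns, `dose`,
#'   `median_auc24`, `auc24_lo5`, `auc24_hi95`, `advisory`.
#' @export
build_dose_table <- function(theta, omega_cl,
                             egfr = c(90, 45, 15), wt = c(85, 65),
                             mannitol = c(TRUE, FALSE),
                             targets = c(400, 600), interval = 12,
                             n_sim = 1000, seed = 1, dose_grid_step = 5,
                             high_dose_threshold = 2000) {
  cells <- expand.grid(target = targets, mannitol = mannitol, wt = wt,
                       egfr = egfr)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ce <- cells[i, ]
    sc <- dose_scenario(ce$egfr, ce$wt, ce$mannitol, interval = interval,
                        n_sim = n_sim, seed = seed + i,
                        dose_grid_step = dose_grid_step,
                        target_auc = ce$target,
                        high_dose_threshold = high_dose_threshold)
    rec <- recommend_dose(sc, theta, omega_cl)
    data.frame(egfr = ce$egfr, wt = ce$wt, mannitol = ce$mannitol,
               interval = interval, target_auc = ce$target,
               dose = rec$dose, median_auc24 = rec$median_auc24,
               auc24_lo5 = rec$auc24_lo5, auc24_hi95 = rec$auc24_hi95,
               advisory = rec$intraventricular_advisory)
  })
  do.call(rbind, rows)
}
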