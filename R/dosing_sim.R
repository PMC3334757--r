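#' Dosing scenario definition
#'
#' A deterministic typical-subject scenario: covariates, a repeated-dose
#' regimen and an output grid.
#'
#' @param label scenario name.
#' @param covariates [subject_covariates()].
#' @param dose per-administration dose, mg (>= 0).
#' @param interval dosing interval, days (1 = once daily, 0.5 = twice
#'   daily).
#' @param duration treatment duration, days.
#' @param horizon simulation horizon, days (> 0).
#' @param dt output grid step, days (default hourly).
#' @return an object of class `acet_scenario`.
#' @export
scenario <- function(label, covariates = subject_covariates(),
                     dose = 500, interval = 1, duration = 5,
                     horizon = 5, dt = 1 / 24) {
  stopifnot(dose >= 0, horizon > 0, interval > 0, duration > 0, dt > 0)
  structure(list(label = label, covariates = covariates, dose = dose,
                 interval = interval, duration = duration,
                 horizon = horizon, dt = dt), class = "acet_scenario")
}

scenario_regimen <- function(sc) {
  if (sc$dose == 0) return(regimen(0, 0))
  bid_regimen(sc$dose, days = min(sc$duration, sc$horizon),
              interval = sc$interval)
}

#' Simulate typical-subject trajectories for a set of scenarios
#'
#' Fully deterministic: zero random effects and no residual noise; the
#' covariate submodel sets the typical baseline and elimination rate,
#' and the trajectory is solved on the scenario grid.
#'
#' @param theta [population_parameters()].
#' @param scenarios a list of [scenario()] objects.
#' @return list with `trajectories` (long data frame: `label`, `time`,
#'   `bicar`) and `summary` (per scenario: baseline, maximum decrease
#'   from baseline, time of nadir).
#' @export
simulate_scenarios <- function(theta, scenarios) {
  if (inherits(scenarios, "acet_scenario")) scenarios <- list(scenarios)
  kelim <- log(2) / theta$half_life
  traj <- list(); summ <- list()
  for (sc in scenarios) {
    b0 <- typical_bicar0(theta, sc$covariates)
    ko <- typical_kout(theta, sc$covariates)
    reg <- scenario_regimen(sc)
    tt <- seq(0, sc$horizon, by = sc$dt)
    bb <- traj_fast(tt, reg, b0, ko, theta$a50, theta$e_max, kelim)
    traj[[sc$label]] <- data.frame(label = sc$label, time = tt, bicar = bb)
    nad <- which.min(bb)
    summ[[sc$label]] <- data.frame(label = sc$label, bicar0 = b0,
                                   max_decrease = b0 - bb[nad],
                                   t_nadir = tt[nad])
  }
  list(trajectories = do.call(rbind, c(traj, make.row.names = FALSE)),
       summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

#' Typical-subject 24-hour dose-response table
#'
#' Change from baseline at 24 h per total daily dose, with the daily
#' dose split over the study's administration schedule (twice daily by
#' default).  The change is strictly decreasing (more negative) in dose
#' and bounded below by `-bicar0/2` (with `e_max = 1` the elimination
#' rate can at most double).
#'
#' @param theta [population_parameters()].
#' @param doses total daily doses, mg (>= 0).
#' @param cov [subject_covariates()].
#' @param doses_per_day administrations per day.
#' @return data frame with columns `daily_dose` and `delta_24h`
#'   (mmol/L).
#' @export
dose_response_24h <- function(theta, doses = c(0, 250, 500, 1000),
                              cov = subject_covariates(),
                              doses_per_day = 2) {
  stopifnot(all(doses >= 0))
  kelim <- log(2) / theta$half_life
  b0 <- typical_bicar0(theta, cov)
  ko <- typical_kout(theta, cov)
  delta <- vapply(doses, function(D) {
    reg <- if (D == 0) regimen(numeric(0), numeric(0)) else
      bid_regimen(D / doses_per_day, days = 1, interval = 1 / doses_per_day)
    traj_fast(1, reg, b0, ko, theta$a50, theta$e_max, kelim) - b0
  }, 1.0)
  data.frame(daily_dose = doses, delta_24h = delta)
}

#' Headline dosing conclusion check
#'
#' Evaluates, for a set of covariate scenarios (reference, high and low
#' serum chloride, furosemide coprescription, systemic corticosteroids)
#' and a menu of per-administration doses given twice daily, the maximum
#' bicarbonate decrease achieved within the horizon and the smallest
#' menu dose achieving a decrease larger than `threshold` (default
#' 5 mmol/L).  The "high"/"low" chloride defaults are the extremes of
#' the study population (108 and 69 mmol/L), as no specific values were
#' reported for the published scenario curves.
#'
#' @param theta [population_parameters()].
#' @param dose_menu per-administration doses, mg.
#' @param doses_per_day administrations per day (default 2, i.e. BID).
#' @param high_chloride,low_chloride chloride scenario values, mmol/L.
#' @param furosemide furosemide scenario dose, mg/day.
#' @param horizon days of treatment and observation.
#' @param threshold target decrease, mmol/L.
#' @return data frame of class `acet_headline`: one row per scenario and
#'   dose with `scenario`, `dose`, `daily_dose`, `max_decrease`,
#'   `achieves_target`; the per-scenario smallest achieving dose is in
#'   attribute `"first_achieving"`.
#' @export
headline_check <- function(theta, dose_menu = c(125, 250, 500, 1000),
                           doses_per_day = 2, high_chloride = 108,
                           low_chloride = 69, furosemide = 160,
                           horizon = 5, threshold = 5) {
  scen_cov <- list(
    reference = subject_covariates(),
    high_chloride = subject_covariates(chloride = high_chloride),
    low_chloride = subject_covariates(chloride = low_chloride),
    furosemide = subject_covariates(furosemide_dose = furosemide),
    corticosteroids = subject_covariates(corticosteroids = TRUE))
  rows <- list()
  for (nm in names(scen_cov)) {
    for (D in dose_menu) {
      sc <- scenario(paste0(nm, "_", D), scen_cov[[nm]], dose = D,
                     interval = 1 / doses_per_day, duration = horizon,
                     horizon = horizon)
      sm <- simulate_scenarios(theta, sc)$summary
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = nm, dose = D,
                   daily_dose = D * doses_per_day,
                   max_decrease = sm$max_decrease,
                   achieves_target = sm$max_decrease > threshold)
    }
  }
  out <- do.call(rbind, rows)
  first <- aggregate(dose ~ scenario, data = out[out$achieves_target, ,
                                                 drop = FALSE], FUN = min)
  names(first)[2] <- "first_achieving_dose"
  attr(out, "first_achieving") <- first
  attr(out, "threshold") <- threshold
  class(out) <- c("acet_headline", "data.frame")
  out
}

#' @export
print.acet_headline <- function(x, ...) {
  cat("Dosing headline check (target decrease >",
      attr(x, "threshold"), "mmol/L)\n")
  print(as.data.frame(x))
  cat("\nSmallest per-administration dose achieving the target:\n")
  print(attr(x, "first_achieving"))
  invisible(x)
}
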