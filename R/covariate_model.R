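#' Population parameters of the final acetazolamide model
#'
#' Fixed effects, variance components and fixed constants of the final
#' covariate model.  Defaults are the published estimates: baseline
#' bicarbonate is standardized to a SAPS II of 50 and a serum chloride
#' of 100 mmol/L,
#' `Bicar0 = tv_bicar0 * (SAPSII/50)^beta_saps * (chloride/100)^beta_chloride * theta_cort^[steroids]`,
#' and the elimination rate is attenuated by furosemide,
#' `kout = tv_kout * (1 - furo/(furo + fur50))`.  Between-subject
#' variability is exponential (log-normal) with standard deviations
#' `omega_*`; residual error is proportional with standard deviation
#' `sigma_prop` (4% coefficient of variation by default).
#'
#' @param tv_bicar0 typical baseline bicarbonate, mmol/L.
#' @param beta_saps power exponent of `(SAPSII/50)` on baseline.
#' @param beta_chloride power exponent of `(chloride/100)` on baseline.
#' @param theta_cort multiplicative baseline effect of concomitant
#'   glucocorticoids.
#' @param tv_kout typical bicarbonate elimination rate, 1/day.
#' @param fur50 daily furosemide dose halving `kout`, mg/day.
#' @param a50 drug amount of half-maximal stimulation, mg.
#' @param e_max maximal fractional stimulation (fixed at 1).
#' @param half_life drug elimination half-life, days (fixed at 0.25).
#' @param omega_bicar0,omega_kout SDs of the log-scale random effects.
#' @param sigma_prop SD of the proportional residual error.
#' @param sigma_add SD of an optional additive residual component,
#'   mmol/L (default 0, i.e. absent, as in the final model).
#' @return an object of class `acet_params`.
#' @examples
#' theta <- population_parameters()
#' theta$tv_bicar0 * theta$tv_kout # equilibrium formation rate, mmol/L/day
#' @export
population_parameters <- function(tv_bicar0 = 35.5,
                                  beta_saps = -0.112,
                                  beta_chloride = -1.18,
                                  theta_cort = 1.092,
                                  tv_kout = 0.395,
                                  fur50 = 187,
                                  a50 = 117,
                                  e_max = 1,
                                  half_life = 0.25,
                                  omega_bicar0 = 0.101,
                                  omega_kout = 0.792,
                                  sigma_prop = 0.04,
                                  sigma_add = 0) {
  stopifnot(tv_bicar0 > 0, tv_kout > 0, fur50 > 0, a50 > 0,
            theta_cort > 0, e_max >= 0, half_life > 0,
            omega_bicar0 >= 0, omega_kout >= 0, sigma_prop > 0,
            sigma_add >= 0)
  structure(list(tv_bicar0 = tv_bicar0, beta_saps = beta_saps,
                 beta_chloride = beta_chloride, theta_cort = theta_cort,
                 tv_kout = tv_kout, fur50 = fur50, a50 = a50,
                 e_max = e_max, half_life = half_life,
                 omega_bicar0 = omega_bicar0, omega_kout = omega_kout,
                 sigma_prop = sigma_prop, sigma_add = sigma_add),
            class = "acet_params")
}

#' @export
print.acet_params <- function(x, ...) {
  cat("Population parameters (acetazolamide bicarbonate model)\n")
  cat(sprintf("  baseline:    tv_bicar0 %.3g mmol/L, SAPS II exp %.3g, ",
              x$tv_bicar0, x$beta_saps))
  cat(sprintf("chloride exp %.3g, steroid x%.3g\n", x$beta_chloride,
              x$theta_cort))
  cat(sprintf("  elimination: tv_kout %.3g /day, Fur50 %.3g mg/day\n",
              x$tv_kout, x$fur50))
  cat(sprintf("  drug effect: e_max %.3g (fixed), a50 %.3g mg, half-life %.3g day\n",
              x$e_max, x$a50, x$half_life))
  cat(sprintf("  variability: omega_bicar0 %.3g, omega_kout %.3g, sigma_prop %.3g\n",
              x$omega_bicar0, x$omega_kout, x$sigma_prop))
  invisible(x)
}

#' Subject covariates entering the final model
#'
#' @param saps2 SAPS II severity score at ICU admission (> 0).
#' @param chloride serum chloride, mmol/L (> 0).
#' @param corticosteroids logical, concomitant glucocorticoids.
#' @param furosemide_dose daily furosemide dose, mg/day (>= 0; 0 when
#'   not coprescribed).
#' @return an object of class `acet_covariates`.
#' @export
subject_covariates <- function(saps2 = 50, chloride = 100,
                               corticosteroids = FALSE,
                               furosemide_dose = 0) {
  if (saps2 <= 0) stop("saps2 must be positive")
  if (chloride <= 0) stop("chloride must be positive")
  if (furosemide_dose < 0) stop("furosemide_dose must be non-negative")
  structure(list(saps2 = saps2, chloride = chloride,
                 corticosteroids = isTRUE(corticosteroids) ||
                   (is.numeric(corticosteroids) && corticosteroids > 0),
                 furosemide_dose = furosemide_dose),
            class = "acet_covariates")
}

#' Typical (covariate-adjusted) baseline bicarbonate
#'
#' @param theta [population_parameters()].
#' @param cov [subject_covariates()].
#' @return typical baseline bicarbonate, mmol/L.
#' @examples
#' typical_bicar0(population_parameters(), subject_covariates()) # 35.5
#' @export
typical_bicar0 <- function(theta, cov) {
  if (cov$saps2 <= 0 || cov$chloride <= 0)
    stop("saps2 and chloride must be positive")
  theta$tv_bicar0 * (cov$saps2 / 50)^theta$beta_saps *
    (cov$chloride / 100)^theta$beta_chloride *
    (if (cov$corticosteroids) theta$theta_cort else 1)
}

#' Typical (covariate-adjusted) bicarbonate elimination rate
#'
#' Furosemide competes with the drug's alkalosis correction: its daily
#' dose attenuates `kout` through an Imax-type term with `fur50` the dose
#' producing a 50% decrease.
#'
#' @inheritParams typical_bicar0
#' @return typical elimination rate, 1/day.
#' @examples
#' typical_kout(population_parameters(), subject_covariates()) # 0.395
#' @export
typical_kout <- function(theta, cov) {
  if (cov$furosemide_dose < 0) stop("furosemide_dose must be non-negative")
  theta$tv_kout *
    (1 - cov$furosemide_dose / (cov$furosemide_dose + theta$fur50))
}

#' Realized individual turnover parameters
#'
#' Applies exponential between-subject variability to the typical
#' covariate-adjusted values: `bicar0_i = typical * exp(eta_bicar0)`,
#' `kout_i = typical * exp(eta_kout)`, and the formation rate follows
#' from the equilibrium, `kin_i = bicar0_i * kout_i`.
#'
#' @inheritParams typical_bicar0
#' @param eta list or named vector with `eta_bicar0`, `eta_kout`.
#' @return list with `bicar0_i`, `kout_i`, `kin_i`.
#' @export
individual_params <- function(theta, cov,
                              eta = list(eta_bicar0 = 0, eta_kout = 0)) {
  e1 <- eta[["eta_bicar0"]]; e2 <- eta[["eta_kout"]]
  stopifnot(is.finite(e1), is.finite(e2))
  b0 <- typical_bicar0(theta, cov) * exp(e1)
  ko <- typical_kout(theta, cov) * exp(e2)
  list(bicar0_i = b0, kout_i = ko, kin_i = b0 * ko)
}

#' Sample between-subject random effects
#'
#' Independent zero-mean normal draws on the log scale with the
#' population SDs `omega_bicar0`, `omega_kout`.  Uses the current R
#' random-number stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param theta [population_parameters()].
#' @param n number of subjects.
#' @return `data.frame` with columns `eta_bicar0`, `eta_kout`.
#' @export
sample_etas <- function(theta, n) {
  stopifnot(n >= 1)
  data.frame(eta_bicar0 = rnorm(n, 0, theta$omega_bicar0),
             eta_kout = rnorm(n, 0, theta$omega_kout))
}
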