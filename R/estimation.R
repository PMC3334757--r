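# Estimated-parameter bookkeeping: order matches the C++ engine.
est_par_names <- c("tv_bicar0", "beta_saps", "beta_chloride",
                   "theta_cort", "tv_kout", "fur50", "a50",
                   "omega_bicar0", "omega_kout", "sigma_prop")
log_scale_pars <- setdiff(est_par_names, c("beta_saps", "beta_chloride"))

theta_to_vec <- function(theta) {
  vapply(est_par_names, function(k) theta[[k]], 1.0)
}
vec_to_theta <- function(v, theta) {
  args <- as.list(unclass(theta))
  args[est_par_names] <- as.list(unname(v))
  do.call(population_parameters, args)
}
to_trans <- function(v) {
  i <- est_par_names %in% log_scale_pars
  v[i] <- log(v[i])
  v
}
from_trans <- function(u) {
  i <- est_par_names %in% log_scale_pars
  u[i] <- exp(u[i])
  u
}

build_subjects <- function(ds) {
  validate_dataset(ds)
  lapply(split(seq_len(nrow(ds)), ds$ID), function(idx) {
    sub <- ds[idx, ]
    obs <- sub[sub$EVID == 0, ]
    dose <- sub[sub$EVID == 1, ]
    list(tobs = obs$TIME, y = obs$DV, dt = dose$TIME, da = dose$AMT,
         saps2 = sub$SAPS2[1], chloride = sub$CHLORIDE[1],
         cort = as.integer(sub$CORT[1] > 0), furo = sub$FURO[1])
  })
}

#' Estimation settings for the mixed-effects fit
#'
#' @param algorithm `"agq"` (nested deterministic quadrature: a dense
#'   prior-scaled grid over the elimination-rate random effect, whose
#'   conditional posterior can be strongly non-Gaussian because the
#'   bounded Emax effect creates likelihood plateaus, nested with
#'   mode-centered Gauss-Hermite over the baseline random effect, which
#'   is conditionally well-behaved) or `"laplace"` (single-node inner
#'   quadrature; the outer grid is retained).
#' @param agq_nodes Gauss-Hermite nodes of the inner (baseline)
#'   quadrature.
#' @param grid_points number of outer grid points over the
#'   elimination-rate random effect.
#' @param grid_width half-width of the outer grid in prior standard
#'   deviations.
#' @param initial optional named list of initial values overriding the
#'   data-driven defaults.
#' @param fixed named list of parameters held fixed at the given values
#'   (e.g. `list(beta_saps = 0)` removes the SAPS II effect).  `e_max`
#'   and the drug half-life are always fixed, as in the final model.
#' @param max_iter,max_eval optimizer budgets.
#' @param rel_tol optimizer relative convergence tolerance.
#' @param compute_se compute standard errors from the numerical observed
#'   information at the optimum (adds a Hessian evaluation).
#' @param hmax maximum quadrature sub-interval (days) of the trajectory
#'   engine.
#' @return an object of class `acet_fit_settings`.
#' @export
fit_settings <- function(algorithm = c("agq", "laplace"), agq_nodes = 9,
                         grid_points = 120, grid_width = 7.5,
                         initial = NULL, fixed = list(),
                         max_iter = 500, max_eval = 2000,
                         rel_tol = 1e-9, compute_se = TRUE, hmax = 0.5) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "laplace") agq_nodes <- 1L
  stopifnot(agq_nodes >= 1, grid_points >= 10, grid_width > 0,
            max_iter >= 1, max_eval >= 1)
  bad <- setdiff(names(fixed), est_par_names)
  if (length(bad)) stop("unknown fixed parameter(s): ",
                        paste(bad, collapse = ", "))
  structure(list(algorithm = algorithm, agq_nodes = as.integer(agq_nodes),
                 grid_points = as.integer(grid_points),
                 grid_width = grid_width,
                 initial = initial, fixed = fixed, max_iter = max_iter,
                 max_eval = max_eval, rel_tol = rel_tol,
                 compute_se = compute_se, hmax = hmax),
            class = "acet_fit_settings")
}

#' Marginal log-likelihood of the population model
#'
#' Per-subject marginal likelihood integrating the two random effects
#' (baseline, elimination rate) over their normal distribution, summed
#' on the log scale over subjects.  The trajectory is exactly linear in
#' the baseline, so the elimination-rate effect is integrated on a
#' dense deterministic prior-scaled grid (one trajectory evaluation per
#' grid point) and the baseline effect by mode-centered Gauss-Hermite
#' quadrature with analytic derivatives; see [fit_settings()].  The
#' computation is deterministic.  When both `omega` values are zero the
#' integral degenerates to the residual-error density at the typical
#' predictions.
#'
#' @param ds an `acet_dataset`.
#' @param theta [population_parameters()].
#' @param settings [fit_settings()].
#' @return the marginal log-likelihood, with the matrix of per-subject
#'   conditional modes attached as attribute `"etas"`.
#' @export
log_marginal_likelihood <- function(ds, theta,
                                    settings = fit_settings()) {
  subjects <- build_subjects(ds)
  ll_subjects(subjects, theta, settings)
}

ll_subjects <- function(subjects, theta, settings) {
  kelim <- log(2) / theta$half_life
  if (theta$omega_bicar0 == 0 && theta$omega_kout == 0) {
    ll <- 0
    etas <- matrix(0, length(subjects), 2)
    for (s in subjects) {
      cov_s <- subject_covariates(s$saps2, s$chloride, s$cort == 1, s$furo)
      f <- cpp_trajectory(s$tobs, s$dt, s$da, typical_bicar0(theta, cov_s),
                          typical_kout(theta, cov_s), theta$a50,
                          theta$e_max, kelim, settings$hmax)
      ll <- ll + sum(dnorm(s$y, f, theta$sigma_prop * f, log = TRUE))
    }
    return(structure(ll, etas = etas))
  }
  if (theta$omega_bicar0 == 0 || theta$omega_kout == 0)
    stop("omega values must be both zero or both positive")
  gh <- gauss_hermite(settings$agq_nodes)
  res <- cpp_marginal_ll(subjects, theta_to_vec(theta), theta$e_max,
                         kelim, gh$nodes, gh$weights,
                         settings$grid_points, settings$grid_width,
                         settings$hmax)
  structure(res$loglik, etas = res$etas)
}

default_initials <- function(ds) {
  obs <- ds[ds$EVID == 0, ]
  pre <- obs[obs$TIME == 0, ]
  b0 <- if (nrow(pre)) mean(pre$DV) else mean(obs$DV)
  doses <- ds$AMT[ds$EVID == 1]
  list(tv_bicar0 = b0, beta_saps = 0, beta_chloride = 0, theta_cort = 1,
       tv_kout = 0.5, fur50 = 100, a50 = median(doses) / 2,
       omega_bicar0 = 0.1, omega_kout = 0.1, sigma_prop = 0.1)
}

#' Fit the population model by maximum marginal likelihood
#'
#' Maximizes [log_marginal_likelihood()] over the non-fixed parameters
#' under positivity constraints (log-parameterization of positive
#' parameters; covariate exponents unconstrained).  `e_max` (1) and the
#' drug half-life (0.25 day) are always held fixed.  Initial values
#' default to data-driven choices: mean pre-dose observation for the
#' baseline, 0.5/day for the elimination rate, half the median
#' administered dose for `a50`.
#'
#' @param ds an `acet_dataset` with at least 2 subjects.
#' @param settings [fit_settings()].
#' @param theta0 optional [population_parameters()] template supplying
#'   the fixed constants (`e_max`, `half_life`).
#' @return an object of class `acet_fit` with elements `estimates`
#'   (an `acet_params`), `se`, `rse` (percent relative standard errors),
#'   `loglik`, `AIC`, `BIC`, `n_obs`, `n_subjects`, `n_par`, `etas`
#'   (empirical conditional modes), `shrinkage`, `convergence`,
#'   `settings`.
#' @export
fit_nlme <- function(ds, settings = fit_settings(), theta0 = NULL) {
  subjects <- build_subjects(ds)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  template <- theta0 %||% population_parameters()
  init <- default_initials(ds)
  if (!is.null(settings$initial)) init[names(settings$initial)] <- settings$initial
  init[names(settings$fixed)] <- settings$fixed
  full0 <- vapply(est_par_names, function(k) init[[k]], 1.0)
  free <- !(est_par_names %in% names(settings$fixed))
  u_full0 <- to_trans(full0)
  make_theta <- function(u_free) {
    u <- u_full0
    u[free] <- u_free
    vec_to_theta(from_trans(u), template)
  }
  neg_ll <- function(u_free) {
    th <- tryCatch(make_theta(u_free), error = function(e) NULL)
    if (is.null(th)) return(1e10)
    v <- tryCatch(
      suppressWarnings(as.numeric(ll_subjects(subjects, th, settings))),
      error = function(e) NA_real_)
    if (!is.finite(v)) return(1e10)
    -v
  }
  obj0 <- neg_ll(u_full0[free])
  opt <- nlminb(u_full0[free], neg_ll,
                control = list(iter.max = settings$max_iter,
                               eval.max = settings$max_eval,
                               rel.tol = settings$rel_tol))
  converged <- opt$convergence == 0
  # the optimizer must never do worse than its starting point
  if (opt$objective > obj0) {
    opt$par <- u_full0[free]
    opt$objective <- obj0
    converged <- FALSE
  }
  theta_hat <- make_theta(opt$par)
  llres <- ll_subjects(subjects, theta_hat, settings)
  ll <- as.numeric(llres)
  etas <- attr(llres, "etas")
  colnames(etas) <- c("eta_bicar0", "eta_kout")
  n_obs <- sum(ds$EVID == 0)
  p <- sum(free)
  est_vec <- theta_to_vec(theta_hat)
  se <- rse <- setNames(rep(NA_real_, length(est_par_names)), est_par_names)
  if (settings$compute_se && p > 0) {
    H <- tryCatch(fd_hessian(neg_ll, opt$par), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        d <- sqrt(pmax(diag(V), 0))
        # delta method back to the natural scale
        scale <- ifelse(est_par_names[free] %in% log_scale_pars,
                        abs(est_vec[free]), 1)
        se[free] <- d * scale
        rse[free] <- 100 * se[free] / abs(est_vec[free])
      }
    }
  }
  omegas <- c(eta_bicar0 = theta_hat$omega_bicar0,
              eta_kout = theta_hat$omega_kout)
  shr <- ifelse(omegas > 0, 1 - apply(etas, 2, sd) / omegas, NA_real_)
  fit <- structure(list(
    estimates = theta_hat, se = se, rse = rse, loglik = ll,
    AIC = -2 * ll + 2 * p, BIC = -2 * ll + p * log(n_obs),
    n_obs = n_obs, n_subjects = length(subjects), n_par = p,
    free = setNames(free, est_par_names), etas = as.data.frame(etas),
    shrinkage = shr,
    convergence = list(converged = converged, code = opt$convergence,
                       message = opt$message, iterations = opt$iterations,
                       evaluations = opt$evaluations),
    settings = settings), class = "acet_fit")
  if (!converged)
    warning("optimizer did not report clean convergence (code ",
            opt$convergence, "); partial results returned")
  fit
}

#' @export
print.acet_fit <- function(x, ...) {
  cat("Population model fit (", x$n_subjects, " subjects, ", x$n_obs,
      " observations)\n", sep = "")
  cat(sprintf("  log-likelihood %.2f | AIC %.1f | BIC %.1f | %d estimated parameters\n",
              x$loglik, x$AIC, x$BIC, x$n_par))
  est <- theta_to_vec(x$estimates)
  tab <- data.frame(estimate = signif(est, 4),
                    rse = ifelse(is.na(x$rse), "", sprintf("(%.0f%%)", x$rse)),
                    row.names = est_par_names)
  tab$fixed <- ifelse(x$free, "", "fixed")
  print(tab)
  cat(sprintf("  shrinkage: bicar0 %.2f, kout %.2f\n",
              x$shrinkage[1], x$shrinkage[2]))
  if (!x$convergence$converged) cat("  NOTE: convergence not clean\n")
  invisible(x)
}

#' Information criteria of a fit
#'
#' `AIC = -2 LL + 2 p` and `BIC = -2 LL + p log(n)` with `p` the number
#' of estimated parameters (fixed effects plus variance components) and
#' `n` the number of observations.
#'
#' @param fit an `acet_fit`.
#' @param n_ref reference sample size for BIC (defaults to the number of
#'   observations used in the fit).
#' @return named vector `c(AIC=, BIC=)`.
#' @export
information_criteria <- function(fit, n_ref = fit$n_obs) {
  p <- fit$n_par
  c(AIC = -2 * fit$loglik + 2 * p,
    BIC = -2 * fit$loglik + p * log(n_ref))
}

#' Likelihood ratio test between nested fits
#'
#' @param fit_full,fit_reduced `acet_fit` objects; the reduced model's
#'   free parameters must be a strict subset of the full model's.
#' @return list with `statistic` (2 * delta log-likelihood), `df` and
#'   `p.value` from the chi-square reference distribution.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  free_f <- names(which(fit_full$free))
  free_r <- names(which(fit_reduced$free))
  if (!all(free_r %in% free_f) || length(free_f) <= length(free_r))
    stop("models are not nested (reduced free parameters must be a ",
         "strict subset of the full model's)")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  df <- length(free_f) - length(free_r)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Forward-inclusion covariate scan
#'
#' Starting from the structural model without covariate effects, tests
#' each candidate effect by the likelihood ratio test and greedily adds
#' the most significant one until none reaches `alpha`.  Candidates are
#' named by the parameter carrying the effect: `beta_saps`,
#' `beta_chloride`, `theta_cort` (baseline pathways) and `fur50`
#' (elimination pathway; its null fixes the half-attenuation dose far
#' above any observed furosemide dose, i.e. no effect).
#'
#' @param ds an `acet_dataset`.
#' @param settings [fit_settings()].
#' @param candidates character vector of candidate effects.
#' @param alpha inclusion threshold (default 0.05).
#' @return list with `selected` (character vector in inclusion order),
#'   `steps` (data frame of tested effects and p-values per step) and
#'   `fit` (the final model fit).
#' @export
covariate_scan <- function(ds, settings = fit_settings(),
                           candidates = c("beta_saps", "beta_chloride",
                                          "theta_cort", "fur50"),
                           alpha = 0.05) {
  null_value <- c(beta_saps = 0, beta_chloride = 0, theta_cort = 1,
                  fur50 = 1e9)
  stopifnot(all(candidates %in% names(null_value)))
  fix_for <- function(excluded) {
    s <- settings
    s$fixed <- c(settings$fixed, as.list(null_value[excluded]))
    s$compute_se <- FALSE
    s
  }
  selected <- character(0)
  steps <- list()
  current <- fit_nlme(ds, fix_for(candidates))
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trial <- lapply(remaining, function(cand) {
      f <- fit_nlme(ds, fix_for(setdiff(remaining, cand)))
      list(cand = cand, fit = f,
           p = likelihood_ratio_test(f, current)$p.value)
    })
    pvals <- vapply(trial, `[[`, 1.0, "p")
    steps[[length(steps) + 1L]] <-
      data.frame(step = length(selected) + 1L, effect = remaining,
                 p.value = pvals)
    best <- which.min(pvals)
    if (pvals[best] >= alpha) break
    selected <- c(selected, remaining[best])
    current <- trial[[best]]$fit
  }
  list(selected = selected, steps = do.call(rbind, steps), fit = current)
}

#' Random-effect shrinkage of a fit
#'
#' `1 - sd(empirical eta)/omega` per random effect; high shrinkage means
#' the individual estimates are pulled to the population mean and carry
#' little subject-level information.
#'
#' @param fit an `acet_fit`.
#' @return named vector of shrinkage values; `NA` where `omega = 0`.
#' @export
shrinkage <- function(fit) {
  omegas <- c(eta_bicar0 = fit$estimates$omega_bicar0,
              eta_kout = fit$estimates$omega_kout)
  ifelse(omegas > 0, 1 - apply(as.matrix(fit$etas), 2, sd) / omegas,
         NA_real_)
}
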