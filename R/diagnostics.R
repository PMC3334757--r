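#' Normalized prediction distribution errors
#'
#' Simulates `K` full-model replicates of every subject's observation
#' vector at the observed design, decorrelates observed and simulated
#' vectors with the simulation-based mean and covariance (symmetric
#' matrix square root), and maps the rank of each decorrelated
#' observation among its decorrelated simulations through the standard
#' normal quantile function.  Ties are mid-ranked and the rank
#' proportion is clipped to `[1/(2K), 1 - 1/(2K)]` so the quantile is
#' always finite.  Under a correct model the NPDEs are approximately
#' iid standard normal.
#'
#' Per-subject simulation streams are derived from the seed and the
#' subject id, so the result is reproducible and invariant to the order
#' of subjects in the dataset.
#'
#' @param ds an `acet_dataset`.
#' @param theta [population_parameters()] to evaluate.
#' @param K number of Monte-Carlo replicates (default 500).
#' @param seed integer seed.
#' @param hmax trajectory engine sub-interval (days).
#' @return an object of class `acet_npde`: a data frame with columns
#'   `ID`, `TIME`, `DV`, `PRED` (simulation-based mean prediction) and
#'   `NPDE`, with attributes `K`, `seed` and `ridged` (number of
#'   subjects needing covariance ridging).
#' @export
compute_npde <- function(ds, theta, K = 500, seed = 1, hmax = 0.5) {
  stopifnot(K >= 2)
  subjects <- build_subjects(ds)
  kelim <- log(2) / theta$half_life
  ridged <- 0L
  ids <- names(subjects)
  out <- lapply(ids, function(id) {
    s <- subjects[[id]]
    m <- length(s$tobs)
    set.seed(derive_seed(seed, as.integer(as.numeric(id))))
    cov_s <- subject_covariates(s$saps2, s$chloride, s$cort == 1, s$furo)
    b0t <- typical_bicar0(theta, cov_s)
    kot <- typical_kout(theta, cov_s)
    e1 <- rnorm(K, 0, theta$omega_bicar0)
    e2 <- rnorm(K, 0, theta$omega_kout)
    fmat <- cpp_traj_matrix(s$tobs, s$dt, s$da, b0t * exp(e1),
                            kot * exp(e2), theta$a50, theta$e_max,
                            kelim, hmax)
    sims <- fmat * (1 + matrix(rnorm(K * m, 0, theta$sigma_prop), K, m))
    if (theta$sigma_add > 0)
      sims <- sims + matrix(rnorm(K * m, 0, theta$sigma_add), K, m)
    mu <- colMeans(sims)
    V <- cov(sims)
    eg <- eigen(V, symmetric = TRUE)
    if (any(eg$values < 1e-10 * max(eg$values))) {
      ridged <<- ridged + 1L
      warning("near-singular simulation covariance for subject ", id,
              "; ridge applied")
      V <- V + diag(1e-8 * mean(diag(V)), m)
      eg <- eigen(V, symmetric = TRUE)
    }
    Vinv_sqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
    ystar <- drop(Vinv_sqrt %*% (s$y - mu))
    simstar <- t(Vinv_sqrt %*% (t(sims) - mu))
    p <- vapply(seq_len(m), function(j) {
      (sum(simstar[, j] < ystar[j]) + 0.5 * sum(simstar[, j] == ystar[j])) / K
    }, 1.0)
    p <- pmin(pmax(p, 1 / (2 * K)), 1 - 1 / (2 * K))
    data.frame(ID = s_id_num(id), TIME = s$tobs, DV = s$y, PRED = mu,
               NPDE = qnorm(p))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$ID, res$TIME), ]
  rownames(res) <- NULL
  structure(res, K = K, seed = seed, ridged = ridged,
            class = c("acet_npde", "data.frame"))
}

s_id_num <- function(id) {
  v <- suppressWarnings(as.numeric(id))
  if (is.na(v)) id else v
}

#' Calibration tests of the NPDE distribution
#'
#' Under a correct model the NPDEs are standard normal: the mean is
#' tested against 0 by the Wilcoxon signed-rank test, the variance
#' against 1 by a chi-square variance test on `n - 1` degrees of freedom
#' (an F-form alternative is available), and normality by the
#' Shapiro-Wilk test (on a deterministic subsample when n exceeds the
#' test's 5000-value limit).
#'
#' @param res an `acet_npde` or a numeric vector of NPDE values
#'   (length >= 3).
#' @param variance_test `"chisq"` or `"F"`.
#' @return list with `p.mean`, `p.variance`, `p.normality`, the
#'   statistics, and `n`.
#' @export
npde_tests <- function(res, variance_test = c("chisq", "F")) {
  variance_test <- match.arg(variance_test)
  x <- if (inherits(res, "acet_npde")) res$NPDE else as.numeric(res)
  n <- length(x)
  if (n < 3) stop("need at least 3 NPDE values")
  if (sd(x) == 0) {
    warning("constant NPDE vector: degenerate distribution")
    return(list(p.mean = NA_real_, p.variance = 0, p.normality = 0,
                statistic.variance = 0, n = n, degenerate = TRUE))
  }
  p_mean <- wilcox.test(x, mu = 0, exact = FALSE)$p.value
  s2 <- var(x)
  if (variance_test == "chisq") {
    stat <- (n - 1) * s2 # / sigma0^2 = 1
    p_var <- 2 * min(pchisq(stat, n - 1), pchisq(stat, n - 1,
                                                 lower.tail = FALSE))
  } else {
    stat <- s2
    p_var <- 2 * min(stats::pf(stat, n - 1, 1e9),
                     stats::pf(stat, n - 1, 1e9, lower.tail = FALSE))
  }
  p_var <- min(p_var, 1)
  xs <- if (n > 5000) x[round(seq(1, n, length.out = 5000))] else x
  p_norm <- shapiro.test(xs)$p.value
  list(p.mean = p_mean, p.variance = p_var, p.normality = p_norm,
       statistic.variance = stat, n = n, degenerate = FALSE)
}

#' Global NPDE calibration decision
#'
#' Combines the three calibration tests with a Bonferroni correction:
#' the model is rejected when any single p-value falls below
#' `alpha / 3`.
#'
#' @param res as in [npde_tests()].
#' @param alpha overall level (default 0.05).
#' @return list with the three p-values, the Bonferroni-combined
#'   `p.global`, and logical `reject`.
#' @export
npde_global_test <- function(res, alpha = 0.05) {
  tst <- npde_tests(res)
  ps <- c(tst$p.mean, tst$p.variance, tst$p.normality)
  pg <- min(1, 3 * min(ps, na.rm = TRUE))
  list(p.mean = tst$p.mean, p.variance = tst$p.variance,
       p.normality = tst$p.normality, p.global = pg,
       reject = pg < alpha)
}

#' Population and individual goodness-of-fit predictions
#'
#' Population predictions use zero random effects (typical
#' covariate-adjusted parameters); individual predictions use the
#' subject's empirical conditional modes from the fit.  Both are model
#' trajectories evaluated at the observation times.
#'
#' @param fit an `acet_fit`.
#' @param ds the dataset the fit was obtained from.
#' @return data frame with columns `ID`, `TIME`, `DV`, `PRED`, `IPRED`.
#' @export
gof_predictions <- function(fit, ds) {
  subjects <- build_subjects(ds)
  theta <- fit$estimates
  kelim <- log(2) / theta$half_life
  stopifnot(nrow(fit$etas) == length(subjects))
  out <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    cov_s <- subject_covariates(s$saps2, s$chloride, s$cort == 1, s$furo)
    b0t <- typical_bicar0(theta, cov_s)
    kot <- typical_kout(theta, cov_s)
    pred <- cpp_trajectory(s$tobs, s$dt, s$da, b0t, kot, theta$a50,
                           theta$e_max, kelim, fit$settings$hmax)
    ipred <- cpp_trajectory(s$tobs, s$dt, s$da,
                            b0t * exp(fit$etas$eta_bicar0[i]),
                            kot * exp(fit$etas$eta_kout[i]),
                            theta$a50, theta$e_max, kelim,
                            fit$settings$hmax)
    data.frame(ID = s_id_num(names(subjects)[i]), TIME = s$tobs,
               DV = s$y, PRED = pred, IPRED = ipred)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$ID, res$TIME), ]
  rownames(res) <- NULL
  res
}
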