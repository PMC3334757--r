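theta <- table2_theta()

test_that("marginal likelihood degenerates to the typical-prediction density when BSV is zero", {
  th0 <- population_parameters(omega_bicar0 = 0, omega_kout = 0)
  ds <- generate_study(study_design(n_subjects = 4), th0, seed = 11)
  ll <- as.numeric(log_marginal_likelihood(ds, th0))
  pk <- pk_constants()
  manual <- 0
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    dose <- sub[sub$EVID == 1, ]
    cov_i <- subject_covariates(sub$SAPS2[1], sub$CHLORIDE[1],
                                sub$CORT[1] == 1, sub$FURO[1])
    f <- solve_bicarbonate(
      turnover_state(typical_bicar0(th0, cov_i), typical_kout(th0, cov_i)),
      effect_parameters(), regimen(dose$TIME, dose$AMT), pk, obs$TIME,
      tol = 1e-10)
    manual <- manual + sum(dnorm(obs$DV, f, th0$sigma_prop * f,
                                 log = TRUE))
  }
  expect_equal(ll, manual, tolerance = 1e-7)
})

test_that("marginal likelihood matches brute-force grid integration on small instances", {
  ds1 <- generate_study(study_design(n_subjects = 1), theta, seed = 21)
  expect_equal(as.numeric(log_marginal_likelihood(ds1, theta)),
               grid_marginal_ll(ds1, theta), tolerance = 1e-4)
  ds3 <- generate_study(study_design(n_subjects = 3), theta, seed = 22)
  expect_equal(as.numeric(log_marginal_likelihood(ds3, theta)),
               grid_marginal_ll(ds3, theta), tolerance = 1e-4)
})

test_that("likelihood is invariant to subject relabeling and joint time shifts", {
  ds <- generate_study(study_design(n_subjects = 6), theta, seed = 23)
  ll <- as.numeric(log_marginal_likelihood(ds, theta))
  # relabel subjects in reverse order
  perm <- ds
  perm$ID <- max(ds$ID) + 1 - perm$ID
  perm <- perm[order(perm$ID, perm$TIME, perm$EVID), ]
  expect_equal(as.numeric(log_marginal_likelihood(perm, theta)), ll,
               tolerance = 1e-10)
  # shift one subject's doses and observations together
  shifted <- ds
  shifted$TIME[shifted$ID == 2] <- shifted$TIME[shifted$ID == 2] + 1.5
  expect_equal(as.numeric(log_marginal_likelihood(shifted, theta)), ll,
               tolerance = 1e-6)
})

test_that("information criteria and the likelihood ratio test follow their definitions", {
  fake <- structure(list(loglik = -100, n_par = 5, n_obs = 100),
                    class = "acet_fit")
  expect_equal(unname(information_criteria(fake)["AIC"]), 210)
  expect_equal(unname(information_criteria(fake)["BIC"]),
               200 + 5 * log(100))
  fake0 <- structure(list(loglik = -100, n_par = 0, n_obs = 100),
                     class = "acet_fit")
  expect_equal(unname(information_criteria(fake0)), c(200, 200))
  free_full <- setNames(rep(FALSE, 10), acetapop:::est_par_names)
  free_red <- free_full
  free_full[c("tv_bicar0", "tv_kout", "beta_chloride")] <- TRUE
  free_red[c("tv_bicar0", "tv_kout")] <- TRUE
  f_full <- structure(list(loglik = -100, free = free_full),
                      class = "acet_fit")
  f_red0 <- structure(list(loglik = -100, free = free_red),
                      class = "acet_fit")
  expect_equal(likelihood_ratio_test(f_full, f_red0)$p.value, 1)
  f_red <- structure(list(loglik = -100 - 3.841459 / 2, free = free_red),
                     class = "acet_fit")
  lrt <- likelihood_ratio_test(f_full, f_red)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p.value, 0.05, tolerance = 1e-4)
  expect_error(likelihood_ratio_test(f_red, f_full), "nested")
})

test_that("shrinkage is one minus the empirical-to-population eta SD ratio", {
  mk <- function(etas, om1, om2) {
    structure(list(etas = as.data.frame(etas),
                   estimates = population_parameters(omega_bicar0 = om1,
                                                     omega_kout = om2)),
              class = "acet_fit")
  }
  e <- cbind(eta_bicar0 = c(-0.1, 0, 0.1), eta_kout = c(-0.4, 0, 0.4))
  f <- mk(e, sd(e[, 1]), 2 * sd(e[, 2]))
  expect_equal(unname(shrinkage(f)), c(0, 0.5), tolerance = 1e-12)
  f0 <- mk(cbind(eta_bicar0 = rep(0, 3), eta_kout = rep(0, 3)), 0.1, 0.2)
  expect_equal(unname(shrinkage(f0)), c(1, 1))
})

test_that("noise-free low-variability data identify the structural parameters to within 1%", {
  th0 <- population_parameters(omega_bicar0 = 1e-3, omega_kout = 1e-3,
                               sigma_prop = 1e-3)
  d <- study_design(n_subjects = 150,
                    obs_count_probs = c(0, 0, 0, 1, 0, 0))
  ds <- generate_study(d, th0, seed = 31)
  fit <- fit_nlme(ds, fit_settings(
    fixed = list(omega_bicar0 = 1e-3, omega_kout = 1e-3,
                 sigma_prop = 1e-3, beta_saps = -0.112,
                 beta_chloride = -1.18, theta_cort = 1.092,
                 fur50 = 187),
    compute_se = FALSE))
  expect_lt(abs(fit$estimates$tv_bicar0 / 35.5 - 1), 0.01)
  expect_lt(abs(fit$estimates$tv_kout / 0.395 - 1), 0.01)
  expect_lt(abs(fit$estimates$a50 / 117 - 1), 0.01)
})

test_that("the optimizer never returns a likelihood below its starting point", {
  ds <- generate_study(study_design(n_subjects = 10), theta, seed = 33)
  st <- fit_settings(compute_se = FALSE, max_iter = 2, max_eval = 10)
  fit <- suppressWarnings(fit_nlme(ds, st))
  init <- acetapop:::default_initials(ds)
  th_init <- do.call(population_parameters, init)
  ll0 <- as.numeric(log_marginal_likelihood(ds, th_init, st))
  expect_gte(fit$loglik, ll0 - 1e-8)
})

test_that("the covariate scan retains a strong true effect", {
  # chloride is the strongest baseline covariate; simulate with it only
  th <- population_parameters(beta_saps = 0, theta_cort = 1)
  d <- study_design(n_subjects = 60, p_furosemide = 0)
  ds <- generate_study(d, th, seed = 35)
  scan <- covariate_scan(ds, fit_settings(compute_se = FALSE),
                         candidates = c("beta_chloride", "theta_cort"))
  expect_true("beta_chloride" %in% scan$selected)
})
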