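# Shared fixtures and independent oracles used across the test files.

table2_theta <- function(...) population_parameters(...)

# random small iv regimen + output grid for property tests
random_instance <- function() {
  nd <- sample(1:6, 1)
  reg <- regimen(sort(runif(nd, 0, 2.5)), sample(c(125, 250, 500), nd,
                                                 replace = TRUE))
  times <- sort(c(0, runif(sample(3:8, 1), 0, 4)))
  st <- turnover_state(runif(1, 25, 45), runif(1, 0.15, 1.2))
  eff <- effect_parameters(e_max = 1, a50 = runif(1, 60, 250))
  list(reg = reg, times = times, st = st, eff = eff)
}

# Brute-force marginal log-likelihood by dense 2-D quadrature over the
# random effects (log-sum-exp over a rectangular grid on the prior
# scale).  Independent of the package's nested-quadrature integration;
# the trajectory engine itself is cross-validated elsewhere against
# solve_bicarbonate() and oracle_bicarbonate().
grid_marginal_ll <- function(ds, theta, n = 161, w = 8) {
  subs <- acetapop:::build_subjects(ds)
  kelim <- log(2) / theta$half_life
  tot <- 0
  for (s in subs) {
    cov_s <- subject_covariates(s$saps2, s$chloride, s$cort == 1, s$furo)
    b0t <- typical_bicar0(theta, cov_s)
    kot <- typical_kout(theta, cov_s)
    e1 <- seq(-w * theta$omega_bicar0, w * theta$omega_bicar0,
              length.out = n)
    e2 <- seq(-w * theta$omega_kout, w * theta$omega_kout, length.out = n)
    g <- expand.grid(e1 = e1, e2 = e2)
    f <- acetapop:::cpp_traj_matrix(s$tobs, s$dt, s$da, b0t * exp(g$e1),
                                    kot * exp(g$e2), theta$a50,
                                    theta$e_max, kelim, 0.5)
    ll <- rowSums(dnorm(matrix(s$y, nrow(f), ncol(f), byrow = TRUE), f,
                        theta$sigma_prop * f, log = TRUE))
    lw <- ll + dnorm(g$e1, 0, theta$omega_bicar0, log = TRUE) +
      dnorm(g$e2, 0, theta$omega_kout, log = TRUE)
    mx <- max(lw)
    tot <- tot + mx + log(sum(exp(lw - mx)) * diff(e1)[1] * diff(e2)[1])
  }
  tot
}
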