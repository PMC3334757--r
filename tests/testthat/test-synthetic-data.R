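theta <- table2_theta()

test_that("generated cohort matches the study design structure", {
  ds <- generate_study(study_design(), theta, seed = 1)
  expect_s3_class(ds, "acet_dataset")
  expect_equal(length(unique(ds$ID)), 68)
  counts <- as.vector(table(ds$ID[ds$EVID == 0]))
  expect_equal(median(counts), 3)
  expect_true(all(counts >= 1 & counts <= 6))
  # every subject dosed, first observation pre-dose at equilibrium
  expect_true(all(tapply(ds$EVID == 1, ds$ID, any)))
  expect_true(all(ds$TIME[ds$EVID == 0 & !duplicated(ds$ID)] == 0))
})

test_that("covariates respect truncation bounds for every seed and match the population medians", {
  d <- study_design()
  for (seed in 1:5) {
    set.seed(seed)
    cv <- draw_covariates(d, 500)
    expect_true(all(cv$saps2 >= 20 & cv$saps2 <= 95))
    expect_true(all(cv$chloride >= 69 & cv$chloride <= 108))
    expect_true(all(cv$furo == 0 | (cv$furo >= 20 & cv$furo <= 160)))
    expect_true(all(cv$cort %in% 0:1))
  }
  set.seed(42)
  cv <- draw_covariates(d, 1e4)
  expect_lt(abs(median(cv$saps2) / 47 - 1), 0.05)
  expect_lt(abs(median(cv$chloride) / 96 - 1), 0.05)
})

test_that("noise-free variability-free data reproduce the typical predictions exactly", {
  th0 <- population_parameters(omega_bicar0 = 0, omega_kout = 0,
                               sigma_prop = 1e-12)
  ds <- generate_study(study_design(n_subjects = 8), th0, seed = 3)
  pk <- pk_constants()
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
    expect_equal(obs$DV, f, tolerance = 1e-7)
    expect_equal(obs$DV[1], sub$TRUE_BICAR0[1], tolerance = 1e-7)
  }
})

test_that("generation is deterministic given a seed and both engines agree", {
  d <- study_design(n_subjects = 12)
  a <- generate_study(d, theta, seed = 99)
  b <- generate_study(d, theta, seed = 99)
  expect_identical(a, b)
  co <- generate_study(d, theta, seed = 99, engine = "ode")
  expect_equal(co$DV, a$DV, tolerance = 1e-7)
})

test_that("dataset CSV round-trips and the written file is byte-stable", {
  ds <- generate_study(study_design(n_subjects = 5), theta, seed = 4)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, p1)
  ds2 <- read_dataset(p1)
  expect_equal(as.data.frame(ds2), as.data.frame(ds), tolerance = 1e-12)
  write_dataset(generate_study(study_design(n_subjects = 5), theta,
                               seed = 4), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("reader flags malformed files with the offending row", {
  ds <- generate_study(study_design(n_subjects = 3), theta, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  # negative dose amount
  bad <- ds; bad$AMT[bad$EVID == 1][1] <- -100
  utils::write.csv(bad, path, row.names = FALSE, na = ".")
  expect_error(read_dataset(path), "invalid dose amount at row")
  # missing mandatory column
  utils::write.csv(ds[setdiff(names(ds), "CHLORIDE")], path,
                   row.names = FALSE, na = ".")
  expect_error(read_dataset(path), "CHLORIDE")
  # non-monotone times within subject
  bad2 <- ds
  bad2$TIME[3] <- 10 # later rows of subject 1 now precede this one
  utils::write.csv(bad2, path, row.names = FALSE, na = ".")
  expect_error(read_dataset(path), "non-monotone")
  # an observation before any dose is a legitimate baseline sample
  expect_silent(validate_ok <- {
    write_dataset(ds, path); read_dataset(path)
  })
})

test_that("24 h intra-patient differences summarize per dose group and reflect the dose-response", {
  # hand-built subject: predose 37.5, 24 h value 33.5 -> delta -4
  one <- data.frame(
    ID = 1, TIME = c(0, 0, 0.5, 1.02), EVID = c(0, 1, 1, 0),
    AMT = c(NA, 250, 250, NA), DV = c(37.5, NA, NA, 33.5),
    MDV = c(0, 1, 1, 0), SAPS2 = 50, CHLORIDE = 100, CORT = 0, FURO = 0)
  s <- delta_24h_summary(one)
  expect_equal(s$median, -4)
  expect_equal(s$daily_dose, 500)
  # noise-free zero-dose cohort: all differences 0
  th0 <- population_parameters(omega_bicar0 = 0, omega_kout = 0,
                               sigma_prop = 1e-12)
  d0 <- study_design(n_subjects = 20, dose_menu = 0,
                     obs_count_probs = c(0, 0, 0, 0, 0, 1),
                     obs_window = 1)
  ds0 <- generate_study(d0, th0, seed = 8)
  s0 <- suppressWarnings(delta_24h_summary(ds0, window = c(0.5, 1.5)))
  expect_true(all(abs(s0$median) < 1e-7))
  # dose-response: larger dose group has more negative median delta
  dd <- study_design(n_subjects = 120,
                     obs_count_probs = c(0, 0, 0, 0, 0, 1))
  dsd <- generate_study(dd, theta, seed = 9)
  sd_ <- suppressWarnings(delta_24h_summary(dsd, window = c(0.6, 1.4)))
  sd_ <- sd_[order(sd_$daily_dose), ]
  expect_gt(nrow(sd_), 1)
  expect_true(all(diff(sd_$median) < 0))
})
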