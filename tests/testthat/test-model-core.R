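test_that("iv bolus amount follows first-order superposition", {
  pk <- pk_constants() # half-life 0.25 day
  expect_equal(pk$half_life, 0.25)
  expect_equal(amount_iv(regimen(0, 500), 0, pk), 500)
  expect_equal(amount_iv(regimen(0, 500), 0.25, pk), 250)
  # two half-lives before the second dose, bolus jump at 0.5
  reg2 <- regimen(c(0, 0.5), 500)
  expect_equal(amount_iv(reg2, 0.5 - 1e-12, pk), 125, tolerance = 1e-9)
  expect_equal(amount_iv(reg2, 0.5, pk), 625)
  # superposition: merged regimen equals sum of parts
  rA <- regimen(c(0, 1), c(250, 500))
  rB <- regimen(c(0.3, 1.7), c(125, 250))
  merged <- regimen(c(rA$time, rB$time), c(rA$amount, rB$amount))
  tt <- seq(0, 3, by = 0.17)
  expect_equal(amount_iv(merged, tt, pk),
               amount_iv(rA, tt, pk) + amount_iv(rB, tt, pk))
  expect_error(amount_iv(regimen(0, 500), -1, pk), "non-negative")
  expect_error(regimen(0, -5), "non-negative")
})

test_that("oral amount has Bateman form with the right limits", {
  reg <- regimen(0, 500, route = "oral")
  pk <- pk_constants(k_a = 50)
  expect_equal(amount_oral(reg, 0, pk), 0) # absorption not started
  # k_a -> infinity approaches the iv solution
  pk_fast <- pk_constants(k_a = 1e6)
  tt <- c(0.1, 0.3, 0.8)
  expect_equal(amount_oral(reg, tt, pk_fast),
               amount_iv(regimen(0, 500), tt, pk_constants()),
               tolerance = 1e-3)
  # washout
  expect_lt(amount_oral(reg, 50, pk), 1e-8)
  # degenerate k_a = k_elim uses the t*exp(-kt) limit
  pk_eq <- pk_constants(k_a = log(2) / 0.25)
  expect_message(a <- amount_oral(reg, 0.25, pk_eq), "limiting")
  k <- log(2) / 0.25
  expect_equal(a, 500 * k * 0.25 * exp(-k * 0.25))
})

test_that("effect multiplier is a bounded increasing Emax curve", {
  eff <- effect_parameters(e_max = 1, a50 = 117)
  expect_equal(effect_multiplier(0, eff), 1)
  expect_equal(effect_multiplier(117, eff), 1.5)
  expect_equal(effect_multiplier(1e12, eff), 2, tolerance = 1e-9)
  amounts <- seq(0, 2000, by = 50)
  expect_true(all(diff(effect_multiplier(amounts, eff)) > 0))
  expect_error(effect_multiplier(-1, eff), "non-negative")
})

test_that("turnover solution stays at equilibrium without drug and finds the new steady state under constant stimulation", {
  st <- turnover_state(35.5, 0.395)
  expect_equal(st$k_in, 35.5 * 0.395)
  pk <- pk_constants()
  tt <- seq(0, 10, by = 0.5)
  none <- solve_bicarbonate(st, effect_parameters(), regimen(numeric(0),
                                                            numeric(0)),
                            pk, tt)
  expect_equal(none, rep(35.5, length(tt)), tolerance = 1e-8)
  # constant E = 2 forever: emulate with a50 -> 0 and a persistent amount
  eff0 <- effect_parameters(e_max = 1, a50 = 1e-9)
  slow_pk <- pk_constants(half_life = 1e6) # drug never washes out
  sol <- solve_bicarbonate(st, eff0, regimen(0, 500), slow_pk, tt)
  expect_true(all(diff(sol) < 1e-10))
  expect_equal(sol[length(sol)], 35.5 / 2, tolerance = 1e-3)
})

test_that("ODE solve, integrating-factor oracle and fast engine agree on randomized regimens", {
  set.seed(101)
  pk <- pk_constants()
  for (rep in 1:6) {
    inst <- random_instance()
    a <- solve_bicarbonate(inst$st, inst$eff, inst$reg, pk, inst$times,
                           tol = 1e-10)
    b <- oracle_bicarbonate(inst$st, inst$eff, inst$reg, pk, inst$times)
    cc <- acetapop:::traj_fast(inst$times, inst$reg, inst$st$bicar0,
                               inst$st$k_out, inst$eff$a50,
                               inst$eff$e_max, pk$k_elim)
    expect_lt(max(abs(a - b)), 1e-6)
    expect_lt(max(abs(cc - b)), 1e-6)
  }
})

test_that("trajectories respect the structural bounds and wash out to baseline", {
  pk <- pk_constants()
  st <- turnover_state(35.5, 0.395)
  eff <- effect_parameters()
  reg <- bid_regimen(1000, days = 3)
  tt <- seq(0, 30, by = 0.25)
  sol <- solve_bicarbonate(st, eff, reg, pk, tt)
  expect_true(all(sol >= st$bicar0 / 2 - 1e-9))
  expect_true(all(sol <= st$bicar0 + 1e-9))
  expect_gt(sol[length(sol)], 0.99 * st$bicar0) # washout recovery
})

test_that("bicarbonate response is monotone in dose", {
  pk <- pk_constants()
  st <- turnover_state(35.5, 0.395)
  eff <- effect_parameters()
  tt <- seq(0.25, 3, by = 0.25)
  sols <- lapply(c(125, 250, 500, 1000), function(d)
    solve_bicarbonate(st, eff, bid_regimen(d, 3), pk, tt))
  for (i in 2:4)
    expect_true(all(sols[[i]] < sols[[i - 1]]))
})

test_that("solver input validation catches malformed calls", {
  st <- turnover_state(35.5, 0.395)
  expect_error(solve_bicarbonate(st, effect_parameters(), regimen(0, 500),
                                 pk_constants(), c(1, 0.5)), "sorted")
  expect_error(oracle_bicarbonate(st, effect_parameters(),
                                  regimen(0, 500, route = "oral"),
                                  pk_constants(k_a = 10), 1), "iv")
  expect_error(turnover_state(-1, 0.4))
  expect_error(pk_constants(half_life = 0))
})
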