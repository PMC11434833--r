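test_that("rate constants follow from clearances and volumes", {
  p <- structural_params(V1 = 21.213, V2 = 5, Q = 23.833,
                         Cl1 = 38.739, Cl2 = 5.567)
  k <- rate_constants(p)
  expect_equal(unname(k["k10"]), 1.8262, tolerance = 1e-4)
  expect_equal(unname(k["k12"]), 1.1235, tolerance = 1e-4)
  expect_equal(unname(k["k21"]), 4.7666, tolerance = 1e-4)
  expect_equal(unname(k["k20"]), 1.1134, tolerance = 1e-4)
  ## inverse mapping reproduces clearances
  expect_equal(k[["k10"]] * p$V1, p$Cl1)
  expect_equal(k[["k12"]] * p$V1, k[["k21"]] * p$V2)
  expect_equal(k[["k20"]] * p$V2, p$Cl2)
  ## boundary cases
  expect_equal(unname(rate_constants(
    structural_params(1, 1, 1, 1, 0))["k20"]), 0)
  expect_equal(unname(rate_constants(structural_params(1, 1, 1, 1, 1))),
               rep(1, 4))
  expect_error(structural_params(-1, 5, 20, 10, 1), "positive")
  expect_error(structural_params(10, 0, 20, 10, 1), "positive")
})

test_that("simulated profiles match an independent adaptive-ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- structural_params(21.213, 5, 23.833, 38.739, 5.567)
  sch <- regimen_schedule(4000, 16000)
  times <- c(0.25, 0.5, 1, 2, 6, 12, 24, 48)
  pr <- simulate_profile(p, sch, times)
  oc <- odesolve_profile(p, sch, times)
  expect_equal(pr$C1, oc$C1, tolerance = 1e-6)
  expect_equal(pr$C2, oc$C2, tolerance = 1e-6)
  ## end-of-load plasma concentration is below the no-elimination bound
  expect_lt(pr$C1[pr$time == 0.5], 4000 / p$V1)
  ## random parameter sets
  for (rp in random_params(5, seed = 101)) {
    pr <- simulate_profile(rp, sch, times)
    oc <- odesolve_profile(rp, sch, times)
    expect_equal(pr$C1, oc$C1, tolerance = 1e-6)
    expect_equal(pr$C2, oc$C2, tolerance = 1e-6)
  }
})

test_that("empty schedule gives zero concentrations; inputs validated", {
  p <- structural_params(20, 5, 20, 10, 2)
  pr <- simulate_profile(p, dose_schedule(), c(0, 1, 10))
  expect_true(all(pr$C1 == 0) && all(pr$C2 == 0))
  expect_error(simulate_profile(p, regimen_schedule(4000, 16000),
                                c(2, 1)), "sorted")
  expect_error(simulate_profile(p, regimen_schedule(4000, 16000),
                                c(-1, 1)), "non-negative")
})

test_that("long-run simulation converges to the closed-form steady state", {
  sch <- regimen_schedule(4000, 16000)
  for (rp in random_params(8, seed = 7)) {
    ss <- steady_state(rp, 16000 / 24)
    pr <- simulate_profile(rp, sch, c(0, 2000))
    expect_equal(pr$C1[2], unname(ss["C1ss"]), tolerance = 1e-6)
    expect_equal(pr$C2[2], unname(ss["C2ss"]), tolerance = 1e-6)
    ## steady-state ratio identity
    expect_equal(ss[["C2ss"]] / ss[["C1ss"]], rp$Q / (rp$Q + rp$Cl2),
                 tolerance = 1e-12)
  }
})

test_that("steady state matches the reference parameter arithmetic", {
  pA <- structural_params(21.213, 5, 23.833, 38.739, 5.567)
  ss <- steady_state(pA, 16000 / 24)
  expect_equal(unname(ss["C1ss"]), 15.41, tolerance = 1e-3)
  expect_equal(unname(ss["C2ss"]), 12.50, tolerance = 1e-3)
  tA <- structural_params(23.248, 5, 20, 7.013, 3.003)
  st <- steady_state(tA, 2000 / 24)
  expect_equal(unname(st["C1ss"]), 8.66, tolerance = 1e-3)
  expect_equal(unname(st["C2ss"]), 7.53, tolerance = 1e-3)
  expect_equal(st[["C2ss"]] / st[["C1ss"]], 0.869, tolerance = 1e-3)
  ## no peritoneal loss: both compartments at rate/Cl1
  p0 <- structural_params(20, 5, 20, 10, 0)
  s0 <- steady_state(p0, 100)
  expect_equal(unname(s0["C1ss"]), 10)
  expect_equal(unname(s0["C2ss"]), 10)
})

test_that("mass balance and dose linearity hold", {
  p <- structural_params(25, 5, 20, 15, 3)
  k <- rate_constants(p)
  sch <- regimen_schedule(4000, 16000)
  tt <- seq(0, 48, by = 0.01)
  pr <- simulate_profile(p, sch, tt)
  input <- ifelse(tt <= 0.5, 8000 * tt, 4000 + (16000 / 24) * (tt - 0.5))
  elim_rate <- k[["k10"]] * pr$A1 + k[["k20"]] * pr$A2
  elim <- cumsum(c(0, diff(tt) * (head(elim_rate, -1) + tail(elim_rate, -1)) / 2))
  balance <- input - (pr$A1 + pr$A2) - elim
  expect_lt(max(abs(balance)) / max(input), 1e-5)
  ## doubling all rates doubles concentrations pointwise
  sch2 <- dose_schedule(sch$start, sch$duration, 2 * sch$rate)
  pr2 <- simulate_profile(p, sch2, c(0.25, 1, 7, 30))
  pr1 <- simulate_profile(p, sch, c(0.25, 1, 7, 30))
  expect_equal(pr2$C1, 2 * pr1$C1, tolerance = 1e-12)
  expect_equal(pr2$C2, 2 * pr1$C2, tolerance = 1e-12)
})
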