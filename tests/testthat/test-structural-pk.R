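# Structural depot-central-hair model: closed forms, ODE agreement,
# mass balance, steady-state superposition.

test_that("Bateman curve matches an independent ODE integration and its analytic limits", {
  reg <- dose_regimen(300, 24)
  p <- plasma_defaults("ATV")

  # independent oracle: integrate the absorption/elimination system with
  # deSolve directly (no package solver involved)
  rhs <- function(t, A, pars)
    list(c(-pars$k12 * A[1], pars$k12 * A[1] - pars$k20 * A[2]))
  sol <- deSolve::ode(c(A1 = 300, A2 = 0), times = c(0, 24), func = rhs,
                      parms = list(k12 = p$k12, k20 = p$k20),
                      rtol = 1e-12, atol = 1e-14)
  oracle_c24 <- unname(sol[2, "A2"]) / p$Vc
  expect_equal(bateman_concentration(24, reg, p), oracle_c24,
               tolerance = 1e-8)
  expect_equal(bateman_concentration(24, reg, p), 0.1672263,
               tolerance = 1e-6)

  # no drug absorbed at t = 0
  expect_identical(bateman_concentration(0, reg, p), 0)

  # analytic limit when absorption and elimination rates coincide
  pd <- plasma_params(k12 = 0.2, CL = 2, Vc = 10)   # k20 = 0.2 exactly
  t <- c(1, 5, 20)
  expect_equal(bateman_concentration(t, reg, pd),
               (300 / 10) * 0.2 * t * exp(-0.2 * t), tolerance = 1e-12)
  # continuity across the degenerate branch
  pe <- plasma_params(k12 = 0.2 + 1e-9, CL = 2, Vc = 10)
  expect_equal(bateman_concentration(t, reg, pe),
               bateman_concentration(t, reg, pd), tolerance = 1e-6)

  expect_error(plasma_params(k12 = -1, CL = 10, Vc = 60), "positive")
  expect_error(plasma_params(k12 = 0.4, CL = 0, Vc = 60), "positive")
  expect_error(bateman_concentration(-1, reg, p), ">= 0")
})

test_that("steady-state trough equals the multi-dose superposition limit", {
  reg <- dose_regimen(300, 24)
  atv <- plasma_defaults("ATV")
  rtv <- plasma_defaults("RTV")

  # brute-force oracle: superposition of 200 single-dose Bateman curves
  sup <- function(reg, p, n = 200)
    sum(bateman_concentration(reg$interval * seq_len(n), reg, p))
  expect_lt(abs(steady_state_trough(reg, atv) - sup(reg, atv)), 1e-8)
  expect_equal(steady_state_trough(reg, atv), 0.1711145, tolerance = 1e-6)

  reg_rtv <- dose_regimen(100, 24)
  expect_lt(abs(steady_state_trough(reg_rtv, rtv) - sup(reg_rtv, rtv)), 1e-8)
  expect_equal(steady_state_trough(reg_rtv, rtv), 0.05697342,
               tolerance = 1e-6)

  # linearity in dose
  expect_identical(steady_state_trough(dose_regimen(0, 24), atv), 0)

  # finite-dose superposition agrees with its own oracle
  reg5 <- dose_regimen(300, 24, n_doses = 5)
  expect_equal(steady_state_trough(reg5, atv), sup(reg5, atv, 5),
               tolerance = 1e-12)

  # monotonicity: increasing dose raises the trough, increasing CL lowers it
  troughs_d <- vapply(c(100, 200, 300, 400),
                      function(D) steady_state_trough(dose_regimen(D, 24), atv),
                      numeric(1))
  expect_true(all(diff(troughs_d) > 0))
  troughs_cl <- vapply(c(5, 10, 15, 20), function(CL)
    steady_state_trough(reg, plasma_params(0.44, CL, 63.4)), numeric(1))
  expect_true(all(diff(troughs_cl) < 0))

  # degenerate-rate steady state still matches superposition
  pd <- plasma_params(k12 = 0.2, CL = 2, Vc = 10)
  expect_lt(abs(steady_state_trough(reg, pd) - sup(reg, pd)), 1e-8)
})

test_that("compartment integration conserves mass and matches the closed form", {
  reg <- dose_regimen(300, 24)
  p <- plasma_defaults("ATV")
  h <- hair_params(frac = 0.16)
  grid <- seq(0, 240, by = 2)
  tr <- integrate_system(reg, p, h, grid, rtol = 1e-10, atol = 1e-12)

  # plasma solution vs closed form, sup-norm relative to the peak
  cf <- bateman_concentration(grid, reg, p)
  expect_lt(max(abs(tr$C2 - cf)) / max(cf), 1e-6)

  # mass balance: A3 = frac (D_tot - A1 - A2) at all times
  expect_lt(max(abs(tr$A3 - 0.16 * (300 - tr$A1 - tr$A2))), 1e-6)

  # all amounts non-negative, hair amount non-decreasing
  expect_true(all(tr$A1 >= -1e-8 & tr$A2 >= -1e-8 & tr$A3 >= -1e-8))
  expect_true(all(diff(tr$A3) >= -1e-10))

  # asymptotic hair amount = frac * dose
  tr_inf <- integrate_system(reg, p, h, c(0, 2000))
  expect_equal(tr_inf$A3[2], 0.16 * 300, tolerance = 1e-6)

  # zero fraction: nothing reaches the hair
  tr0 <- integrate_system(reg, p, hair_params(0), grid)
  expect_true(all(tr0$A3 == 0))

  # repeated dosing: mass balance against the cumulative dose
  # grid avoids the dose instants themselves (the solver reports the
  # pre-event state at an event time)
  reg3 <- dose_regimen(300, 24, n_doses = 3)
  tr3 <- integrate_system(reg3, p, h, c(0, seq(0.5, 96, by = 1)))
  d_tot <- 300 * pmin(3, floor(tr3$time / 24) + 1)
  expect_lt(max(abs(tr3$A3 - 0.16 * (d_tot - tr3$A1 - tr3$A2))), 1e-5)

  expect_error(integrate_system(reg, p, h, c(3, 1)), "sorted")
})

test_that("hair prediction is the fraction times the trough, scaled by hair volume", {
  expect_equal(predict_hair(0.16, 2.0), 0.32)
  expect_equal(predict_hair(0, 5), 0)
  expect_equal(predict_hair(0.16, 2.0, hair_params(0.16, Vh = 2)), 0.16)
  expect_error(predict_hair(-0.1, 1), ">= 0")
  expect_error(hair_params(0.1, Vh = 0), "Vh")
})
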