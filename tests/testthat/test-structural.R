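test_that("disposition constants satisfy the defining identities", {
  p <- structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
  d <- derive_disposition_constants(p)
  # direct arithmetic: k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp
  expect_equal(d$k10, 4.64 / 15.87, tolerance = 1e-12)
  expect_equal(d$k12, 0.62 / 15.87, tolerance = 1e-12)
  expect_equal(d$k21, 0.62 / 4.11, tolerance = 1e-12)
  # alpha, beta are the quadratic roots; frozen values recomputed by hand
  expect_equal(d$alpha, 0.3596660, tolerance = 1e-6)
  expect_equal(d$beta, 0.1226285, tolerance = 1e-6)
  expect_equal(d$alpha + d$beta, d$k10 + d$k12 + d$k21, tolerance = 1e-12)
  expect_equal(d$alpha * d$beta, d$k10 * d$k21, tolerance = 1e-12)
  expect_gte(d$alpha, d$beta)
})

test_that("root identities hold across randomized parameter draws", {
  set.seed(41)
  for (i in 1:50) {
    p <- structural_params(CL = runif(1, 0.1, 20), Vc = runif(1, 0.5, 50),
                           Vp = runif(1, 0.5, 50), Q = runif(1, 0.05, 10))
    d <- derive_disposition_constants(p)
    expect_equal(d$alpha * d$beta, d$k10 * d$k21,
                 tolerance = 1e-12 * max(1, d$k10 * d$k21))
    expect_equal(d$alpha + d$beta, d$k10 + d$k12 + d$k21, tolerance = 1e-12)
  }
})

test_that("one-compartment input collapses to alpha = k10, beta = 0", {
  p <- structural_params(CL = 2, Vc = 10)
  d <- derive_disposition_constants(p)
  expect_equal(d$alpha, 0.2)
  expect_equal(d$beta, 0)
  expect_equal(d$k12, 0)
  expect_equal(d$k21, 0)
})

test_that("invalid structural parameters are rejected", {
  expect_error(structural_params(CL = -1, Vc = 10, Vp = 1, Q = 1), "positive")
  expect_error(structural_params(CL = 1, Vc = 0, Vp = 1, Q = 1), "positive")
  expect_error(structural_params(CL = 1, Vc = 10, Vp = 2), "together")
  expect_error(dose_events(c(8, 0), 10, 0.5), "sorted")
  expect_error(dose_events(0, 10, 0), "> 0")
  expect_error(dose_events(0, -5, 0.5), ">= 0")
})

test_that("zero-amount doses give zero concentrations and dose linearity is exact", {
  p <- structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
  ev0 <- dose_events(c(0, 8), 0, 0.5)
  expect_equal(predict_concentrations(p, ev0, c(1, 5, 10)), c(0, 0, 0))
  ev1 <- dose_events(c(0, 8), 22.9, 0.5)
  ev3 <- dose_events(c(0, 8), 3 * 22.9, 0.5)
  tt <- seq(0.25, 16, by = 0.25)
  expect_equal(predict_concentrations(p, ev3, tt),
               3 * predict_concentrations(p, ev1, tt))
})

test_that("multi-dose profiles are superpositions of shifted single doses", {
  p <- structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
  tau <- 8
  two <- dose_events(c(0, tau), 22.9, 0.5)
  one <- dose_events(0, 22.9, 0.5)
  t_after_2nd <- c(0.5, 1, 3, 6)
  expect_equal(
    predict_concentrations(p, two, tau + t_after_2nd),
    predict_concentrations(p, one, t_after_2nd) +
      predict_concentrations(p, one, t_after_2nd + tau))
})

test_that("times before the first dose return zero", {
  p <- structural_params(CL = 2, Vc = 10, Vp = 5, Q = 1)
  ev <- dose_events(2, 50, 0.5)
  expect_equal(predict_concentrations(p, ev, c(0, 1, 1.99)), c(0, 0, 0))
})

test_that("closed form matches ODE integration on the reference regimen", {
  p <- structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
  ev <- dose_events(0, 22.9, 0.5)
  tt <- seq(0.1, 8, by = 0.1)
  cf <- predict_concentrations(p, ev, tt)
  od <- ode_oracle(p, ev, tt)
  expect_lt(max(abs(cf - od) / od), 1e-6)
})

test_that("steady-state metrics match the one-compartment closed form", {
  # Cmax_ss = (R0/CL)(1 - e^{-kT}) / (1 - e^{-k tau}) at infusion end
  CL <- 1.5; Vc <- 12; wtkg <- 10; dose_kg <- 5; Tinf <- 1; tau <- 24
  p <- structural_params(CL, Vc)
  reg <- regimen(dose_kg, tau, Tinf)
  m <- steady_state_metrics(p, reg, wtkg)
  k <- CL / Vc
  R0 <- dose_kg * wtkg / Tinf
  cmax_ref <- (R0 / CL) * (1 - exp(-k * Tinf)) / (1 - exp(-k * tau))
  expect_equal(m$cmax, cmax_ref, tolerance = 1e-12)
  expect_equal(m$cmin, cmax_ref * exp(-k * (tau - Tinf)), tolerance = 1e-12)
})

test_that("an enormous interval reduces steady state to the single-dose profile", {
  p <- structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
  m <- steady_state_metrics(p, regimen(5, 5000, 1), 10)
  single <- predict_concentrations(p, dose_events(0, 50, 1), c(1, 5000))
  expect_equal(m$cmax, single[1], tolerance = 1e-9)
})

test_that("explicit long superposition converges to the steady-state solution", {
  p <- structural_params(CL = 4.64, Vc = 15.87, Vp = 4.11, Q = 0.62)
  d <- derive_disposition_constants(p)
  t_half_beta <- log(2) / d$beta
  tau <- 24
  n_doses <- ceiling(10 * t_half_beta / tau) + 1
  ss <- steady_state_metrics(p, regimen(7, tau, 1), 4.5)
  fin <- steady_state_metrics(p, regimen(7, tau, 1, n_doses = n_doses), 4.5)
  expect_lt(abs(fin$cmax - ss$cmax) / ss$cmax, 1e-3)
  expect_lt(abs(fin$cmin - ss$cmin) / ss$cmin, 1e-3)
})

test_that("degenerate Q = 0 accumulation is flagged", {
  # with Q ~ 0 the peripheral exponential has rate ~ 0: no finite steady state
  p <- structural_params(CL = 2, Vc = 10, Vp = 5, Q = 1e-300)
  expect_error(steady_state_metrics(p, regimen(5, 24, 1), 10),
               "non-accumulating")
})
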