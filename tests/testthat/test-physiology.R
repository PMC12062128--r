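# Growth-rate fitting, phase detection, specific rates, yields, carbon
# balance, RQ and media stoichiometry.

noise_free_run <- function(...) {
  simulate_batch(simulation_config(sampling_interval = 0.5, horizon = 40,
                                   ...))
}

test_that("log-linear regression recovers the configured growth rate exactly", {
  s <- noise_free_run()
  tr <- attr(s, "truth")
  win <- c(0, floor(tr$t_nlim * 2) / 2)       # samples inside the true phase
  fit <- fit_growth_rate(s, win)
  expect_equal(fit$mu, 0.34, tolerance = 1e-6 / 0.34)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- data.frame(time_h = 0:5, od = rep(2, 6))
  expect_equal(fit_growth_rate(flat)$mu, 0)
  expect_error(fit_growth_rate(s, c(0, 0.4)), "at least 3")
})

test_that("noisy growth-rate estimates cover the truth (Monte-Carlo)", {
  hits <- 0L
  for (seed in 1:100) {
    s <- simulate_batch(simulation_config(
      ammonium_sulfate = 5,                 # no N depletion inside the window
      sampling_interval = 1, horizon = 11,
      noise_od = 0.05, noise_conc = 0, seed = seed))
    fit <- fit_growth_rate(s, c(0, 11))     # 12 points
    if (abs(fit$mu - 0.34) <= 3 * fit$se) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("phase detection locates nitrogen depletion", {
  # configure depletion at t = 20 h: X must grow e^(mu*20)-fold
  mu <- 0.2; X0 <- 0.05
  needN <- (X0 * exp(mu * 20) - X0) * biomass_n_fraction()
  as_g <- needN * MOLAR_MASS[["as"]] / (2 * MOLAR_MASS[["n"]])
  s <- simulate_batch(simulation_config(
    glucose = 30, ammonium_sulfate = as_g, inoculum_cdw = X0,
    mu_exp = mu, sampling_interval = 1, horizon = 40))
  expect_equal(attr(s, "truth")$t_nlim, 20, tolerance = 0.01)
  ph <- detect_phases(s, "ammonium")
  expect_gte(ph$nlim[1], 19)
  expect_lte(ph$nlim[1], 21)
  # %DO basis finds the same transition from the oxygen-uptake spike
  ph_do <- detect_phases(s, "do")
  expect_lt(abs(ph_do$nlim[1] - 20), 2.5)

  # excess nitrogen: no depletion event, single-phase annotation
  s2 <- simulate_batch(simulation_config(glucose = 20, xylose = 0,
                                         ammonium_sulfate = 5,
                                         sampling_interval = 1, horizon = 20))
  expect_warning(ph2 <- detect_phases(s2, "ammonium"), "single-phase")
  expect_null(ph2$nlim)
})

test_that("EG consumption on glucose begins only inside the detected Nlim phase", {
  s <- noise_free_run()
  ph <- detect_phases(s, "ammonium")
  before <- s$eg_g_l[s$time_h <= ph$nlim[1] - 0.5]
  after <- s$eg_g_l[s$time_h >= ph$nlim[1] + 0.5 &
                      s$time_h <= attr(s, "truth")$t_glc_depleted]
  expect_equal(diff(before), rep(0, length(before) - 1))
  expect_true(all(diff(after) < 0))
})

test_that("specific rates recover the generator ground truth within 1%", {
  s <- noise_free_run()
  tr <- attr(s, "truth")
  exp_win <- c(0, floor(tr$t_nlim * 2) / 2)
  q_glc <- specific_rate(s, "glucose", exp_win)
  expect_equal(q_glc$q, tr$q_glc_exp, tolerance = 0.01)

  nlim_win <- c(ceiling(tr$t_nlim * 2) / 2,
                floor(tr$t_glc_depleted * 2) / 2)
  q_eg <- specific_rate(s, "eg", nlim_win)
  expect_equal(q_eg$q, -0.06, tolerance = 0.01)
  q_ga <- specific_rate(s, "ga", nlim_win)
  expect_equal(q_ga$q / abs(q_eg$q), 1.01, tolerance = 0.01)

  # constant analyte: zero rate
  expect_equal(specific_rate(s, "xylose", exp_win)$q, 0)
  expect_error(specific_rate(s, "glucose", c(0, 0.4)), "at least 3")
})

test_that("molar, Cmol and mass yields are mutually consistent", {
  expect_equal(molar_yield(26.2, 26.2), 1)
  expect_equal(molar_yield(2.21, 2.19), 1.009, tolerance = 1e-3)
  expect_equal(mass_yield(1, 1), 76.05 / 62.07)
  expect_equal(mass_yield(1, 1), 1.225, tolerance = 1e-3)
  # EG and GA both have 2 carbons: Cmol yield equals molar yield
  expect_equal(cmol_yield(3.3, 2.2), molar_yield(3.3, 2.2))
  expect_error(molar_yield(1, 0), "> 0")
})

test_that("regression yield slope matches the configured conversion", {
  eg <- seq(0, 20, by = 2)
  fit <- regression_yield(eg, eg)            # exact 1:1
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$se, 0, tolerance = 1e-9)

  hits <- 0L
  set.seed(99)
  for (i in 1:100) {
    ga <- 1.3 * eg + rnorm(length(eg), 0, 0.02 * max(eg))
    f <- regression_yield(eg, ga)
    if (abs(f$slope - 1.3) <= 3 * f$se) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  expect_error(regression_yield(rep(1, 5), 1:5), "degenerate")
})

test_that("the extra-GA route pushes the regression yield above 1", {
  s <- simulate_batch(simulation_config(
    glucose = 0, xylose = 10, eg = 9.31, ammonium_sulfate = 0.275,
    mu_exp = 0.11, y_ga_eg = 1.0, extra_ga_factor = 0.6, q_eg = 0.2,
    eg_gating = "xylose_coconsume", sampling_interval = 1, horizon = 60))
  tr <- attr(s, "truth")
  t_end <- if (is.finite(tr$t_xyl_depleted)) floor(tr$t_xyl_depleted) else
    max(s$time_h)
  nl <- s$time_h >= ceiling(tr$t_nlim) & s$time_h <= t_end
  eg_cons <- (s$eg_g_l[nl][1] - s$eg_g_l[nl]) / MOLAR_MASS[["eg"]] * 1000
  ga_prod <- (s$ga_g_l[nl] - s$ga_g_l[nl][1]) / MOLAR_MASS[["ga"]] * 1000
  fit <- regression_yield(eg_cons, ga_prod)
  expect_equal(fit$slope, 1.6, tolerance = 0.01)
})

test_that("carbon balance reproduces the published closure arithmetic", {
  expect_equal(carbon_balance(0.562, 0.366), 0.928, tolerance = 1e-12)
  expect_equal(carbon_balance(0.554, 0.377), 0.931, tolerance = 1e-12)
  expect_equal(carbon_balance(1, 0), 1)
  expect_warning(carbon_balance(0.8, 0.4), "exceeds 1.05")
})

test_that("respiratory quotient is the CO2/O2 yield ratio", {
  expect_equal(respiratory_quotient(30.63, 22.57), 1.357, tolerance = 5e-4)
  expect_equal(round(respiratory_quotient(30.63, 22.57), 2), 1.36)
  # control row: the direct ratio gives 1.28, one hundredth under the
  # published per-replicate average
  expect_equal(respiratory_quotient(29.88, 23.32), 1.281, tolerance = 5e-4)
  expect_equal(respiratory_quotient(7, 7), 1)
  expect_error(respiratory_quotient(1, 0), "> 0")
})

test_that("media stoichiometry reproduces the published C/N and conversions", {
  expect_equal(cn_ratio_molar(c(glucose = 10), 0.275), 80, tolerance = 0.005)
  expect_equal(cn_ratio_molar(c(glucose = 20), 5), 8.80, tolerance = 0.005)
  expect_equal(cn_ratio_molar(c(glucose = 10, xylose = 10), 0.550), 80,
               tolerance = 0.005)
  expect_error(cn_ratio_molar(c(glucose = 10), 0), "> 0")

  expect_equal(mm_to_gl(150, MOLAR_MASS[["eg"]]), 9.31, tolerance = 1e-3)
  expect_equal(mm_to_gl(75, MOLAR_MASS[["eg"]]), 4.66, tolerance = 2e-3)
  expect_equal(mm_to_gl(0, 62.07), 0)
  expect_equal(gl_to_mm(mm_to_gl(150, 62.07), 62.07), 150)

  expect_equal(ammonium_from_as(275), 75.1, tolerance = 1e-3)
  expect_equal(ammonium_from_as(0), 0)
  expect_equal(ammonium_from_as(132.14), 2 * 18.039, tolerance = 1e-3)
})

test_that("OD converts linearly to dry cell weight", {
  expect_equal(od_to_cdw(1), 0.3)
  expect_equal(od_to_cdw(0), 0)
  expect_equal(od_to_cdw(10), 3)
  expect_error(od_to_cdw(-1), "non-negative")
})

test_that("the physiology summary recovers RQ and yield on a clean run", {
  s <- noise_free_run()
  ps <- summarize_physiology(s)
  expect_equal(ps$rq, 1.36, tolerance = 1e-6)
  expect_equal(ps$yields$y_ga_eg$mol, 1.01, tolerance = 0.01)
  expect_equal(ps$mu_nlim$mu, 0.084, tolerance = 0.01)
  expect_equal(ps$carbon_closure, 1, tolerance = 0.01)
})
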