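# LP engine, pFBA, FVA, sampling, and flux reporting.

test_that("FBA solves hand-checked toy networks", {
  m <- toy_chain()
  sol <- solve_fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_A"]), -10, tolerance = 1e-9)

  blocked <- toy_chain(transport_ub = 0)
  expect_equal(solve_fba(blocked)$objective_value, 0, tolerance = 1e-12)
})

test_that("contradictory fixed constraints are reported as infeasible", {
  m <- toy_chain()
  cs <- model_bounds(m)
  i <- match("EX_A", cs$id)
  cs$lower[i] <- cs$upper[i] <- 1   # force secretion through an uptake-only path
  sol <- solve_fba(m, cs)
  expect_identical(sol$status, "infeasible")
})

test_that("FBA matches brute-force vertex enumeration on small random networks", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(3:6, 1); nm <- sample(1:(n - 1), 1)
    A <- matrix(sample(-2:2, nm * n, replace = TRUE), nm, n)
    if (qr(A)$rank < nm) next
    lb <- round(runif(n, -5, 0), 1); ub <- round(runif(n, 0, 5), 1)
    b <- as.vector(A %*% (lb + runif(n) * (ub - lb)))
    cc <- round(runif(n, -3, 3), 1)
    ours <- egflux:::lp_solve_core(cc, A, b, lb, ub, maximize = TRUE)
    oracle <- brute_force_lp(cc, A, b, lb, ub, maximize = TRUE)
    expect_identical(ours$status, "optimal")
    expect_equal(ours$obj, oracle$obj, tolerance = 1e-7)
  }
})

test_that("pFBA keeps the optimal growth and picks the shortest route", {
  m <- toy_diamond()
  sol <- solve_pfba(m)
  expect_identical(sol$status, "optimal")
  fba <- solve_fba(m)
  expect_equal(sol$objective_value, fba$objective_value,
               tolerance = 1e-9 * max(1, abs(fba$objective_value)))
  # brute force over route splits: all flux on the one-step route minimizes sum|v|
  expect_equal(unname(sol$fluxes["DIRECT"]), 10, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["VIA1"]), 0, tolerance = 1e-8)
})

test_that("pFBA total flux is minimal among sampled points at the same growth", {
  m <- toy_diamond()
  p <- solve_pfba(m)
  cs <- model_bounds(m)
  i <- match("GROW", cs$id)
  cs$lower[i] <- cs$upper[i] <- p$objective_value
  ss <- sample_solution_space(m, cs, n = 100, growth_fraction = 1, seed = 11)
  totals <- colSums(abs(attr(ss, "samples")))
  expect_true(all(attr(p, "total_flux") <= totals + 1e-6))
})

test_that("FVA brackets fluxes correctly", {
  m <- toy_parallel()
  fva <- flux_variability(m, growth_fraction = 1)
  r1 <- fva[fva$id == "R1", ]
  expect_equal(r1$min, 0, tolerance = 1e-9)
  expect_equal(r1$max, 10, tolerance = 1e-9)
  # a reaction fixed two-sided reports its fixed value without any LP
  cs <- apply_measured_rates(m, c(EX_A = -10))
  fva2 <- flux_variability(m, cs)
  ex <- fva2[fva2$id == "EX_A", ]
  expect_equal(ex$min, -10)
  expect_equal(ex$max, -10)
})

test_that("measured-rate constraints pin both bounds and reject unknown ids", {
  m <- toy_chain()
  cs <- apply_measured_rates(m, c(EX_A = -1))
  row <- cs[cs$id == "EX_A", ]
  expect_equal(row$lower, -1)
  expect_equal(row$upper, -1)
  expect_identical(row$provenance, "measured")
  expect_identical(apply_measured_rates(m)[, 1:3], model_bounds(m))
  expect_error(apply_measured_rates(m, c(NOPE = 1)), "NOPE")
})

test_that("sampling is seeded, feasible, and contained in the FVA box", {
  m <- build_core_model()
  cs <- apply_measured_rates(m, c(EX_glc__D_e = -2, EX_eg_e = -1,
                                  EX_glyclt_e = 1))
  ss1 <- sample_solution_space(m, cs, n = 200, seed = 42)
  ss2 <- sample_solution_space(m, cs, n = 200, seed = 42)
  expect_identical(ss1$summary, ss2$summary)

  X <- attr(ss1, "samples")
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% X)), 1e-6)
  fva <- attr(ss1, "fva")
  expect_true(all(ss1$summary$min >= fva$min - 1e-6))
  expect_true(all(ss1$summary$max <= fva$max + 1e-6))
  # growth floor respected
  floor_mu <- 0.9 * solve_fba(m, cs)$objective_value
  expect_true(all(X["BIOMASS", ] >= floor_mu - 1e-6))
  # fixed exchange: zero spread, median at the fixed value
  eg <- ss1$summary[ss1$summary$id == "EX_eg_e", ]
  expect_equal(eg$median, -1, tolerance = 1e-9)
  expect_equal(eg$sd, 0, tolerance = 1e-9)
  expect_error(sample_solution_space(m, cs, n = 1, seed = 1), "at least 2")
  expect_error(sample_solution_space(m, cs, n = 10), "seed")
})

test_that("uptake normalization divides by the uptake magnitude", {
  m <- toy_chain()
  cs <- apply_measured_rates(m, c(EX_A = -2))
  sol <- solve_fba(m, cs)
  nv <- normalize_by_uptake(sol, "EX_A")
  expect_equal(unname(nv["GROW"]), 1, tolerance = 1e-9)
  # the published scale: raw 0.46 over uptake 2.0 is 0.23
  expect_equal(0.46 / abs(-2.0), 0.23)
  zero <- solve_fba(m, apply_measured_rates(m, c(EX_A = 0)))
  expect_error(normalize_by_uptake(zero, "EX_A"), "zero")
})

test_that("route fractions are magnitude shares in [0, 1]", {
  fl <- c(a = 1, b = 0)
  expect_equal(route_fraction(fl, "a", c("a", "b")), 1)
  fl2 <- c(a = 0.92, b = 0.08)
  expect_equal(route_fraction(fl2, "a", c("a", "b")), 0.92)
  set.seed(1)
  for (i in 1:20) {
    fl3 <- stats::setNames(rnorm(4), letters[1:4])
    num <- sample(letters[1:4], 2)
    expect_lte(route_fraction(fl3, num, letters[1:4]), 1)
  }
  expect_error(route_fraction(c(a = 0), "a", "a"), "zero denominator")
})

test_that("pFBA routes all EG oxidation through the NADP dehydrogenase on glucose", {
  m <- build_core_model()
  cs <- apply_measured_rates(m, c(EX_glc__D_e = -2, EX_eg_e = -1,
                                  EX_glyclt_e = 1))
  p <- solve_pfba(m, cs)
  expect_identical(p$status, "optimal")
  frac <- route_fraction(p$fluxes, "EGDH_NADP", c("EGDH_NADP", "EGDH_NAD"))
  expect_equal(frac, 1, tolerance = 1e-6)
  # steady state and bound feasibility of the solution
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% p$fluxes)), 1e-6)
  bd <- resolve <- egflux:::resolve_constraints(m, cs)
  expect_true(all(p$fluxes >= bd$lower - 1e-6 & p$fluxes <= bd$upper + 1e-6))
})

test_that("without the xylulose-1P route no glycolaldehyde can come from xylose", {
  m <- build_core_model(xylulose1p_route = FALSE)
  # xylose-only condition, EG closed: maximal total GAH production is zero
  cs <- apply_measured_rates(m, c(EX_xyl__D_e = -1, EX_eg_e = 0))
  S <- stoichiometric_matrix(m)
  bd <- egflux:::resolve_constraints(m, cs)
  gah_prod <- as.numeric(S["gah_c", ] > 0)   # maximize GAH-producing flux
  r <- egflux:::lp_solve_core(gah_prod, S, rep(0, nrow(S)), bd$lower,
                              bd$upper, maximize = TRUE)
  expect_identical(r$status, "optimal")
  expect_equal(r$obj, 0, tolerance = 1e-9)
  # with the route enabled the same LP finds a positive maximum
  m2 <- build_core_model(xylulose1p_route = TRUE)
  S2 <- stoichiometric_matrix(m2)
  bd2 <- egflux:::resolve_constraints(
    m2, apply_measured_rates(m2, c(EX_xyl__D_e = -1, EX_eg_e = 0)))
  gah2 <- as.numeric(S2["gah_c", ] > 0)
  r2 <- egflux:::lp_solve_core(gah2, S2, rep(0, nrow(S2)), bd2$lower,
                               bd2$upper, maximize = TRUE)
  expect_gt(r2$obj, 0.1)
})
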