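test_that("the ODE right-hand side is stoichiometry times rates with boundary clamp", {
  fx <- makeLinearChain(3)
  m <- prepareModel(fx$model)
  conc <- stats::setNames(m@species$initial_concentration, m@species$id)
  ## at the analytic steady state every derivative vanishes
  conc[names(fx$steadyState)] <- fx$steadyState
  d <- odeDerivatives(m, conc, parameterValues(m))
  expect_lt(max(abs(d)), 1e-10)
  ## below steady state the first intermediate accumulates
  conc["S1"] <- 0.1
  d2 <- odeDerivatives(m, conc, parameterValues(m))
  expect_gt(d2[["S1"]], 0)
  ## boundary species entries stay exactly zero despite net production
  expect_identical(unname(d2[c("X0", "Xout")]), c(0, 0))
})

test_that("solver matches the linear-chain closed form", {
  fx <- makeLinearChain(3, v0 = 1, Vmax = 2, Km = 1)
  ss <- solveSteadyState(prepareModel(fx$model))
  expect_true(ss@converged)
  expect_equal(ss@concentrations, fx$steadyState, tolerance = 1e-6)
  expect_equal(ss@fluxes, fx$fluxes, tolerance = 1e-8)

  ## a different parameterization: S* = Km*v0/(Vmax - v0) = 2*1/(3-1) = 1
  fx2 <- makeLinearChain(1, v0 = 1, Vmax = 3, Km = 2)
  ss2 <- solveSteadyState(prepareModel(fx2$model))
  expect_equal(unname(ss2@concentrations), 1, tolerance = 1e-6)

  ## mixed per-step constants
  fx3 <- makeLinearChain(4, v0 = 0.5, Vmax = c(2, 3, 1.5, 4),
                         Km = c(1, 0.2, 2, 0.7))
  ss3 <- solveSteadyState(prepareModel(fx3$model))
  expect_equal(ss3@concentrations, fx3$steadyState, tolerance = 1e-6)
})

test_that("an initial vector at the steady state is returned unchanged", {
  fx <- makeLinearChain(3)
  m <- prepareModel(fx$model)
  init <- stats::setNames(m@species$initial_concentration, m@species$id)
  init[names(fx$steadyState)] <- fx$steadyState
  ss <- solveSteadyState(m, initialConcentrations = init)
  expect_true(ss@converged)
  expect_equal(ss@concentrations, fx$steadyState, tolerance = 1e-9)
})

test_that("unbounded accumulation is reported as non-convergence, not an error", {
  fx <- makeLinearChain(1, v0 = 1, Vmax = 0.5, failure = TRUE)
  ss <- solveSteadyState(prepareModel(fx$model), timeCap = 1e4)
  expect_false(ss@converged)
})

test_that("fluxes balance at converged steady states", {
  ## unbranched chain: every flux equals the source rate
  fx <- makeLinearChain(3)
  m <- prepareModel(fx$model)
  ss <- solveSteadyState(m)
  expect_equal(unname(ss@fluxes), rep(1, 4), tolerance = 1e-8)
  ## reactionFluxes reproduces the stored fluxes and rejects failures
  expect_equal(reactionFluxes(m, ss), ss@fluxes)
  bad <- solveSteadyState(prepareModel(
    makeLinearChain(1, v0 = 1, Vmax = 0.5, failure = TRUE)$model),
    timeCap = 1e3)
  expect_error(reactionFluxes(m, bad), "non-converged")

  ## branched fixture: input flux equals the sum of the outputs
  bf <- makeBranchedFixture()
  ssb <- solveSteadyState(bf$model)
  expect_true(ssb@converged)
  expect_equal(ssb@fluxes[["Rin"]],
               ssb@fluxes[["Rout1"]] + ssb@fluxes[["Rout2"]],
               tolerance = 1e-8)

  ## stoichiometric balance |S v| <= tol for free species at any converged result
  rv <- makeReversibleChain(2)
  ssr <- solveSteadyState(rv$model)
  expect_true(ssr@converged)
  expect_lt(ssr@residualNorm, 1e-9)
})

test_that("solving is deterministic", {
  rv <- makeReversibleChain(2)
  a <- solveSteadyState(rv$model)
  b <- solveSteadyState(rv$model)
  expect_identical(a@concentrations, b@concentrations)
  expect_identical(a@fluxes, b@fluxes)
})
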