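test_that("window statistics: constant, linear and short series", {
  ws <- windowStatistics(rep(3, 50), 10)
  expect_equal(nrow(ws), 5L)
  expect_equal(ws$slope, rep(0, 5))
  expect_equal(ws$cv, rep(0, 5))
  ## strictly linear series k, 2k, ...: normalized slope = k / window mean
  k <- 0.4
  series <- k * (1:10)
  ws2 <- windowStatistics(series, 10)
  expect_equal(ws2$slope, k / mean(series), tolerance = 1e-12)
  ## shorter than one window: empty
  expect_equal(nrow(windowStatistics(1:5, 10)), 0L)
  ## zero-mean window: NA statistics (counts as unstable)
  ws3 <- windowStatistics(rep(0, 10), 10)
  expect_true(is.na(ws3$slope))
})

test_that("detection verdicts are scale-free", {
  set.seed(5)
  series <- 10 + cumsum(rnorm(300, 0, 1e-4))
  a <- windowStatistics(series, 50)
  b <- windowStatistics(series * 10, 50)
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(a$cv, b$cv, tolerance = 1e-12)
})

test_that("the stability criterion needs fitness plus enough flat fluxes", {
  cfg <- equilibrationConfig(windowSize = 10, consecutiveWindows = 5,
                             fluxFraction = 0.8, slopeTol = 1e-5,
                             cvTol = 0.01)
  flat <- windowStatistics(rep(2, 50), 10)
  drift <- windowStatistics(seq(1, 2, length.out = 50), 10)
  tenFluxes <- function(nFlat) {
    out <- c(list(fitness = flat),
             rep(list(flat), nFlat), rep(list(drift), 10 - nFlat))
    names(out) <- c("fitness", paste0("flux_R", 1:10))
    out
  }
  expect_true(equilibriumReached(tenFluxes(10), cfg))
  expect_true(equilibriumReached(tenFluxes(8), cfg))
  ## only 70% of fluxes flat: below the 80% requirement
  expect_false(equilibriumReached(tenFluxes(7), cfg))
  ## drifting fitness fails regardless of fluxes
  s <- tenFluxes(10); s$fitness <- drift
  expect_false(equilibriumReached(s, cfg))
  ## 4 of the 5 most recent windows flat: not enough
  mixed <- rbind(drift[1, ], flat[1:4, ])
  s2 <- tenFluxes(10); s2$fitness <- mixed
  expect_false(equilibriumReached(s2, cfg))
})

test_that("equilibration doubles past detection and respects the cap", {
  rv <- makeReversibleChain(2)
  st <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                       Ne = 1000)
  root <- equilibrateRoot(st, rv$model, quickEqConfig(), seed = 7)
  expect_true(root@criterionMet)
  expect_false(root@capReached)
  ## total = 2 x detection generation, so the total is even and the trace
  ## spans at least twice the earliest possible detection span
  expect_true(root@generationsElapsed %% 2 == 0)
  expect_gt(nrow(root@counters), 0)

  ## generation cap 0: immediate return, no events
  root0 <- equilibrateRoot(st, rv$model,
                           quickEqConfig(generationCap = 0), seed = 7)
  expect_true(root0@capReached)
  expect_false(root0@criterionMet)
  expect_equal(nrow(root0@counters), 0L)
})

test_that("root snapshots round-trip losslessly and resume identically", {
  rv <- makeReversibleChain(2)
  st <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                       Ne = 1000)
  root <- equilibrateRoot(st, rv$model,
                          quickEqConfig(generationCap = 1500), seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  exportRoot(root, path)
  root2 <- importRoot(path, rv$model)
  expect_identical(root@parameterValues, root2@parameterValues)
  expect_identical(root@rngState, root2@rngState)
  expect_identical(root@fitness, root2@fitness)
  expect_identical(root@counters$n, root2@counters$n)
  expect_identical(root@generationsElapsed, root2@generationsElapsed)
  ## import against a model missing a parameter errors naming the id
  chain <- prepareModel(makeLinearChain(2)$model)
  expect_error(importRoot(path, chain), "Vf_1|missing|unknown")
  ## continuing from the snapshot reproduces the uninterrupted trajectory
  s1 <- rootToState(root, rv$model)
  r1 <- simulateGenerations(s1, rv$model, 400)
  s2 <- rootToState(root2, rv$model)
  r2 <- simulateGenerations(s2, rv$model, 400)
  expect_identical(r1$state@parameterValues, r2$state@parameterValues)
  expect_identical(r1$state@fitness, r2$state@fitness)
  ## resumed counting continues from generations_elapsed
  expect_equal(r1$state@generationsElapsed, root@generationsElapsed + 400)
})
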