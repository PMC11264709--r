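test_that("logistic kernel and normalized flux fitness hit their anchors", {
  expect_identical(rawLogistic(0.5), 0.5)
  ## direct evaluation of the logistic at the anchors
  expect_equal(rawLogistic(0), 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(rawLogistic(1), 1 / (1 + exp(-5)), tolerance = 1e-12)

  expect_equal(fluxFitness(0, 1), 0)
  expect_equal(fluxFitness(1, 1), 1)
  expect_equal(fluxFitness(-2, -2), 1)  # signed reference flux
  ## saturating limit of the normalization
  l0 <- 1 / (1 + exp(5)); l1 <- 1 / (1 + exp(-5))
  expect_equal(fluxFitness(1e9, 1), (1 - l0) / (l1 - l0), tolerance = 1e-9)
  expect_equal(fluxFitness(1e9, 1), 1.006783, tolerance = 1e-6)
  ## a multiplier of 2 re-anchors score 1 at the starting flux while
  ## placing it on the rising part of the logistic: doubling the flux now
  ## yields a real fitness gain (positive-selection mode)
  expect_equal(fluxFitness(1, 1, multiplier = 2), 1)
  expect_gt(fluxFitness(2, 1, multiplier = 2), 1.5)
  expect_equal(fluxFitness(0, 1, multiplier = 2), 0)
  expect_error(fluxFitness(1, 0), "zero start flux")
})

test_that("population fitness is the weighted geometric mean with absorbing zero", {
  expect_equal(populationFitness(c(1, 1, 1), c(0.2, 0.3, 0.5)), 1)
  expect_equal(populationFitness(c(0.9, 1.1), c(0.5, 0.5)), sqrt(0.99))
  expect_equal(populationFitness(c(0, 1), c(0.5, 0.5)), 0)
})

test_that("Kimura fixation probability matches closed forms and is overflow-safe", {
  ## neutral limit returns p exactly
  expect_identical(fixationProbability(0, 1000, 2, 0.5), 0.5)
  ## tiny |s|: indistinguishable from p at printed precision
  expect_equal(fixationProbability(1e-15, 1e6, 2, 0.5), 0.5,
               tolerance = 1e-8)
  expect_identical(fixationProbability(1e-17, 1000, 2, 0.5), 0.5)
  ## closed form (1 - e^-2cNesp)/(1 - e^-2cNes)
  expect_equal(fixationProbability(0.001, 1000, 2, 0.5),
               (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  ## strongly deleterious: essentially zero, no overflow/NaN
  v <- fixationProbability(-0.01, 1e6, 2, 0.5)
  expect_true(is.finite(v))
  expect_lt(v, 1e-300)
  ## monotone nondecreasing in s over a wide grid
  sGrid <- c(-0.5, -0.1, -0.01, -1e-4, 0, 1e-4, 0.01, 0.1, 0.5)
  pv <- vapply(sGrid, fixationProbability, numeric(1L), Ne = 5000, c = 2)
  expect_true(all(diff(pv) >= -1e-15))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("mutational effects have the prescribed means and stay positive", {
  set.seed(101)
  n <- 1e5
  dBind <- sampleEffects(n, "binding_constant")
  dVmax <- sampleEffects(n, "forward_max_velocity")
  se <- 0.01 / sqrt(n)
  expect_lt(abs(mean(dBind) - 0.01), 3 * se)
  expect_lt(abs(mean(dVmax) + 0.01), 3 * se)
  expect_true(all(1 + dBind > 0))
  ## degenerate sigma = 0 gives the mean exactly
  expect_identical(sampleEffects(5, "binding_constant", sd = 0), rep(0.01, 5))
  expect_identical(sampleEffects(5, "other", sd = 0), rep(-0.01, 5))
})

test_that("proposal engine recovers lambda and the 1:1 expression:function ratio", {
  fx <- makeLinearChain(5, withEnzyme = TRUE)
  m <- prepareModel(fx$model)
  st <- initPopulation(m, data.frame(reaction = "R5", weight = 1), Ne = 1000)
  plan <- st@plan
  expect_equal(sum(plan$category == "functional"), 10L)  # kcat_i + Km_i
  expect_equal(sum(plan$category == "E"), 5L)
  expect_equal(unname(plan$lambda[plan$category == "E"]), rep(0.006, 5))
  set.seed(7)
  gens <- 2e4
  nF <- 0L; nE <- 0L
  for (g in seq_len(gens)) {
    pr <- proposeMutations(st, m)
    if (!nrow(pr)) next
    nF <- nF + sum(pr$category == "functional")
    nE <- nE + sum(pr$category == "E")
  }
  ## per functional parameter per generation rate ~ Poisson(0.003)
  rate <- nF / (gens * 10)
  se <- sqrt(0.003 / (gens * 10))
  expect_lt(abs(rate - 0.003), 3 * se)
  ## aggregate E:functional ratio ~ 1
  ratio <- nE / nF
  seR <- ratio * sqrt(1 / nE + 1 / nF)
  expect_lt(abs(ratio - 1), 3 * seR)
})

test_that("Haldane partner updates restore the identity after mutations", {
  m <- prepareModel(uniUniReversibleModel(Vf = 10, Keq = 2, KmS = 1, KmP = 4))
  g <- haldaneGroups(m)[[1L]]
  pv <- parameterValues(m)
  ## Vr from the identity: Vf*KmP/(Keq*KmS) = 10*4/(2*1) = 20
  expect_equal(applyHaldaneUpdate(g, pv), 20)
  ## KmS 1 -> 1.01: Vr = 40/2.02
  pv2 <- pv; pv2[["KmS_A"]] <- 1.01
  expect_equal(applyHaldaneUpdate(g, pv2), 40 / 2.02, tolerance = 1e-12)
  ## arbitrary KmP perturbation: residual restored below 1e-9
  pv3 <- pv; pv3[["KmP_B"]] <- pv3[["KmP_B"]] * 1.0137
  pv3[[g$vr]] <- applyHaldaneUpdate(g, pv3)
  expect_lt(max(haldaneResiduals(m, pv3)), 1e-9)
  ## degenerate Vf/Keq guard
  pv4 <- pv; pv4[["VfR"]] <- -1
  expect_error(applyHaldaneUpdate(g, pv4), "positive")
})

test_that("a generation step proposes, scores, fixes or reverts cleanly", {
  bf <- makeBranchedFixture(neutralModule = TRUE)
  m <- bf$model
  st <- initPopulation(m, data.frame(reaction = c("Rout1", "Rout2"),
                                     weight = c(0.5, 0.5)), Ne = 1000)
  expect_equal(st@fitness, 1)
  set.seed(11)
  sawEvent <- FALSE; sawReject <- FALSE; sawNeutral <- FALSE
  before <- st@parameterValues
  for (g in 1:3000) {
    res <- generationStep(st, m)
    if (!is.null(res$event)) {
      sawEvent <- TRUE
      ## a proposal touching only the disconnected side reaction is neutral:
      ## s = 0 and Pfix = p = 0.5
      if (all(res$proposals$reaction == "Rside")) {
        sawNeutral <- TRUE
        expect_identical(res$event$s, 0)
        expect_identical(res$event$pfix, 0.5)
      }
      if (!res$event$fixed) {
        sawReject <- TRUE
        ## rejection reverts every parameter bit-identically
        expect_identical(res$state@parameterValues, st@parameterValues)
      }
      expect_gte(res$event$pfix, 0); expect_lte(res$event$pfix, 1)
    }
    st <- res$state
  }
  expect_true(sawEvent && sawReject && sawNeutral)
  ## generations advanced; fitness stayed in the admissible band
  expect_equal(st@generationsElapsed, 3000)
  l0 <- 1 / (1 + exp(5)); l1 <- 1 / (1 + exp(-5))
  expect_lte(st@fitness, (1 - l0) / (l1 - l0))
  expect_gte(st@fitness, 0)
})

test_that("simulating zero generations or with nothing mutable is the identity", {
  rv <- makeReversibleChain(2)
  st <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                       Ne = 1000)
  r0 <- simulateGenerations(st, rv$model, 0)
  expect_identical(r0$state@parameterValues, st@parameterValues)
  expect_null(r0$events)
  ## excluding every parameter: no events ever
  allIds <- parameterTable(rv$model)$id
  st2 <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                        Ne = 1000, exclude = allIds)
  r2 <- simulateGenerations(st2, rv$model, 500)
  expect_null(r2$events)
  expect_identical(r2$state@parameterValues, st2@parameterValues)
})

test_that("neutral-class events fix about half the time", {
  ## on the source-fed reversible chain the steady-state flux is pinned to
  ## the source rate, so every mutation is selectively neutral
  rv <- makeReversibleChain(2)
  st <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                       Ne = 1000)
  set.seed(19)
  sim <- simulateGenerations(st, rv$model, 6000)
  ev <- sim$events
  expect_gt(nrow(ev), 100)
  frac <- mean(ev$fixed)
  se <- sqrt(0.25 / nrow(ev))
  expect_lt(abs(frac - 0.5), 3 * se)
})
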