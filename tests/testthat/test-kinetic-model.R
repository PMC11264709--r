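test_that("native format parses a minimal document and round-trips", {
  m <- parseNativeModel(oneReactionDoc())
  expect_s4_class(m, "KineticModel")
  expect_equal(nrow(speciesTable(m)), 2L)
  expect_length(reactionList(m), 1L)
  expect_true(speciesTable(m)$is_boundary[speciesTable(m)$id == "X0"])
  expect_equal(unname(parameterValues(m)[c("Vmax", "Km")]), c(2, 1))

  ## round trip preserves parameter values and stoichiometry
  rv <- makeReversibleChain(2)
  m2 <- parseNativeModel(writeNativeModel(rv$model))
  expect_identical(parameterValues(m2), parameterValues(rv$model))
  expect_identical(parameterTable(m2)$scope, parameterTable(rv$model)$scope)
  for (i in seq_along(reactionList(rv$model)))
    expect_identical(reactionList(m2)[[i]]$substrates,
                     reactionList(rv$model)[[i]]$substrates)
})

test_that("native parser rejects undeclared identifiers and bad syntax", {
  doc <- oneReactionDoc()
  doc[9] <- "  R1: X0 -> S1   rate = Vmax*X0/(Kfoo + X0)"
  expect_error(parseNativeModel(doc), "Kfoo")
  expect_error(parseNativeModel(sub("init=1.0", "oops", doc[3])),
               "line|species|section")
  ## unsupported function in a rate law
  doc2 <- oneReactionDoc()
  doc2[9] <- "  R1: X0 -> S1   rate = sin(X0)"
  expect_error(parseNativeModel(doc2), "sin")
})

test_that("SBML subset round-trips and flags are mapped", {
  rv <- makeReversibleChain(2)
  xml <- writeSBML(rv$model)
  m2 <- parseSBML(xml)
  pv1 <- parameterValues(rv$model)
  expect_equal(parameterValues(m2)[names(pv1)], pv1)
  sp <- speciesTable(m2)
  expect_true(all(sp$is_boundary[sp$id %in% c("X0", "Xout")]))
  expect_false(any(sp$is_boundary[sp$id %in% c("S1", "S2", "S3")]))
  ## the re-parsed model still solves to the same steady state
  ss <- solveSteadyState(prepareModel(m2))
  expect_true(ss@converged)
  expect_equal(unname(ss@fluxes), rep(1, 4), tolerance = 1e-8)
})

test_that("SBML reader rejects out-of-subset constructs", {
  xml <- writeSBML(makeLinearChain(1)$model)
  withEvents <- sub("<listOfReactions>",
                    "<listOfEvents><event id=\"e1\"/></listOfEvents><listOfReactions>",
                    xml)
  expect_error(parseSBML(withEvents), "listOfEvents")
  withRules <- sub("<listOfReactions>",
                   "<listOfRules><assignmentRule/></listOfRules><listOfReactions>",
                   xml)
  expect_error(parseSBML(withRules), "listOfRules")
  noKinetic <- gsub("(?s)<kineticLaw>.*?</kineticLaw>", "", xml, perl = TRUE)
  expect_error(parseSBML(noKinetic), "kinetic law")
})

test_that("parameter classification follows name heuristics and overrides", {
  doc <- c("species:", "  X0 init=1 boundary", "  S1 init=1",
           "parameters:",
           "  KmATP = 0.1", "  parameter__12 = 5", "  Vmax_HK = 3",
           "  kcat_P = 2", "  Keq9 = 1.5", "  E_hk = 0.2", "  Vr_HK = 1",
           "reactions:",
           "  R1: X0 -> S1  rate = Vmax_HK*X0/(KmATP + X0)")
  m <- parseNativeModel(doc)
  roles <- classifyParameters(m)
  expect_equal(unname(roles["KmATP"]), "binding_constant")
  expect_equal(unname(roles["parameter__12"]), "other")
  expect_equal(unname(roles["Vmax_HK"]), "forward_max_velocity")
  expect_equal(unname(roles["Vr_HK"]), "reverse_max_velocity")
  expect_equal(unname(roles["kcat_P"]), "catalytic_constant")
  expect_equal(unname(roles["Keq9"]), "equilibrium_constant")
  expect_equal(unname(roles["E_hk"]), "enzyme_concentration")
  ## overrides take precedence; unknown ids error
  roles2 <- classifyParameters(m, c(parameter__12 = "binding_constant"))
  expect_equal(unname(roles2["parameter__12"]), "binding_constant")
  expect_error(classifyParameters(m, c(nope = "binding_constant")), "nope")
  ## purity: same inputs, same map
  expect_identical(roles, classifyParameters(m))
})

test_that("Haldane groups are built for pairable reversible reactions only", {
  m <- uniUniReversibleModel()
  m <- prepareModel(m)
  gs <- haldaneGroups(m)
  expect_length(gs, 1L)
  g <- gs[[1L]]
  expect_equal(g$reaction, "Rrev")
  expect_equal(g$substrate_kms, "KmS_A")
  expect_equal(g$product_kms, "KmP_B")
  ## identity holds by direct evaluation: Keq = Vf*KmP/(Vr*KmS)
  pv <- parameterValues(m)
  expect_equal(pv[["KeqR"]],
               pv[["VfR"]] * pv[["KmP_B"]] / (pv[["VrR"]] * pv[["KmS_A"]]),
               tolerance = 1e-12)
  expect_lt(max(haldaneResiduals(m)), 1e-9)
  ## the dependent reverse velocity and the equilibrium constant are frozen
  pt <- parameterTable(m)
  expect_false(pt$mutable[pt$id == "VrR"])
  expect_false(pt$mutable[pt$id == "KeqR"])

  ## bi-uni reaction (2 substrates, 1 product): no group
  biUni <- parseNativeModel(c(
    "species:", "  A init=1", "  B init=1", "  C init=1",
    "parameters:",
    "  Vf1 = 1", "  Vr1 = 1", "  Keq1 = 1  scope=R1",
    "  KmA = 1", "  KmB = 1", "  KmC = 1",
    "reactions:",
    "  R1: A + B -> C  rate = (Vf1*A*B/(KmA*KmB) - Vr1*C/KmC)/(1 + A/KmA + B/KmB + C/KmC)"))
  expect_length(buildHaldaneGroups(biUni, classifyParameters(biUni)), 0L)

  ## irreversible reaction (no reverse velocity): no group
  irr <- parseNativeModel(oneReactionDoc())
  expect_length(buildHaldaneGroups(irr, classifyParameters(irr)), 0L)
})

test_that("rate evaluation matches hand calculations", {
  doc <- c("species:", "  E init=1 boundary", "  S init=1",
           "parameters:", "  kcat = 2", "  Km = 1",
           "reactions:", "  R1: S -> S  rate = kcat*E*S/(Km + S)")
  m <- parseNativeModel(doc)
  rxn <- reactionList(m)[[1L]]
  expect_equal(evaluateRate(rxn, c(E = 1, S = 1), c(kcat = 2, Km = 1)), 1.0)
  expect_equal(evaluateRate(rxn, c(E = 1, S = 0), c(kcat = 2, Km = 1)), 0.0)
  ## division by zero (S = -Km) names the reaction
  expect_error(evaluateRate(rxn, c(E = 1, S = 1), c(kcat = 2, Km = -1)),
               "R1")
  ## reversible MM at equilibrium concentrations (P/S = Keq) has zero rate
  m2 <- uniUniReversibleModel(Vf = 10, Keq = 2, KmS = 1, KmP = 4)
  rev <- reactionList(m2)[[2L]]
  v <- evaluateRate(rev, c(X0 = 1, A = 0.3, B = 0.6, Xout = 0),
                    parameterValues(m2))
  expect_equal(v, 0, tolerance = 1e-12)
})
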