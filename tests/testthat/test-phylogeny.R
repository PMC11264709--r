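test_that("Newick parsing enforces rootedness and branch lengths", {
  t1 <- parseNewickTree("(A:1.0,B:2.0):0.0;")
  expect_equal(ape::Ntip(t1), 2L)
  expect_equal(sum(t1$edge[, 1] == 3L), 2L)  # root has two children
  t2 <- parseNewickTree("((A:1,B:1):0.5,C:1.5);")
  expect_equal(ape::Ntip(t2), 3L)
  expect_equal(nrow(t2$edge), 4L)
  ## unrooted trifurcation at the root is rejected
  expect_error(parseNewickTree("(A:1,B:1,C:1);"), "rooted")
  ## missing branch lengths and missing semicolon are rejected
  expect_error(parseNewickTree("(A,B);"), "branch length")
  expect_error(parseNewickTree("(A:1,B:1)"), ";")
  ## polytomies below the root need the explicit flag
  poly <- "((A:1,B:1,C:1):1,D:2);"
  expect_error(parseNewickTree(poly), "polytom")
  expect_equal(ape::Ntip(parseNewickTree(poly, allowPolytomy = TRUE)), 4L)
})

test_that("calibration finds the 7-proposal crossing in both categories", {
  plan <- data.frame(param = c("kcat_1", "E_1", "kcat_2", "E_2"),
                     role = c("catalytic_constant", "enzyme_concentration",
                              "catalytic_constant", "enzyme_concentration"),
                     reaction = c("R1", "R1", "R2", "R2"),
                     category = c("functional", "E", "functional", "E"),
                     lambda = 0.003, stringsAsFactors = FALSE)
  ## deterministic counters: one proposal per reaction per category every
  ## 100 generations -> across-reaction average reaches 7 at generation 700
  gens <- rep(seq(100, 2000, by = 100), each = 4)
  counters <- data.frame(
    generation = gens,
    reaction = rep(c("R1", "R1", "R2", "R2"), 20),
    category = rep(c("functional", "E", "functional", "E"), 20),
    n = 1L, stringsAsFactors = FALSE)
  sc <- calibrateGenerationScale(counters, plan)
  expect_equal(sc@gUnit, 700)
  ## halving one category's rate moves the crossing to the slower category
  counters2 <- counters[!(counters$category == "E" &
                          counters$generation %% 200 == 100), ]
  sc2 <- calibrateGenerationScale(counters2, plan)
  expect_equal(unname(sc2@crossing["functional"]), 700)
  expect_equal(sc2@gUnit, unname(sc2@crossing["E"]))
  expect_gt(sc2@gUnit, 1300)
  ## empty counters: error instructing longer equilibration
  empty <- counters[0, ]
  expect_error(calibrateGenerationScale(empty, plan), "equilibrate longer")
})

test_that("branch lengths convert to generations with the factor-100 rule", {
  expect_equal(branchGenerations(2.5, "myr", 1000), 2500)
  expect_equal(branchGenerations(0.025, "subs", 1000), 2500)
  expect_equal(branchGenerations(0, "myr", 1000), 0)
  ## unrounded ratio between the two unit conventions is exactly 100
  expect_identical(branchGenerations(0.03, "subs", 1000, round = FALSE) /
                   branchGenerations(0.03, "myr", 1000, round = FALSE), 100)
  ## half-up rounding
  expect_equal(branchGenerations(1.0005, "myr", 1000), 1001)
  expect_error(branchGenerations(-1, "myr", 1000), "negative")
})

test_that("tree simulation inherits states exactly and is reproducible", {
  rv <- makeReversibleChain(2)
  st <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                       Ne = 1000)
  root <- equilibrateRoot(st, rv$model,
                          quickEqConfig(generationCap = 1200), seed = 2)
  tree <- parseNewickTree("((A:1.0,B:1.0):0.5,C:1.5);")
  tr <- simulateTree(root, tree, rv$model, scale = 200, units = "myr",
                     popsize = 1000, seed = 11)
  ## one trace per edge
  expect_length(tr, nrow(tree$edge))
  ## children of the shared internal node inherit its end state bit-identically
  internal <- tr[["branch5"]]
  expect_identical(tr[["branch1"]]$inheritedValues,
                   internal$endState$parameterValues)
  expect_identical(tr[["branch2"]]$inheritedValues,
                   internal$endState$parameterValues)
  ## C branches straight off the root
  expect_identical(tr[["branch3"]]$inheritedValues, root@parameterValues)
  ## generation counts follow the branch lengths
  expect_equal(internal$generations, 100)
  expect_equal(tr[["branch3"]]$generations, 300)
  ## identical seed reproduces the full result; a different seed does not
  tr2 <- simulateTree(root, tree, rv$model, scale = 200, units = "myr",
                      popsize = 1000, seed = 11)
  expect_identical(lapply(tr, `[[`, "endState"),
                   lapply(tr2, `[[`, "endState"))
  ## zero-length branches inherit unchanged state
  tz <- parseNewickTree("((A:0.0,B:1.0):0.5,C:1.0);")
  trz <- simulateTree(root, tz, rv$model, scale = 200, units = "myr",
                      popsize = 1000, seed = 4)
  expect_equal(trz[["branch1"]]$generations, 0)
  expect_identical(trz[["branch1"]]$endState$parameterValues,
                   trz[["branch1"]]$inheritedValues)
})

test_that("per-branch population sizes are honored and missing ones error", {
  rv <- makeReversibleChain(1)
  st <- initPopulation(rv$model, data.frame(reaction = "R2", weight = 1),
                       Ne = 1000)
  root <- equilibrateRoot(st, rv$model,
                          quickEqConfig(generationCap = 600), seed = 9)
  tree <- parseNewickTree("(A:0.5,B:0.5);")
  tr <- simulateTree(root, tree, rv$model, scale = 100, units = "myr",
                     popsize = c(A = 500, B = 2000), seed = 1)
  expect_equal(tr[["branch1"]]$Ne, 500)
  expect_equal(tr[["branch2"]]$Ne, 2000)
  expect_error(simulateTree(root, tree, rv$model, scale = 100,
                            units = "myr", popsize = c(A = 500), seed = 1),
               "B")
})

test_that("lineages concatenate branches with strictly increasing generations", {
  rv <- makeReversibleChain(2)
  st <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                       Ne = 1000)
  root <- equilibrateRoot(st, rv$model,
                          quickEqConfig(generationCap = 1200), seed = 21)
  tree <- parseNewickTree("((A:1.0,B:1.0):0.5,C:1.5);")
  tr <- simulateTree(root, tree, rv$model, scale = 400, units = "myr",
                     popsize = 1000, seed = 13)
  ln <- assembleLineages(tree, tr)
  expect_named(ln, c("A", "B", "C"))
  ## lineage length equals the sum of its branches' generation counts
  expect_equal(ln$A$generations, 200 + 400)
  expect_equal(ln$C$generations, 600)
  ## the deepest lineage concatenates two branch traces
  expect_equal(ln$A$branches, c(5L, 1L))
  for (nm in names(ln)) {
    mt <- ln[[nm]]$mutations
    if (!is.null(mt)) expect_true(all(diff(unique(mt$generation)) > 0))
  }
  ## the shared ancestral branch contributes identical events to A and B
  ma <- ln$A$mutations; mb <- ln$B$mutations
  if (!is.null(ma) && !is.null(mb)) {
    sharedA <- ma[ma$branch == 5L, ]
    sharedB <- mb[mb$branch == 5L, ]
    expect_identical(sharedA, sharedB)
  }
  ## end state equals the terminal branch's end state
  expect_identical(ln$B$endState, tr[["branch2"]]$endState)
})
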