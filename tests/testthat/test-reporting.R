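test_that("percent change and column normalization behave per contract", {
  expect_equal(percentChange(2, 3), 50)
  expect_equal(percentChange(4, 4), 0)
  expect_equal(percentChange(4, 3), -25)
  expect_true(is.na(percentChange(0, 1)))

  m <- cbind(a = c(4, -2, 1), b = c(0, 0, 0), c = c(-3, NA, 1.5))
  n <- normalizeColumns(m)
  expect_equal(unname(n[, "a"]), c(1, -0.5, 0.25))
  expect_equal(unname(n[, "b"]), c(0, 0, 0))
  expect_equal(unname(n[, "c"]), c(-1, NA, 0.5))
  ## sign pattern preserved; normalized cells within [-1, 1]
  expect_true(all(sign(n) == sign(m), na.rm = TRUE))
  expect_true(all(abs(n) <= 1, na.rm = TRUE))
})

test_that("replicate averaging is cell-wise on raw percents", {
  m1 <- matrix(c(10, -10), 1, 2, dimnames = list("A", c("x", "y")))
  m2 <- matrix(c(-10, -10), 1, 2, dimnames = list("A", c("x", "y")))
  avg <- averageReplicates(list(m1, m2))
  expect_equal(unname(avg[1, ]), c(0, -10))
  expect_identical(averageReplicates(list(m1)), m1)
  expect_identical(averageReplicates(list(m1, m1)), m1)
  m3 <- m2; colnames(m3) <- c("x", "z")
  expect_error(averageReplicates(list(m1, m3)), "labels")
})

test_that("the output file set is complete, consistent and re-readable", {
  rv <- makeReversibleChain(2)
  st <- initPopulation(rv$model, data.frame(reaction = "R3", weight = 1),
                       Ne = 1000)
  root <- equilibrateRoot(st, rv$model,
                          quickEqConfig(generationCap = 1500), seed = 31)
  tree <- parseNewickTree("(A:1.0,B:2.0);")
  mkRun <- function(seed) {
    tr <- simulateTree(root, tree, rv$model, scale = 400, units = "myr",
                       popsize = 1000, seed = seed)
    list(traces = tr, lineages = assembleLineages(tree, tr))
  }
  runs <- list(mkRun(1), mkRun(2), mkRun(3))
  dir <- withr::local_tempdir()
  summary <- writeOutputs(runs, root, dir)
  files <- summary$files$file
  ## 2-leaf tree: two lineage trajectory files per replicate, 2-row matrix
  expect_equal(sum(grepl("^lineage_", files) & grepl("sim1", files)), 2L)
  cm <- readMatrixTSV(file.path(dir, "change_lineages_raw_sim1.tsv"))
  expect_equal(nrow(cm), 2L)
  ## three replicates: per-replicate matrices plus the averaged pair
  expect_true("change_lineages_raw_avg.tsv" %in% files)
  avg <- readMatrixTSV(file.path(dir, "change_lineages_raw_avg.tsv"))
  mats <- lapply(1:3, function(i)
    readMatrixTSV(file.path(dir, sprintf("change_lineages_raw_sim%d.tsv", i))))
  expect_equal(avg, averageReplicates(mats), tolerance = 1e-15)
  ## matrix round trip is numerically exact at full precision
  m1 <- buildChangeMatrix(root, runs[[1]]$lineages, by = "lineage")
  expect_identical(readMatrixTSV(file.path(dir, "change_lineages_raw_sim1.tsv")),
                   m1)
  ## manifest covers every written file with checksums
  man <- read.table(file.path(dir, "MANIFEST.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  expect_setequal(man$file, files)
  expect_true(all(nchar(man$md5) == 32L))
  ## fixed events in the mutation TSVs match the reported total
  logs <- do.call(rbind, lapply(1:3, function(i)
    read.table(file.path(dir, sprintf("mutations_sim%d.tsv", i)),
               sep = "\t", header = TRUE, stringsAsFactors = FALSE)))
  perEvent <- !duplicated(logs[, c("sim", "branch", "generation")])
  expect_equal(sum(logs$fixed[perEvent]), summary$fixedEvents)
  ## dry run writes nothing
  dir2 <- withr::local_tempdir()
  s2 <- writeOutputs(runs, root, dir2, dryRun = TRUE)
  expect_equal(length(list.files(dir2)), 0L)
  expect_setequal(s2$files$file, files)
})
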