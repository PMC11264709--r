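## Commands-file parsing and end-to-end orchestration:
## equilibrate -> calibrate -> simulate the tree -> report.
##
## The commands file is line-oriented `key = value` with '#' comments.
## Repeatable keys: `select = reaction:weight[:multiplier]`,
## `popsize = label:value` (or a single integer), `exclude = id`,
## `override = id:role`.

#' Parse a commands file into a run configuration
#'
#' Mandatory keys: \code{model}, \code{tree}, at least one \code{select},
#' \code{popsize}, \code{ploidy}.  Optional keys with defaults:
#' \code{units} (myr), \code{n_simulations} (1), \code{seed} (1),
#' \code{lambda} (0.003), \code{effect_sd} (0.01), \code{p} (0.5),
#' \code{steady_tolerance} (1e-9), \code{time_cap} (1e6),
#' \code{window_size} (100), \code{consecutive_windows} (5),
#' \code{flux_fraction} (0.8), \code{slope_tol} (1e-5), \code{cv_tol}
#' (0.01), \code{generation_cap} (1e6), \code{outdir} (fluxsel_out),
#' \code{import_root} (none), \code{allow_polytomy} (false),
#' \code{model_format} (inferred from the extension: .xml/.sbml is SBML,
#' anything else native).  Relative paths resolve against the commands
#' file's directory.
#'
#' @param path path to the commands file (or its text as a vector of
#'   lines).
#' @return a validated list of class \code{"RunConfig"} holding the loaded
#'   model (prepared), tree, targets, and all settings.
#' @export
parseCommandsFile <- function(path) {
  baseDir <- "."
  if (length(path) == 1L && file.exists(path)) {
    baseDir <- dirname(path)
    lines <- readLines(path, warn = FALSE)
  } else lines <- path
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[trimws(lines) != ""])
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, 0L) == 0L)
  if (length(bad))
    stop(sprintf("malformed commands line: '%s'", lines[bad[1L]]),
         call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  one <- function(key, default = NULL) {
    i <- which(keys == key)
    if (!length(i)) {
      if (is.null(default))
        stop(sprintf("missing mandatory key '%s' in commands file", key),
             call. = FALSE)
      return(default)
    }
    vals[i[length(i)]]
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(baseDir, p)

  modelPath <- resolve(one("model"))
  format <- one("model_format",
                if (grepl("\\.(xml|sbml)$", modelPath, ignore.case = TRUE))
                  "sbml" else "native")
  model <- switch(format, sbml = parseSBML(modelPath),
                  native = parseNativeModel(modelPath),
                  stop(sprintf("unknown model_format '%s'", format),
                       call. = FALSE))

  overrides <- NULL
  ov <- vals[keys == "override"]
  if (length(ov)) {
    parts <- strsplit(ov, ":", fixed = TRUE)
    overrides <- stats::setNames(vapply(parts, `[`, "", 2L),
                                 vapply(parts, `[`, "", 1L))
  }
  exclude <- vals[keys == "exclude"]
  model <- prepareModel(model, overrides, exclude)

  treeVal <- one("tree")
  treeText <- if (grepl(";", treeVal, fixed = TRUE)) treeVal else
    resolve(treeVal)
  allowPoly <- tolower(one("allow_polytomy", "false")) %in%
    c("true", "1", "yes")
  tree <- parseNewickTree(treeText, allowPolytomy = allowPoly)

  sel <- vals[keys == "select"]
  if (!length(sel))
    stop("missing mandatory key 'select' in commands file", call. = FALSE)
  parts <- strsplit(sel, ":", fixed = TRUE)
  targets <- data.frame(
    reaction = vapply(parts, `[`, "", 1L),
    weight = as.numeric(vapply(parts, `[`, "", 2L)),
    multiplier = vapply(parts, function(x)
      if (length(x) >= 3L) as.numeric(x[3L]) else 1, numeric(1L)),
    stringsAsFactors = FALSE)
  badR <- setdiff(targets$reaction, reactionIds(model))
  if (length(badR))
    stop(sprintf("selection on reaction(s) absent from the model: %s",
                 paste(badR, collapse = ", ")), call. = FALSE)
  if (anyNA(targets$weight) || any(targets$weight <= 0))
    stop("selection weights must be positive numbers", call. = FALSE)
  if (any(targets$multiplier <= 0))
    stop("selection multipliers must be positive", call. = FALSE)
  targets$weight <- targets$weight / sum(targets$weight)

  ps <- vals[keys == "popsize"]
  if (!length(ps))
    stop("missing mandatory key 'popsize' in commands file", call. = FALSE)
  if (length(ps) == 1L && !grepl(":", ps, fixed = TRUE)) {
    popsize <- as.numeric(ps)
    if (is.na(popsize) || popsize < 1)
      stop("popsize must be a positive integer", call. = FALSE)
  } else {
    pp <- strsplit(ps, ":", fixed = TRUE)
    popsize <- stats::setNames(as.numeric(vapply(pp, `[`, "", 2L)),
                               vapply(pp, `[`, "", 1L))
    if (anyNA(popsize) || any(popsize < 1))
      stop("per-branch popsize entries must be positive integers",
           call. = FALSE)
  }

  ploidy <- as.integer(one("ploidy"))
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2", call. = FALSE)
  nSim <- as.integer(one("n_simulations", "1"))
  if (is.na(nSim) || nSim < 1L)
    stop("n_simulations must be >= 1", call. = FALSE)

  units <- one("units", "myr")
  if (!units %in% c("myr", "subs"))
    stop("units must be 'myr' or 'subs'", call. = FALSE)

  importRootPath <- one("import_root", NA_character_)
  if (!is.na(importRootPath)) importRootPath <- resolve(importRootPath)

  cfg <- list(
    model = model, tree = tree, targets = targets,
    popsize = popsize, ploidy = ploidy, units = units,
    nSimulations = nSim,
    seed = as.integer(one("seed", "1")),
    p = as.numeric(one("p", "0.5")),
    lambda = as.numeric(one("lambda", "0.003")),
    effectSD = as.numeric(one("effect_sd", "0.01")),
    steadyTolerance = as.numeric(one("steady_tolerance", "1e-9")),
    timeCap = as.numeric(one("time_cap", "1e6")),
    equilibration = equilibrationConfig(
      windowSize = as.integer(one("window_size", "100")),
      consecutiveWindows = as.integer(one("consecutive_windows", "5")),
      fluxFraction = as.numeric(one("flux_fraction", "0.8")),
      slopeTol = as.numeric(one("slope_tol", "1e-5")),
      cvTol = as.numeric(one("cv_tol", "0.01")),
      generationCap = as.numeric(one("generation_cap", "1e6"))),
    outdir = one("outdir", "fluxsel_out"),
    importRoot = importRootPath)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full pipeline
#'
#' Equilibrates the root (or imports an equilibrated root), calibrates the
#' generation scale from the equilibration's proposal counters, runs
#' \code{n_simulations} independent branching simulations over the tree
#' from the shared root, and writes the output file set.  Deterministic
#' given the seed.
#'
#' @param config a \code{"RunConfig"} from [parseCommandsFile()].
#' @param dryRun validate and simulate but write nothing (default FALSE).
#' @param quiet suppress progress messages (default TRUE).
#' @return invisibly, a summary list: the equilibrated \code{root}, the
#'   \code{scale}, per-simulation \code{runs}, and the reporter summary
#'   (\code{files}, \code{fixedEvents}).
#' @export
runPipeline <- function(config, dryRun = FALSE, quiet = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  model <- config$model
  say <- function(...) if (!quiet) message(sprintf(...))
  uniformNe <- if (is.null(names(config$popsize))) config$popsize else
    config$popsize[[1L]]
  if (!is.null(config$importRoot) && !is.na(config$importRoot)) {
    say("importing equilibrated root from %s", config$importRoot)
    root <- importRoot(config$importRoot, model)
  } else {
    say("equilibrating root population (seed %d)", config$seed)
    state <- initPopulation(model, config$targets, Ne = uniformNe,
                            ploidy = config$ploidy, p = config$p,
                            lambda = config$lambda,
                            effectSD = config$effectSD,
                            steadyTolerance = config$steadyTolerance,
                            timeCap = config$timeCap)
    root <- equilibrateRoot(state, model, config$equilibration,
                            seed = config$seed)
    say("equilibration: %g generations, criterion %s",
        root@generationsElapsed,
        if (root@criterionMet) "met" else "not met (cap)")
  }
  scale <- calibrateGenerationScale(root@counters,
                                    mutationPlan(model, config$lambda))
  say("generation scale: %g generations per Myr", scale@gUnit)
  runs <- vector("list", config$nSimulations)
  for (simIdx in seq_len(config$nSimulations)) {
    say("branching simulation %d/%d", simIdx, config$nSimulations)
    traces <- simulateTree(root, config$tree, model, scale,
                           units = config$units,
                           popsize = config$popsize,
                           seed = config$seed * 1000L + simIdx)
    lineages <- assembleLineages(config$tree, traces)
    runs[[simIdx]] <- list(traces = traces, lineages = lineages)
  }
  summary <- writeOutputs(runs, root, config$outdir, dryRun = dryRun)
  invisible(list(root = root, scale = scale, runs = runs,
                 summary = summary))
}
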