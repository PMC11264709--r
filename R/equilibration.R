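## Root-population burn-in to mutation-selection equilibrium.
##
## Stability is detected on non-overlapping windows of consecutive fixation
## events: within each window the least-squares slope (normalized by the
## window mean) and the coefficient of variation of the fitness series and
## of every reaction-flux series are computed; equilibrium is declared when
## fitness and at least a configurable fraction (default 80%) of the flux
## series are flat over a configurable number (default 5) of consecutive
## windows.  Once the criterion is met at generation g, equilibration
## continues for another g generations (total 2g) before returning.

#' Equilibration configuration
#'
#' @param windowSize fixation events per window (default 100).
#' @param consecutiveWindows windows that must all be flat (default 5).
#' @param fluxFraction fraction of flux series required flat (default 0.8).
#' @param slopeTol tolerance on the mean-normalized per-fixation slope
#'   (default 1e-5).
#' @param cvTol tolerance on the within-window coefficient of variation
#'   (default 0.01).
#' @param generationCap hard cap on equilibration generations
#'   (default 1e6); when hit first, branching proceeds from the capped
#'   state.
#' @return list of class \code{"EquilibrationConfig"}.
#' @export
equilibrationConfig <- function(windowSize = 100L, consecutiveWindows = 5L,
                                fluxFraction = 0.8, slopeTol = 1e-5,
                                cvTol = 0.01, generationCap = 1e6) {
  stopifnot(windowSize >= 2, consecutiveWindows >= 1,
            fluxFraction > 0, fluxFraction <= 1,
            slopeTol > 0, cvTol > 0, generationCap >= 0)
  structure(list(windowSize = as.integer(windowSize),
                 consecutiveWindows = as.integer(consecutiveWindows),
                 fluxFraction = fluxFraction, slopeTol = slopeTol,
                 cvTol = cvTol, generationCap = generationCap),
            class = "EquilibrationConfig")
}

#' Windowed flatness statistics of a fixation series
#'
#' Splits a series of values recorded at consecutive fixation events into
#' non-overlapping windows of \code{windowSize} and returns, per window,
#' the ordinary least-squares slope over (index, value) divided by the
#' window mean, and the coefficient of variation sd/mean.  A window with
#' mean 0 gets NA statistics and counts as unstable.  The mean
#' normalization makes the verdicts invariant to rescaling the series.
#'
#' @param series numeric values at fixation events.
#' @param windowSize window length in fixations.
#' @return data.frame(window, slope, cv); zero rows if the series is
#'   shorter than one window.
#' @export
windowStatistics <- function(series, windowSize) {
  stopifnot(windowSize >= 2)
  nw <- length(series) %/% windowSize
  if (nw == 0L)
    return(data.frame(window = integer(), slope = numeric(),
                      cv = numeric()))
  idx <- seq_len(windowSize)
  sxx <- sum((idx - mean(idx))^2)
  out <- data.frame(window = seq_len(nw), slope = NA_real_, cv = NA_real_)
  for (w in seq_len(nw)) {
    y <- series[((w - 1L) * windowSize + 1L):(w * windowSize)]
    m <- mean(y)
    if (m == 0) next
    b <- sum((idx - mean(idx)) * (y - m)) / sxx
    out$slope[w] <- b / m
    out$cv[w] <- sd(y) / m
  }
  out
}

#' Has the windowed stability criterion been met?
#'
#' @param stats named list of [windowStatistics()] tables; must contain an
#'   element \code{"fitness"}, all other elements are treated as flux
#'   series.
#' @param config an [equilibrationConfig()].
#' @return TRUE iff fitness and at least \code{fluxFraction} of the flux
#'   series each have |slope| <= slopeTol and |cv| <= cvTol in the most
#'   recent \code{consecutiveWindows} complete windows.
#' @export
equilibriumReached <- function(stats, config) {
  k <- config$consecutiveWindows
  flat <- function(df) {
    if (nrow(df) < k) return(FALSE)
    recent <- df[(nrow(df) - k + 1L):nrow(df), ]
    all(is.finite(recent$slope) & is.finite(recent$cv) &
        abs(recent$slope) <= config$slopeTol &
        abs(recent$cv) <= config$cvTol)
  }
  if (!"fitness" %in% names(stats))
    stop("stats must contain a 'fitness' series", call. = FALSE)
  if (!flat(stats[["fitness"]])) return(FALSE)
  fluxStats <- stats[names(stats) != "fitness"]
  if (!length(fluxStats)) return(TRUE)
  mean(vapply(fluxStats, flat, logical(1L))) >= config$fluxFraction
}

#' Equilibrate the root population
#'
#' Runs mutation-selection on the root until the windowed stability
#' criterion is met at some generation g, then continues for another g
#' generations (total 2g), accumulating per-reaction per-category proposal
#' counters throughout for the branch-length calibration.  If the
#' generation cap is hit first, the root is returned with
#' \code{capReached = TRUE}.
#'
#' @param state a [PopulationState-class] from [initPopulation()] (the
#'   model must reach steady state at its original parameters, which
#'   [initPopulation()] enforces).
#' @param model the prepared model.
#' @param config an [equilibrationConfig()].
#' @param seed optional integer seed set before the run.
#' @param resumeFrom optional [EquilibratedRoot-class] to continue from:
#'   parameter state, counters, generation count and RNG state are restored
#'   and equilibration proceeds (the import-and-equilibrate-further
#'   workflow).
#' @return an [EquilibratedRoot-class].
#' @export
equilibrateRoot <- function(state, model, config = equilibrationConfig(),
                            seed = NULL, resumeFrom = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counters <- list()
  fixMat <- NULL   # rows: fixations; cols: fitness + fluxes
  if (!is.null(resumeFrom)) {
    state <- rootToState(resumeFrom, model,
                         restoreRNG = is.null(seed))
    if (nrow(resumeFrom@counters)) counters <- list(resumeFrom@counters)
  } else if (!exists(".Random.seed", envir = globalenv())) {
    ## materialize .Random.seed so the snapshot can capture it
    invisible(runif(1))
  }
  detection <- NA_real_
  extra <- 0
  nfix <- 0L
  gen0 <- state@generationsElapsed
  capReached <- FALSE
  repeat {
    if (state@generationsElapsed - gen0 >= config$generationCap &&
        is.na(detection)) {
      capReached <- TRUE
      break
    }
    if (!is.na(detection) && extra <= 0) break
    stepRes <- generationStep(state, model)
    state <- stepRes$state
    if (!is.na(detection)) extra <- extra - 1
    if (is.null(stepRes$event)) next
    pr <- stepRes$proposals
    agg <- stats::aggregate(list(n = rep(1L, nrow(pr))),
                            by = list(reaction = pr$reaction,
                                      category = pr$category), FUN = sum)
    agg$generation <- stepRes$event$generation
    counters[[length(counters) + 1L]] <- agg
    if (stepRes$event$fixed) {
      row <- c(fitness = state@fitness, state@fluxes)
      fixMat <- if (is.null(fixMat)) matrix(row, nrow = 1,
                                            dimnames = list(NULL, names(row)))
                else rbind(fixMat, row)
      nfix <- nfix + 1L
      if (is.na(detection) &&
          nfix %% config$windowSize == 0L &&
          nfix >= config$windowSize * config$consecutiveWindows) {
        stats <- lapply(seq_len(ncol(fixMat)), function(j)
          windowStatistics(fixMat[, j], config$windowSize))
        names(stats) <- colnames(fixMat)
        if (equilibriumReached(stats, config)) {
          detection <- state@generationsElapsed - gen0
          extra <- detection
        }
      }
    }
  }
  counters <- if (length(counters)) {
    ct <- do.call(rbind, counters)
    ct[, c("generation", "reaction", "category", "n")]
  } else data.frame(generation = numeric(), reaction = character(),
                    category = character(), n = integer(),
                    stringsAsFactors = FALSE)
  new("EquilibratedRoot",
      parameterValues = state@parameterValues,
      concentrations = state@concentrations,
      fluxes = state@fluxes,
      startFluxes = state@startFluxes,
      fitness = state@fitness,
      targets = state@targets,
      generationsElapsed = state@generationsElapsed,
      counters = counters,
      criterionMet = !is.na(detection),
      capReached = capReached,
      rngState = get(".Random.seed", envir = globalenv()),
      settings = list(Ne = state@Ne, ploidy = state@ploidy, p = state@p,
                      lambda = state@lambda, effectSD = state@effectSD,
                      steadyTolerance = state@steadyTolerance,
                      timeCap = state@timeCap))
}

#' Rebuild a PopulationState from an equilibrated root
#'
#' @param root an [EquilibratedRoot-class].
#' @param model the prepared model; every parameter id of the root must
#'   exist in the model (a mismatch errors naming the id).
#' @param restoreRNG restore the snapshot's RNG state (default TRUE).
#' @param Ne optional override of the population size (used per branch).
#' @return a [PopulationState-class].
#' @export
rootToState <- function(root, model, restoreRNG = TRUE, Ne = NULL) {
  missing <- setdiff(names(root@parameterValues),
                     model@parameters$id)
  if (length(missing))
    stop(sprintf("root snapshot does not match the model; unknown parameter(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  missing2 <- setdiff(model@parameters$id, names(root@parameterValues))
  if (length(missing2))
    stop(sprintf("root snapshot is missing parameter(s): %s",
                 paste(missing2, collapse = ", ")), call. = FALSE)
  if (restoreRNG)
    assign(".Random.seed", root@rngState, envir = globalenv())
  st <- root@settings
  new("PopulationState",
      parameterValues = root@parameterValues,
      concentrations = root@concentrations,
      fluxes = root@fluxes,
      startFluxes = root@startFluxes,
      targets = root@targets,
      fitness = root@fitness,
      Ne = as.numeric(if (is.null(Ne)) st$Ne else Ne),
      ploidy = as.integer(st$ploidy), p = st$p,
      plan = mutationPlan(model, st$lambda),
      effectSD = st$effectSD, lambda = st$lambda,
      steadyTolerance = st$steadyTolerance, timeCap = st$timeCap,
      generationsElapsed = root@generationsElapsed)
}

FMT <- "%.17g"

#' Export / import an equilibrated root snapshot
#'
#' Lossless plain-text round trip of an [EquilibratedRoot-class], including
#' the proposal counters and the RNG state, so an equilibration can be
#' reused for any tree with the same starting population parameters, or
#' continued.
#'
#' @param root an [EquilibratedRoot-class].
#' @param path output file path.
#' @return \code{exportRoot} the path, invisibly; \code{importRoot} the
#'   reconstructed [EquilibratedRoot-class].
#' @export
exportRoot <- function(root, path) {
  num <- function(x) sprintf(FMT, x)
  kv <- function(vec) sprintf("%s\t%s", names(vec), num(vec))
  st <- root@settings
  out <- c(
    "fluxsel_root\tv1",
    sprintf("generations_elapsed\t%s", num(root@generationsElapsed)),
    sprintf("fitness\t%s", num(root@fitness)),
    sprintf("criterion_met\t%d", as.integer(root@criterionMet)),
    sprintf("cap_reached\t%d", as.integer(root@capReached)),
    sprintf("ne\t%s", num(st$Ne)),
    sprintf("ploidy\t%d", st$ploidy),
    sprintf("p\t%s", num(st$p)),
    sprintf("lambda\t%s", num(st$lambda)),
    sprintf("effect_sd\t%s", num(st$effectSD)),
    sprintf("steady_tolerance\t%s", num(st$steadyTolerance)),
    sprintf("time_cap\t%s", num(st$timeCap)),
    "[parameters]", kv(root@parameterValues),
    "[concentrations]", kv(root@concentrations),
    "[fluxes]", kv(root@fluxes),
    "[start_fluxes]", kv(root@startFluxes),
    "[targets]",
    sprintf("%s\t%s\t%s", root@targets$reaction, num(root@targets$weight),
            num(root@targets$multiplier)),
    "[counters]",
    if (nrow(root@counters))
      sprintf("%s\t%s\t%s\t%d", num(root@counters$generation),
              root@counters$reaction, root@counters$category,
              root@counters$n) else character(),
    "[rng_state]",
    paste(root@rngState, collapse = ","))
  writeLines(out, path)
  invisible(path)
}

#' @rdname exportRoot
#' @param model optional [KineticModel-class] to validate the snapshot's
#'   parameter ids against (a missing id errors naming it).
#' @export
importRoot <- function(path, model = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "fluxsel_root\tv1"))
    stop("not a fluxsel root snapshot (bad header/version)", call. = FALSE)
  secStarts <- grep("^\\[", lines)
  header <- lines[2:(if (length(secStarts)) secStarts[1L] - 1L else length(lines))]
  hv <- strsplit(header, "\t", fixed = TRUE)
  hmap <- stats::setNames(vapply(hv, `[`, "", 2L), vapply(hv, `[`, "", 1L))
  section <- function(name) {
    i <- which(lines == paste0("[", name, "]"))
    if (!length(i)) return(character())
    j <- secStarts[secStarts > i]
    end <- if (length(j)) j[1L] - 1L else length(lines)
    if (end < i + 1L) return(character())
    lines[(i + 1L):end]
  }
  readVec <- function(name) {
    rows <- strsplit(section(name), "\t", fixed = TRUE)
    stats::setNames(as.numeric(vapply(rows, `[`, "", 2L)),
                    vapply(rows, `[`, "", 1L))
  }
  tg <- strsplit(section("targets"), "\t", fixed = TRUE)
  targets <- data.frame(
    reaction = vapply(tg, `[`, "", 1L),
    weight = as.numeric(vapply(tg, `[`, "", 2L)),
    multiplier = as.numeric(vapply(tg, `[`, "", 3L)),
    stringsAsFactors = FALSE)
  ctLines <- section("counters")
  counters <- if (length(ctLines)) {
    ct <- strsplit(ctLines, "\t", fixed = TRUE)
    data.frame(generation = as.numeric(vapply(ct, `[`, "", 1L)),
               reaction = vapply(ct, `[`, "", 2L),
               category = vapply(ct, `[`, "", 3L),
               n = as.integer(vapply(ct, `[`, "", 4L)),
               stringsAsFactors = FALSE)
  } else data.frame(generation = numeric(), reaction = character(),
                    category = character(), n = integer(),
                    stringsAsFactors = FALSE)
  params <- readVec("parameters")
  if (!is.null(model)) {
    missing <- setdiff(model@parameters$id, names(params))
    extra <- setdiff(names(params), model@parameters$id)
    if (length(c(missing, extra)))
      stop(sprintf("root snapshot does not match the model (missing: %s; unknown: %s)",
                   paste(missing, collapse = ", "),
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  new("EquilibratedRoot",
      parameterValues = params,
      concentrations = readVec("concentrations"),
      fluxes = readVec("fluxes"),
      startFluxes = readVec("start_fluxes"),
      fitness = as.numeric(hmap[["fitness"]]),
      targets = targets,
      generationsElapsed = as.numeric(hmap[["generations_elapsed"]]),
      counters = counters,
      criterionMet = hmap[["criterion_met"]] == "1",
      capReached = hmap[["cap_reached"]] == "1",
      rngState = as.integer(strsplit(section("rng_state"), ",",
                                     fixed = TRUE)[[1L]]),
      settings = list(Ne = as.numeric(hmap[["ne"]]),
                      ploidy = as.integer(hmap[["ploidy"]]),
                      p = as.numeric(hmap[["p"]]),
                      lambda = as.numeric(hmap[["lambda"]]),
                      effectSD = as.numeric(hmap[["effect_sd"]]),
                      steadyTolerance = as.numeric(hmap[["steady_tolerance"]]),
                      timeCap = as.numeric(hmap[["time_cap"]])))
}
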