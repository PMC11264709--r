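## Tabular outputs: mutation logs, lineage/branch trajectories, and
## percent-change matrices with column-wise normalization, plus
## cross-replicate averaging.  TSV is the canonical output format (UTF-8,
## '.' decimal separator, 17 significant digits); a manifest lists every
## file with its md5 checksum.

#' Percent change between a start and an end value
#'
#' \eqn{100 (end - start)/start}; a zero start value yields \code{NA} (the
#' cell is flagged undefined and excluded from normalization).
#'
#' @param start,end numeric (vectorized).
#' @return percent change.
#' @export
percentChange <- function(start, end) {
  out <- 100 * (end - start) / start
  out[start == 0] <- NA_real_
  out
}

#' Normalize a percent-change matrix column-wise
#'
#' Each cell is divided by the maximum absolute value of its column, so
#' positive values fall in [0, 1] and negative values in [-1, 0]; an
#' all-zero (or all-NA) column stays zero; signs are preserved cell-wise.
#'
#' @param m numeric matrix (NA cells allowed; they stay NA).
#' @return normalized matrix of the same shape.
#' @export
normalizeColumns <- function(m) {
  for (j in seq_len(ncol(m))) {
    mx <- suppressWarnings(max(abs(m[, j]), na.rm = TRUE))
    if (is.finite(mx) && mx > 0) m[, j] <- m[, j] / mx
    else m[!is.na(m[, j]), j] <- 0
  }
  m
}

#' Average percent-change matrices across replicate simulations
#'
#' Cell-wise arithmetic mean of the raw percent changes; inputs must share
#' identical row and column labels.  Normalize the result with
#' [normalizeColumns()] if a normalized average is wanted (averaging
#' happens on the raw percents, before any normalization).
#'
#' @param matrices list of matrices with identical dimnames.
#' @return the averaged matrix.
#' @export
averageReplicates <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ref <- dimnames(matrices[[1L]])
  for (m in matrices[-1L])
    if (!identical(dimnames(m), ref))
      stop("replicate matrices have mismatched row/column labels",
           call. = FALSE)
  Reduce(`+`, matrices) / length(matrices)
}

## columns of the change matrix: fitness, per-reaction fluxes, steady-state
## concentrations, parameter values
stateColumns <- function(fitness, fluxes, concentrations, parameterValues) {
  c(fitness = fitness,
    stats::setNames(fluxes, paste0("flux_", names(fluxes))),
    stats::setNames(concentrations, paste0("conc_", names(concentrations))),
    parameterValues)
}

#' Percent-change matrix over lineages or branches
#'
#' Rows are lineages (external nodes) or branches; columns are all model
#' values (fitness, fluxes, steady-state concentrations, parameters).
#' Cells are the percent change from the equilibrated root's values to the
#' values at the end of the lineage/branch.
#'
#' @param root an [EquilibratedRoot-class].
#' @param traces output of [simulateTree()] (for \code{by = "branch"}) or
#'   [assembleLineages()] (for \code{by = "lineage"}).
#' @param by \code{"lineage"} or \code{"branch"}.
#' @return numeric matrix of raw percent changes.
#' @export
buildChangeMatrix <- function(root, traces, by = c("lineage", "branch")) {
  by <- match.arg(by)
  startCols <- stateColumns(root@fitness, root@fluxes,
                            root@concentrations, root@parameterValues)
  rows <- lapply(traces, function(tr) {
    es <- tr$endState
    endCols <- stateColumns(es$fitness, es$fluxes, es$concentrations,
                            es$parameterValues)
    percentChange(startCols, endCols[names(startCols)])
  })
  labels <- if (by == "lineage") names(traces) else
    vapply(traces, function(tr) sprintf("branch%d_%s", tr$branch, tr$label),
           character(1L))
  m <- do.call(rbind, rows)
  dimnames(m) <- list(labels, names(startCols))
  m
}

fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

## TSV writer with deterministic full-precision formatting
writeTSV <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]])) df2[[j]] <- fmtNum(df2[[j]])
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  path
}

writeMatrixTSV <- function(m, path) {
  df <- data.frame(row = rownames(m),
                   apply(m, 2L, fmtNum, simplify = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  path
}

#' Read back a matrix TSV written by the reporter
#'
#' @param path file written by [writeOutputs()] (a \code{change_*} table).
#' @return numeric matrix with row/column labels.
#' @export
readMatrixTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

mutationLogColumns <- c("sim", "branch", "generation", "parameter",
                        "old_value", "new_value", "effect",
                        "haldane_partner", "s", "pfix", "fixed",
                        "fitness_before", "fitness_after")

formatMutationLog <- function(mutations, sim, branch) {
  if (is.null(mutations) || !nrow(mutations))
    return(stats::setNames(
      data.frame(matrix(ncol = length(mutationLogColumns), nrow = 0)),
      mutationLogColumns))
  data.frame(sim = sim, branch = branch,
             generation = mutations$generation,
             parameter = mutations$param,
             old_value = mutations$old_value,
             new_value = mutations$new_value,
             effect = mutations$effect,
             haldane_partner = mutations$haldane_partner,
             s = mutations$s, pfix = mutations$pfix,
             fixed = mutations$fixed,
             fitness_before = mutations$fitness_before,
             fitness_after = mutations$fitness_after,
             stringsAsFactors = FALSE)
}

#' Write the canonical output file set of one or more branching runs
#'
#' Produces, per replicate simulation: the full mutation log (fixed and
#' unfixed proposals), one trajectory TSV per branch and per lineage, and
#' raw plus normalized percent-change matrices for lineages and branches.
#' With several replicates an averaged (then normalized) matrix pair is
#' added.  A manifest lists every file with its md5 checksum.  File names
#' are deterministic; numbers are written at full double precision so
#' identical runs produce byte-identical files.
#'
#' @param runs list of replicate results; each element is a list with
#'   \code{traces} ([simulateTree()]) and \code{lineages}
#'   ([assembleLineages()]).
#' @param root the shared [EquilibratedRoot-class].
#' @param dir output directory (created if needed).
#' @param dryRun if TRUE nothing is written; the summary is returned.
#' @return invisibly, a summary list: \code{files} (manifest data.frame),
#'   \code{fixedEvents} total fixed-event count, \code{nSims}.
#' @export
writeOutputs <- function(runs, root, dir, dryRun = FALSE) {
  if (!dryRun) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  totalFixed <- 0L
  lineageMats <- list(); branchMats <- list()
  emit <- function(writer, obj, name) {
    path <- file.path(dir, name)
    if (!dryRun) writer(obj, path)
    files[[length(files) + 1L]] <<- name
  }
  for (simIdx in seq_along(runs)) {
    run <- runs[[simIdx]]
    logs <- list()
    for (tr in run$traces) {
      logs[[length(logs) + 1L]] <-
        formatMutationLog(tr$mutations, simIdx, tr$branch)
      if (!is.null(tr$mutations))
        totalFixed <- totalFixed +
          sum(tr$mutations$fixed[!duplicated(tr$mutations$generation)])
      if (!is.null(tr$trace))
        emit(writeTSV, tr$trace,
             sprintf("branch_%d_%s_sim%d.tsv", tr$branch, tr$label, simIdx))
    }
    emit(writeTSV, do.call(rbind, logs), sprintf("mutations_sim%d.tsv", simIdx))
    for (nm in names(run$lineages)) {
      ln <- run$lineages[[nm]]
      if (!is.null(ln$trace))
        emit(writeTSV, ln$trace, sprintf("lineage_%s_sim%d.tsv", nm, simIdx))
    }
    lm <- buildChangeMatrix(root, run$lineages, by = "lineage")
    bm <- buildChangeMatrix(root, run$traces, by = "branch")
    lineageMats[[simIdx]] <- lm; branchMats[[simIdx]] <- bm
    emit(writeMatrixTSV, lm, sprintf("change_lineages_raw_sim%d.tsv", simIdx))
    emit(writeMatrixTSV, normalizeColumns(lm),
         sprintf("change_lineages_norm_sim%d.tsv", simIdx))
    emit(writeMatrixTSV, bm, sprintf("change_branches_raw_sim%d.tsv", simIdx))
    emit(writeMatrixTSV, normalizeColumns(bm),
         sprintf("change_branches_norm_sim%d.tsv", simIdx))
  }
  if (length(runs) > 1L) {
    avgL <- averageReplicates(lineageMats)
    avgB <- averageReplicates(branchMats)
    emit(writeMatrixTSV, avgL, "change_lineages_raw_avg.tsv")
    emit(writeMatrixTSV, normalizeColumns(avgL), "change_lineages_norm_avg.tsv")
    emit(writeMatrixTSV, avgB, "change_branches_raw_avg.tsv")
    emit(writeMatrixTSV, normalizeColumns(avgB), "change_branches_norm_avg.tsv")
  }
  files <- unlist(files)
  manifest <- data.frame(file = files, stringsAsFactors = FALSE)
  if (!dryRun) {
    manifest$md5 <- unname(tools::md5sum(file.path(dir, files)))
    write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(list(files = manifest, fixedEvents = totalFixed,
                 nSims = length(runs)))
}
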