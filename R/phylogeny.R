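## Phylogeny handling: Newick parsing (via ape), branch-length calibration
## to generation counts, recursive branch simulation, lineage assembly.
##
## Calibration rests on the two-percent rule (diverging vertebrate lineages
## accumulate ~1% sequence difference per lineage per million years), a
## typical enzyme gene exposing ~250 amino-acid sites to the functional
## effect distribution and ~250 expression-affecting sites: the generation
## count at which an across-reaction average of 7 proposals has accrued in
## BOTH categories during equilibration is taken as the number of
## generations per million years (equivalently per 1% divergence).

#' Parse a rooted Newick tree
#'
#' Wraps the standard Newick grammar and enforces this simulator's
#' contract: the tree is rooted (exactly two children at the root), every
#' edge carries a branch length, and polytomies below the root require
#' \code{allowPolytomy = TRUE}.
#'
#' @param text Newick string (trailing semicolon required) or path to a
#'   file containing one.
#' @param allowPolytomy tolerate multifurcations below the root
#'   (default FALSE).
#' @return an \code{ape} \code{phylo} object.
#' @export
parseNewickTree <- function(text, allowPolytomy = FALSE) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick string: missing trailing ';'", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e)
                     stop(sprintf("malformed Newick string: %s",
                                  conditionMessage(e)), call. = FALSE))
  if (is.null(tree))
    stop("malformed Newick string: could not be parsed", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("every edge must carry a branch length", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length", call. = FALSE)
  rootNode <- ape::Ntip(tree) + 1L
  degRoot <- sum(tree$edge[, 1L] == rootNode)
  if (degRoot != 2L)
    stop(sprintf("tree must be rooted: the root has %d children, expected 2",
                 degRoot), call. = FALSE)
  if (!allowPolytomy) {
    internal <- tabulate(tree$edge[, 1L])
    poly <- which(internal > 2L)
    poly <- setdiff(poly, rootNode)
    if (length(poly))
      stop("tree contains polytomies below the root; set allowPolytomy = TRUE to simulate them",
           call. = FALSE)
  }
  tree
}

#' Calibrate the generation scale from equilibration counters
#'
#' Finds, separately for the enzyme-concentration and the functional
#' parameter category, the smallest generation at which the across-reaction
#' average cumulative proposal count reaches 7; the scale is the larger of
#' the two crossings (both categories must have accrued 7).
#'
#' @param counters data.frame(generation, reaction, category, n) as
#'   accumulated by [equilibrateRoot()].
#' @param plan the mutation plan (defines which reactions participate in
#'   each category); see [mutationPlan()].
#' @param threshold proposals per reaction required (default 7).
#' @return a [GenerationScale-class].
#' @export
calibrateGenerationScale <- function(counters, plan, threshold = 7) {
  crossing <- c(E = NA_real_, functional = NA_real_)
  for (cat in names(crossing)) {
    nre <- length(unique(plan$reaction[plan$category == cat &
                                       !is.na(plan$reaction)]))
    if (nre == 0L) next
    sub <- counters[counters$category == cat, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$generation), , drop = FALSE]
    avg <- cumsum(sub$n) / nre
    hit <- which(avg >= threshold)
    if (length(hit)) crossing[cat] <- sub$generation[hit[1L]]
  }
  present <- c(E = any(plan$category == "E"),
               functional = any(plan$category == "functional"))
  need <- names(crossing)[present]
  if (any(is.na(crossing[need])))
    stop(sprintf(
      "equilibration too short to calibrate: the across-reaction average did not reach %g proposals in category '%s'; equilibrate longer",
      threshold, paste(need[is.na(crossing[need])], collapse = "', '")),
      call. = FALSE)
  gUnit <- max(crossing[need])
  new("GenerationScale", gUnit = max(gUnit, 1), crossing = crossing[need])
}

#' Convert a branch length to a generation count
#'
#' Lengths in millions of years are multiplied by the generation scale;
#' lengths in substitutions per site are first converted to percent
#' divergence (factor 100).  Results are rounded half-up; a branch that
#' rounds to 0 is simulated for 0 generations.
#'
#' @param length non-negative branch length.
#' @param units \code{"myr"} or \code{"subs"} (substitutions per site).
#' @param scale a [GenerationScale-class] or a bare numeric generations-
#'   per-Myr value.
#' @param round round to an integer count (default TRUE).
#' @return generation count (numeric).
#' @export
branchGenerations <- function(length, units = c("myr", "subs"), scale,
                              round = TRUE) {
  units <- match.arg(units)
  if (any(length < 0)) stop("negative branch length", call. = FALSE)
  g <- if (is(scale, "GenerationScale")) scale@gUnit else as.numeric(scale)
  out <- length * g * if (units == "subs") 100 else 1
  if (round) floor(out + 0.5) else out
}

## deterministic per-branch seed derived from (seed, branch path); keeps
## sibling branches statistically independent and any branch replayable
deriveSeed <- function(seed, path) {
  key <- paste0("b", seed, "/", path)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483587
  as.integer(h + 1L)
}

nodeLabels <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  labs <- character(ntip + nn)
  labs[seq_len(ntip)] <- tree$tip.label
  inner <- if (!is.null(tree$node.label)) tree$node.label else
    rep("", nn)
  blank <- is.na(inner) | inner == ""
  inner[blank] <- paste0("node", ntip + which(blank))
  labs[ntip + seq_len(nn)] <- inner
  labs
}

#' Simulate evolution along every branch of the tree
#'
#' Depth-first recursion from the equilibrated root: each branch is
#' simulated for its calibrated generation count with its own effective
#' population size, children inherit their parent's final parameter state
#' bit-identically, and every branch gets an independent RNG stream derived
#' deterministically from the run seed and the branch path.  No
#' re-equilibration is attempted after a population-size change.
#'
#' @param root an [EquilibratedRoot-class].
#' @param tree a rooted \code{phylo} from [parseNewickTree()].
#' @param model the prepared model.
#' @param scale a [GenerationScale-class] (or numeric generations/Myr).
#' @param units branch-length units, \code{"myr"} or \code{"subs"}.
#' @param popsize a single effective population size for the whole tree, or
#'   a named vector addressing branches by the label of their child node
#'   (tip labels; unlabeled internal nodes are auto-labelled
#'   \code{node<k>}); in named mode a branch without an entry is an error.
#' @param seed integer run seed.
#' @return list of branch traces keyed by child-node id
#'   (\code{branch<node>}); each has \code{branch}, \code{label},
#'   \code{parent}, \code{Ne}, \code{generations}, \code{inheritedValues},
#'   \code{events}, \code{mutations}, \code{trace} and \code{endState}.
#'   The tree and scale ride along as attributes.
#' @export
simulateTree <- function(root, tree, model, scale, units = "myr",
                         popsize, seed = 1L) {
  ntip <- ape::Ntip(tree)
  labs <- nodeLabels(tree)
  lookupNe <- function(node) {
    if (length(popsize) == 1L && is.null(names(popsize)))
      return(as.numeric(popsize))
    lab <- labs[node]
    if (!lab %in% names(popsize))
      stop(sprintf("no population size given for branch '%s'", lab),
           call. = FALSE)
    as.numeric(popsize[[lab]])
  }
  traces <- list()
  recurse <- function(node, startValues, startConc, startFluxes0,
                      startFitness, path) {
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    for (i in seq_along(children)) {
      child <- children[i]
      len <- tree$edge.length[which(tree$edge[, 1L] == node &
                                    tree$edge[, 2L] == child)]
      gens <- branchGenerations(len, units, scale)
      childPath <- if (path == "") as.character(i) else
        paste(path, i, sep = ".")
      set.seed(deriveSeed(seed, childPath))
      state <- rootToState(root, model, restoreRNG = FALSE,
                           Ne = lookupNe(child))
      state@parameterValues <- startValues
      state@concentrations <- startConc
      state@fluxes <- startFluxes0
      state@fitness <- startFitness
      state@generationsElapsed <- 0
      sim <- simulateGenerations(state, model, gens)
      traces[[paste0("branch", child)]] <<- list(
        branch = child,
        label = labs[child],
        parent = node,
        path = childPath,
        Ne = state@Ne,
        generations = gens,
        inheritedValues = startValues,
        events = sim$events,
        mutations = sim$mutations,
        trace = sim$trace,
        endState = list(parameterValues = sim$state@parameterValues,
                        concentrations = sim$state@concentrations,
                        fluxes = sim$state@fluxes,
                        fitness = sim$state@fitness))
      if (child > ntip)
        recurse(child, sim$state@parameterValues,
                sim$state@concentrations, sim$state@fluxes,
                sim$state@fitness, childPath)
    }
  }
  recurse(ape::Ntip(tree) + 1L, root@parameterValues, root@concentrations,
          root@fluxes, root@fitness, "")
  attr(traces, "tree") <- tree
  attr(traces, "scale") <- if (is(scale, "GenerationScale")) scale@gUnit
                           else as.numeric(scale)
  attr(traces, "units") <- units
  traces
}

#' Assemble per-external-node lineages from branch traces
#'
#' A lineage concatenates the branch simulations on the path from the root
#' to one external node; generation indices are offset cumulatively so they
#' increase strictly along the lineage.  Lineages are numbered by the
#' branch number of their terminal (external) node.
#'
#' @param tree the \code{phylo} the traces were simulated on.
#' @param traces output of [simulateTree()].
#' @return named list (one element per tip label); each has \code{lineage}
#'   (terminal node number), \code{branches} (child-node path),
#'   \code{generations}, concatenated \code{mutations} and \code{trace}
#'   tables (with a \code{branch} column), and \code{endState}.
#' @export
assembleLineages <- function(tree, traces) {
  ntip <- ape::Ntip(tree)
  rootNode <- ntip + 1L
  parentOf <- integer(max(tree$edge))
  parentOf[tree$edge[, 2L]] <- tree$edge[, 1L]
  out <- list()
  for (tip in seq_len(ntip)) {
    pathNodes <- tip
    node <- tip
    while (node != rootNode) {
      node <- parentOf[node]
      pathNodes <- c(node, pathNodes)
    }
    branchNodes <- pathNodes[-1L]   # child node of each edge, root-to-tip
    offset <- 0
    muts <- list(); trs <- list()
    for (b in branchNodes) {
      tr <- traces[[paste0("branch", b)]]
      if (!is.null(tr$mutations)) {
        m <- tr$mutations
        m$generation <- m$generation + offset
        m$branch <- b
        muts[[length(muts) + 1L]] <- m
      }
      if (!is.null(tr$trace)) {
        t2 <- tr$trace
        t2$generation <- t2$generation + offset
        t2$branch <- b
        trs[[length(trs) + 1L]] <- t2
      }
      offset <- offset + tr$generations
    }
    terminal <- traces[[paste0("branch", tip)]]
    out[[tree$tip.label[tip]]] <- list(
      lineage = tip,
      branches = branchNodes,
      generations = offset,
      mutations = if (length(muts)) do.call(rbind, muts) else NULL,
      trace = if (length(trs)) do.call(rbind, trs) else NULL,
      endState = terminal$endState)
  }
  out
}
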