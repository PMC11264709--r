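#' @import methods
#' @importFrom stats rpois rnorm runif sd lm coef
#' @importFrom utils head tail write.table read.table
NULL

PARAM_ROLES <- c("forward_max_velocity", "reverse_max_velocity",
                 "catalytic_constant", "reverse_catalytic_constant",
                 "binding_constant", "equilibrium_constant",
                 "enzyme_concentration", "other")

#' Kinetic metabolic model
#'
#' An S4 container for an ODE-based kinetic model: species with initial
#' concentrations (boundary species are held constant), reactions with
#' stoichiometry and an explicit kinetic rate law stored as an expression
#' tree, a parameter table with biochemical role annotations, and the
#' Haldane-constrained parameter groups of reversible reactions.
#'
#' @slot species data.frame with columns \code{id}, \code{initial_concentration},
#'   \code{is_boundary}.
#' @slot reactions list; each element has \code{id}, \code{substrates} and
#'   \code{products} (data.frames with columns \code{species}, \code{stoich}),
#'   \code{modifiers} (character), \code{rate} (a quoted R expression over
#'   species and parameter ids) and \code{rate_text}.
#' @slot parameters data.frame with columns \code{id}, \code{value},
#'   \code{scope} (\code{"global"} or a reaction id), \code{role},
#'   \code{mutable}.
#' @slot haldaneGroups list of Haldane groups (see [buildHaldaneGroups()]).
#' @slot units opaque unit annotation strings.
#'
#' @seealso [parseNativeModel()], [parseSBML()], [prepareModel()]
#' @export
setClass("KineticModel",
  representation(
    species = "data.frame",
    reactions = "list",
    parameters = "data.frame",
    haldaneGroups = "list",
    units = "character"
  ),
  prototype(haldaneGroups = list(), units = character())
)

validKineticModel <- function(object) {
  msg <- character()
  sp <- object@species
  pr <- object@parameters
  if (anyDuplicated(sp$id)) msg <- c(msg, "duplicated species ids")
  if (anyDuplicated(pr$id)) msg <- c(msg, "duplicated parameter ids")
  if (length(intersect(sp$id, pr$id)))
    msg <- c(msg, "species and parameter ids overlap")
  if (length(object@reactions) < 1) msg <- c(msg, "model has no reactions")
  if (any(sp$initial_concentration < 0))
    msg <- c(msg, "negative initial concentration")
  if (nrow(pr) && any(pr$mutable & pr$value <= 0))
    msg <- c(msg, "mutable parameter with non-positive value")
  rid <- vapply(object@reactions, `[[`, "", "id")
  if (anyDuplicated(rid)) msg <- c(msg, "duplicated reaction ids")
  known <- c(sp$id, pr$id)
  for (rxn in object@reactions) {
    used <- exprIdentifiers(rxn$rate)
    bad <- setdiff(used, known)
    if (length(bad))
      msg <- c(msg, sprintf("reaction '%s' references undeclared id(s): %s",
                            rxn$id, paste(bad, collapse = ", ")))
    for (side in list(rxn$substrates, rxn$products)) {
      if (nrow(side)) {
        if (any(!side$species %in% sp$id))
          msg <- c(msg, sprintf("reaction '%s' uses unknown species", rxn$id))
        if (any(side$stoich <= 0 | side$stoich != round(side$stoich)))
          msg <- c(msg, sprintf("reaction '%s' has non positive-integer stoichiometry",
                                rxn$id))
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("KineticModel", validKineticModel)

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel:", nrow(object@species), "species (",
      sum(object@species$is_boundary), "boundary ),",
      length(object@reactions), "reactions,",
      nrow(object@parameters), "parameters,",
      length(object@haldaneGroups), "Haldane group(s)\n")
})

#' Accessors for KineticModel
#'
#' @param model a [KineticModel-class] object.
#' @return \code{speciesTable} and \code{parameterTable} return data.frames;
#'   \code{reactionList} the list of reactions; \code{reactionIds} a character
#'   vector; \code{parameterValues} a named numeric vector of current values;
#'   \code{haldaneGroups} the list of Haldane groups.
#' @export
speciesTable <- function(model) model@species

#' @rdname speciesTable
#' @export
parameterTable <- function(model) model@parameters

#' @rdname speciesTable
#' @export
reactionList <- function(model) model@reactions

#' @rdname speciesTable
#' @export
reactionIds <- function(model) vapply(model@reactions, `[[`, "", "id")

#' @rdname speciesTable
#' @export
parameterValues <- function(model) {
  stats::setNames(model@parameters$value, model@parameters$id)
}

#' @rdname speciesTable
#' @export
haldaneGroups <- function(model) model@haldaneGroups

#' Steady-state solution of a kinetic model
#'
#' Concentrations of the non-boundary species at which every net production
#' rate vanishes (within tolerance), together with the per-reaction signed
#' fluxes evaluated at those concentrations.
#'
#' @slot concentrations named numeric, non-boundary species only.
#' @slot fluxes named numeric, one signed rate per reaction.
#' @slot residualNorm max absolute time-derivative at the solution.
#' @slot converged logical; \code{FALSE} signals divergence, oscillation or
#'   unbounded accumulation (an in-band result, not an error).
#' @export
setClass("SteadyStateResult",
  representation(
    concentrations = "numeric",
    fluxes = "numeric",
    residualNorm = "numeric",
    converged = "logical"
  )
)

setMethod("show", "SteadyStateResult", function(object) {
  cat("SteadyStateResult:", if (object@converged) "converged" else "NOT converged",
      sprintf("(residual %.3g)\n", object@residualNorm))
})

#' Population state of the mutation-selection process
#'
#' The population is represented by a single parameter state (one mutation
#' fixes before the next arises).  Holds the current parameter values, the
#' converged steady state they imply, the immutable reference fluxes used for
#' proportionalization, the current fitness, and the demographic constants
#' entering Kimura's fixation probability.
#'
#' @slot parameterValues named numeric, current kinetic parameter values.
#' @slot concentrations named numeric, current steady-state concentrations
#'   (non-boundary species).
#' @slot fluxes named numeric, current per-reaction fluxes.
#' @slot startFluxes named numeric over selection targets, fixed at
#'   initialization (pre-mutation reference).
#' @slot targets data.frame with columns \code{reaction}, \code{weight},
#'   \code{multiplier}.
#' @slot fitness current population fitness.
#' @slot Ne effective population size.
#' @slot ploidy 1 or 2.
#' @slot p initial allele frequency used in the fixation probability
#'   (default 0.5).
#' @slot plan mutation plan (see [mutationPlan()]).
#' @slot effectSD standard deviation of the mutational-effect distribution.
#' @slot lambda per-parameter Poisson proposal rate per generation.
#' @slot steadyTolerance,timeCap steady-state solver controls.
#' @slot generationsElapsed generations simulated so far.
#' @export
setClass("PopulationState",
  representation(
    parameterValues = "numeric",
    concentrations = "numeric",
    fluxes = "numeric",
    startFluxes = "numeric",
    targets = "data.frame",
    fitness = "numeric",
    Ne = "numeric",
    ploidy = "integer",
    p = "numeric",
    plan = "data.frame",
    effectSD = "numeric",
    lambda = "numeric",
    steadyTolerance = "numeric",
    timeCap = "numeric",
    generationsElapsed = "numeric"
  )
)

setValidity("PopulationState", function(object) {
  msg <- character()
  if (object@Ne < 1) msg <- c(msg, "Ne must be >= 1")
  if (!object@ploidy %in% c(1L, 2L)) msg <- c(msg, "ploidy must be 1 or 2")
  if (object@p <= 0 || object@p >= 1) msg <- c(msg, "p must be in (0,1)")
  if (any(object@startFluxes == 0))
    msg <- c(msg, "zero start flux on a selected reaction")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState: fitness %.6f, Ne %g, ploidy %d, %g generations\n",
              object@fitness, object@Ne, object@ploidy,
              object@generationsElapsed))
})

#' Equilibrated root population
#'
#' Snapshot of the root population after burn-in to mutation-selection
#' equilibrium: parameter values, reference fluxes, fitness, the per-reaction
#' per-category proposal counters needed for branch-length calibration, and
#' the RNG state, so a run can be exported, re-imported and resumed exactly.
#'
#' @slot parameterValues,concentrations,fluxes,startFluxes,fitness see
#'   [PopulationState-class].
#' @slot targets selection targets data.frame.
#' @slot generationsElapsed total equilibration generations.
#' @slot counters data.frame (\code{generation}, \code{reaction},
#'   \code{category}, \code{n}) logging every mutation proposal.
#' @slot criterionMet logical, windowed stability criterion satisfied.
#' @slot capReached logical, generation cap hit before the criterion.
#' @slot rngState the \code{.Random.seed} vector at the end of equilibration.
#' @slot settings list of simulation settings (Ne, ploidy, p, lambda,
#'   effectSD, steadyTolerance, timeCap).
#' @export
setClass("EquilibratedRoot",
  representation(
    parameterValues = "numeric",
    concentrations = "numeric",
    fluxes = "numeric",
    startFluxes = "numeric",
    fitness = "numeric",
    targets = "data.frame",
    generationsElapsed = "numeric",
    counters = "data.frame",
    criterionMet = "logical",
    capReached = "logical",
    rngState = "integer",
    settings = "list"
  )
)

setMethod("show", "EquilibratedRoot", function(object) {
  cat(sprintf(
    "EquilibratedRoot: %g generations, fitness %.6f, criterion %s\n",
    object@generationsElapsed, object@fitness,
    if (object@criterionMet) "met" else
      if (object@capReached) "not met (cap reached)" else "not met"))
})

#' Generation scale from branch-length calibration
#'
#' Number of simulated generations corresponding to one million years of
#' divergence (equivalently, 1\% sequence divergence), derived from the
#' generation at which the across-reaction average number of mutational
#' proposals reaches 7 in both the enzyme-concentration and the functional
#' parameter category during equilibration.
#'
#' @slot gUnit generations per million years (>= 1).
#' @slot crossing named numeric, per-category crossing generation.
#' @export
setClass("GenerationScale",
  representation(gUnit = "numeric", crossing = "numeric")
)

setMethod("show", "GenerationScale", function(object) {
  cat(sprintf("GenerationScale: %g generations per Myr (1%% divergence)\n",
              object@gUnit))
})
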