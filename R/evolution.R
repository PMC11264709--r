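## Mutation-selection engine.
##
## Per generation, every mutable parameter receives a Poisson(lambda)
## number of mutation proposals (lambda = 0.003 by default); enzyme
## concentration parameters receive rate lambda * k where k is the number
## of that reaction's mutable functional parameters, so that expression
## mutations and functional mutations are proposed in a 1:1 aggregate
## ratio.  Effects are multiplicative, drawn from Normal(mu, sigma) with
## mu = +1% for binding constants (poorer binding means a larger Km) and
## -1% for everything else, truncated so values stay positive.  All
## proposals of one generation are applied jointly, the steady state is
## re-solved, population fitness is re-scored, and the joint event fixes
## with Kimura's probability.

#' Logistic fitness kernel
#'
#' The raw logistic of the proportionalized flux \eqn{x}:
#' \deqn{L(x) = 1 / (1 + e^{10(0.5 - x)}).}
#' The inflection at \eqn{x = 0.5} and the saturating upper branch encode a
#' diminishing marginal return: no flux is (nearly) lethal, and production
#' beyond the starting level buys almost no additional fitness.
#'
#' @param x proportionalized flux (finite numeric, vectorized).
#' @return values in (0, 1).
#' @export
rawLogistic <- function(x) 1 / (1 + exp(10 * (0.5 - x)))

#' Normalized fitness score of one selected flux
#'
#' Proportionalizes the current flux by the immutable reference flux and the
#' target's multiplier, \eqn{x = \mathrm{flux}/(\mathrm{start\_flux}\cdot
#' \mathrm{multiplier})}, and rescales the logistic so that a score of 0
#' corresponds to zero flux and a score of 1 to the starting flux (at
#' multiplier 1):
#' \deqn{\mathrm{score} = (L(x) - L(0)) / (L(x_0) - L(0)),\quad x_0 = 1/\mathrm{multiplier},}
#' floored at 0 below the zero-flux anchor.
#'
#' @param flux current signed flux of the target reaction.
#' @param startFlux reference flux (non-zero; a zero reference is a
#'   configuration error caught at initialization).
#' @param multiplier positive target multiplier (default 1; values > 1 put
#'   the population below the inflection, modelling positive selection).
#' @return non-negative score; its supremum is
#'   \eqn{(1 - L(0))/(L(x_0) - L(0))}.
#' @export
fluxFitness <- function(flux, startFlux, multiplier = 1) {
  if (startFlux == 0)
    stop("zero start flux on a selected reaction", call. = FALSE)
  x <- flux / (startFlux * multiplier)
  l0 <- rawLogistic(0)
  score <- (rawLogistic(x) - l0) / (rawLogistic(1 / multiplier) - l0)
  pmax(score, 0)
}

#' Population fitness: weighted geometric mean of target scores
#'
#' @param scores non-negative per-target scores.
#' @param weights per-target weights summing to 1.
#' @return \eqn{\prod_i s_i^{w_i}}; 0 as soon as any positively weighted
#'   score is 0.
#' @export
populationFitness <- function(scores, weights) {
  stopifnot(length(scores) == length(weights),
            abs(sum(weights) - 1) < 1e-9, all(scores >= 0))
  if (any(scores == 0 & weights > 0)) return(0)
  prod(scores^weights)
}

#' Kimura's fixation probability
#'
#' Diffusion approximation for the probability that a new variant with
#' selection coefficient \eqn{s} fixes:
#' \deqn{P_{fix} = \frac{1 - e^{-2 c N_e s p}}{1 - e^{-2 c N_e s}},}
#' with ploidy \eqn{c}, effective population size \eqn{N_e} and initial
#' frequency \eqn{p}.  Evaluated with overflow-safe branches: the neutral
#' limit (\eqn{|2cN_e s| < 10^{-12}}) returns \eqn{p} exactly, and strongly
#' deleterious arguments use the asymptotic form \eqn{e^{2cN_e s (1-p)}}
#' so no overflow can occur.  With the default \eqn{p = 0.5} a neutral
#' mutation fixes with probability one half.
#'
#' @param s selection coefficient (new/old fitness - 1).
#' @param Ne effective population size (>= 1).
#' @param c ploidy, 1 or 2.
#' @param p initial frequency in (0, 1), default 0.5.
#' @return probability in [0, 1].
#' @export
fixationProbability <- function(s, Ne, c = 2, p = 0.5) {
  stopifnot(Ne >= 1, c %in% c(1, 2), p > 0, p < 1)
  a <- 2 * c * Ne * s
  out <- numeric(length(a))
  neutral <- abs(a) < 1e-12
  lowTail <- !neutral & a < -30
  mid <- !neutral & !lowTail
  out[neutral] <- p
  out[lowTail] <- exp(a[lowTail] * (1 - p))
  out[mid] <- (-expm1(-a[mid] * p)) / (-expm1(-a[mid]))
  pmin(pmax(out, 0), 1)
}

#' Draw multiplicative mutational effects
#'
#' Effects are deviations \eqn{\delta} applied as
#' \eqn{\mathrm{new} = \mathrm{old}(1+\delta)}, drawn from a normal
#' distribution centered at -1\% for all roles except binding constants
#' (+1\%, since poorer binding corresponds to a larger Km) and redrawn
#' until \eqn{1+\delta > 0}.
#'
#' @param n number of draws.
#' @param role parameter role (determines the sign of the mean).
#' @param sd standard deviation of the effect distribution (default 0.01;
#'   \code{sd = 0} degenerates to the mean exactly).
#' @return numeric vector of deviations.
#' @export
sampleEffects <- function(n, role, sd = 0.01) {
  mu <- if (identical(role, "binding_constant")) 0.01 else -0.01
  if (sd == 0) return(rep(mu, n))
  out <- rnorm(n, mu, sd)
  bad <- which(1 + out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mu, sd)
    bad <- bad[1 + out[bad] <= 0]
  }
  out
}

#' Mutation plan for a prepared model
#'
#' One row per mutable parameter with its role, owning reaction, category
#' (\code{"E"} for enzyme concentration, \code{"functional"} otherwise) and
#' per-generation Poisson proposal rate.  Functional parameters get rate
#' \code{lambda}; each reaction's enzyme-concentration parameter gets
#' \code{lambda * k}, \code{k} being the count of that reaction's mutable
#' functional parameters, which yields the 1:1 aggregate proposal ratio
#' between expression-level and functional mutations.  Locally scoped
#' parameters belong to their reaction; globals are attributed to the first
#' reaction (model order) whose rate law references them.
#'
#' @param model a prepared [KineticModel-class] (see [prepareModel()]).
#' @param lambda base Poisson rate per parameter per generation
#'   (default 0.003).
#' @param exclude parameter ids excluded from mutation.
#' @return data.frame(param, role, reaction, category, lambda).
#' @export
mutationPlan <- function(model, lambda = 0.003, exclude = character()) {
  pr <- model@parameters
  mut <- pr[pr$mutable & !pr$id %in% exclude, , drop = FALSE]
  if (!nrow(mut))
    return(data.frame(param = character(), role = character(),
                      reaction = character(), category = character(),
                      lambda = numeric(), stringsAsFactors = FALSE))
  owner <- character(nrow(mut))
  for (i in seq_len(nrow(mut))) {
    if (mut$scope[i] != "global") { owner[i] <- mut$scope[i]; next }
    owner[i] <- NA_character_
    for (rxn in model@reactions) {
      if (mut$id[i] %in% exprIdentifiers(rxn$rate)) {
        owner[i] <- rxn$id
        break
      }
    }
  }
  plan <- data.frame(param = mut$id, role = mut$role, reaction = owner,
                     category = ifelse(mut$role == "enzyme_concentration",
                                       "E", "functional"),
                     lambda = lambda, stringsAsFactors = FALSE)
  for (i in which(plan$category == "E")) {
    k <- sum(plan$category == "functional" &
             plan$reaction %in% plan$reaction[i], na.rm = TRUE)
    plan$lambda[i] <- lambda * k
  }
  plan
}

## map param id -> index of the Haldane group it participates in (as Km or
## forward velocity); used to trigger the coupled Vr update
haldaneTriggerMap <- function(model) {
  m <- character(0)
  idx <- integer(0)
  for (g in seq_along(model@haldaneGroups)) {
    grp <- model@haldaneGroups[[g]]
    trig <- c(grp$substrate_kms, grp$product_kms, grp$vf)
    m <- c(m, trig)
    idx <- c(idx, rep(g, length(trig)))
  }
  stats::setNames(idx, m)
}

#' Initialize the population state
#'
#' Solves the model's steady state at its original parameters (a model that
#' cannot reach steady state is rejected with a configuration error), fixes
#' the selected reactions' start fluxes as the proportionalization
#' reference, and sets the starting fitness (1 by construction when all
#' multipliers are 1).
#'
#' @param model a prepared [KineticModel-class].
#' @param targets data.frame with columns \code{reaction}, \code{weight},
#'   optional \code{multiplier}; weights are normalized to sum to 1.
#' @param Ne effective population size.
#' @param ploidy 1 or 2 (default 2).
#' @param p initial frequency for the fixation probability (default 0.5).
#' @param lambda per-parameter proposal rate (default 0.003).
#' @param effectSD effect-distribution standard deviation (default 0.01).
#' @param exclude parameter ids excluded from mutation.
#' @param steadyTolerance,timeCap steady-state solver controls.
#' @return a [PopulationState-class].
#' @export
initPopulation <- function(model, targets, Ne, ploidy = 2L, p = 0.5,
                           lambda = 0.003, effectSD = 0.01,
                           exclude = character(),
                           steadyTolerance = 1e-9, timeCap = 1e6) {
  stopifnot(is.data.frame(targets), nrow(targets) >= 1L)
  if (is.null(targets$multiplier)) targets$multiplier <- 1
  bad <- setdiff(targets$reaction, reactionIds(model))
  if (length(bad))
    stop(sprintf("selection target(s) not in the model: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (any(targets$weight <= 0))
    stop("selection weights must be positive", call. = FALSE)
  targets$weight <- targets$weight / sum(targets$weight)
  ss <- solveSteadyState(model, steadyTolerance = steadyTolerance,
                         timeCap = timeCap)
  if (!ss@converged)
    stop("model does not reach steady state at its original parameters; it cannot be simulated",
         call. = FALSE)
  startFluxes <- ss@fluxes[targets$reaction]
  if (any(startFluxes == 0))
    stop(sprintf("zero start flux on selected reaction(s): %s",
                 paste(targets$reaction[startFluxes == 0], collapse = ", ")),
         call. = FALSE)
  scores <- mapply(fluxFitness, startFluxes, startFluxes,
                   targets$multiplier)
  new("PopulationState",
      parameterValues = parameterValues(model),
      concentrations = ss@concentrations,
      fluxes = ss@fluxes,
      startFluxes = startFluxes,
      targets = targets,
      fitness = populationFitness(scores, targets$weight),
      Ne = as.numeric(Ne), ploidy = as.integer(ploidy), p = p,
      plan = mutationPlan(model, lambda, exclude),
      effectSD = effectSD, lambda = lambda,
      steadyTolerance = steadyTolerance, timeCap = timeCap,
      generationsElapsed = 0)
}

#' Propose this generation's mutations
#'
#' Draws a Poisson proposal count for every row of the state's mutation
#' plan and an effect for every proposal; a count of zero for all rows
#' yields an empty proposal set and leaves the state untouched.  Haldane
#' coupling is resolved later, jointly, when the proposals are applied.
#'
#' @param state a [PopulationState-class].
#' @param model the prepared model.
#' @return data.frame(param, role, reaction, category, old_value, effect,
#'   new_value), zero rows if nothing mutates.
#' @export
proposeMutations <- function(state, model) {
  plan <- state@plan
  counts <- rpois(nrow(plan), plan$lambda)
  tot <- sum(counts)
  empty <- data.frame(param = character(), role = character(),
                      reaction = character(), category = character(),
                      old_value = numeric(), effect = numeric(),
                      new_value = numeric(), stringsAsFactors = FALSE)
  if (tot == 0L) return(empty)
  rows <- rep(seq_len(nrow(plan)), counts)
  values <- state@parameterValues
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    d <- sampleEffects(1L, plan$role[i], state@effectSD)
    old <- values[[plan$param[i]]]
    newv <- old * (1 + d)
    values[[plan$param[i]]] <- newv
    out[[k]] <- data.frame(param = plan$param[i], role = plan$role[i],
                           reaction = plan$reaction[i],
                           category = plan$category[i],
                           old_value = old, effect = d, new_value = newv,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## apply proposals + Haldane updates to a value vector; returns
## list(values, haldane = data.frame(param, old, new))
applyProposals <- function(model, values, proposals) {
  trig <- haldaneTriggerMap(model)
  for (k in seq_len(nrow(proposals)))
    values[[proposals$param[k]]] <- proposals$new_value[k]
  touched <- unique(trig[names(trig) %in% proposals$param])
  hp <- NULL
  if (length(touched)) {
    hp <- do.call(rbind, lapply(touched, function(g) {
      grp <- model@haldaneGroups[[g]]
      old <- values[[grp$vr]]
      newv <- applyHaldaneUpdate(grp, values)
      data.frame(param = grp$vr, old = old, new = newv,
                 stringsAsFactors = FALSE)
    }))
    for (k in seq_len(nrow(hp))) values[[hp$param[k]]] <- hp$new[k]
  }
  list(values = values, haldane = hp)
}

#' Advance the population by one generation
#'
#' Draws proposals; with none, the state is returned unchanged and no event
#' is logged.  Otherwise all of the generation's proposals (plus their
#' Haldane partner updates) are applied jointly, the steady state is
#' re-solved warm-started from the current concentrations, and the joint
#' event is accepted with Kimura's probability.  A post-mutation solver
#' failure scores fitness 0 (lethal); lethal events are recorded but cannot
#' fix (the population would be extinct).  On rejection every parameter,
#' including Haldane partners, reverts bit-identically.
#'
#' @param state a [PopulationState-class] holding a converged baseline.
#' @param model the prepared model.
#' @return list(state = new state, event = one-row data.frame or NULL,
#'   proposals = the proposal table with haldane annotations).
#' @export
generationStep <- function(state, model) {
  state@generationsElapsed <- state@generationsElapsed + 1
  proposals <- proposeMutations(state, model)
  if (!nrow(proposals))
    return(list(state = state, event = NULL, proposals = proposals))
  ap <- applyProposals(model, state@parameterValues, proposals)
  ss <- solveSteadyState(model, ap$values,
                         initialConcentrations = state@concentrations,
                         steadyTolerance = state@steadyTolerance,
                         timeCap = state@timeCap)
  fitnessBefore <- state@fitness
  if (ss@converged) {
    scores <- mapply(fluxFitness, ss@fluxes[state@targets$reaction],
                     state@startFluxes, state@targets$multiplier)
    fitnessAfter <- populationFitness(scores, state@targets$weight)
  } else fitnessAfter <- 0
  s <- fitnessAfter / fitnessBefore - 1
  pfix <- fixationProbability(s, state@Ne, state@ploidy, state@p)
  lethal <- fitnessAfter == 0
  fixed <- !lethal && runif(1L) < pfix
  if (fixed) {
    state@parameterValues <- ap$values
    state@concentrations <- ss@concentrations
    state@fluxes <- ss@fluxes
    state@fitness <- fitnessAfter
  }
  proposals$haldane_partner <- NA_character_
  proposals$haldane_old <- NA_real_
  proposals$haldane_new <- NA_real_
  if (!is.null(ap$haldane)) {
    trig <- haldaneTriggerMap(model)
    for (k in seq_len(nrow(ap$haldane))) {
      gidx <- which(vapply(model@haldaneGroups, `[[`, "", "vr") ==
                    ap$haldane$param[k])[1L]
      grp <- model@haldaneGroups[[gidx]]
      members <- c(grp$substrate_kms, grp$product_kms, grp$vf)
      hit <- which(proposals$param %in% members)
      if (length(hit)) {
        last <- hit[length(hit)]
        proposals$haldane_partner[last] <- ap$haldane$param[k]
        proposals$haldane_old[last] <- ap$haldane$old[k]
        proposals$haldane_new[last] <- ap$haldane$new[k]
      }
    }
  }
  event <- data.frame(generation = state@generationsElapsed,
                      n_proposals = nrow(proposals),
                      fitness_before = fitnessBefore,
                      fitness_after = fitnessAfter,
                      s = s, pfix = pfix, fixed = fixed, lethal = lethal,
                      stringsAsFactors = FALSE)
  list(state = state, event = event, proposals = proposals)
}

#' Simulate a span of generations
#'
#' Runs [generationStep()] for \code{nGenerations} generations,
#' accumulating the per-proposal mutation log, the per-event summary, and a
#' trace of fitness and all reaction fluxes at every fixation.
#'
#' @param state a [PopulationState-class].
#' @param model the prepared model.
#' @param nGenerations non-negative generation count (0 is the identity).
#' @param collectCounters record per-generation per-reaction proposal
#'   counts by category (needed for branch-length calibration).
#' @return list(state, events, mutations, trace, counters).  \code{events}
#'   has one row per proposal-bearing generation; \code{mutations} one row
#'   per proposal with the event columns joined on; \code{trace} one row
#'   per fixation (generation, fitness, one column per reaction flux);
#'   \code{counters} (generation, reaction, category, n) or NULL.
#' @export
simulateGenerations <- function(state, model, nGenerations,
                                collectCounters = FALSE) {
  stopifnot(nGenerations >= 0)
  events <- list(); muts <- list(); traces <- list(); counters <- list()
  for (g in seq_len(nGenerations)) {
    stepRes <- generationStep(state, model)
    state <- stepRes$state
    if (is.null(stepRes$event)) next
    events[[length(events) + 1L]] <- stepRes$event
    pr <- stepRes$proposals
    pr$generation <- stepRes$event$generation
    pr$s <- stepRes$event$s
    pr$pfix <- stepRes$event$pfix
    pr$fixed <- stepRes$event$fixed
    pr$fitness_before <- stepRes$event$fitness_before
    pr$fitness_after <- stepRes$event$fitness_after
    muts[[length(muts) + 1L]] <- pr
    if (collectCounters) {
      agg <- stats::aggregate(list(n = rep(1L, nrow(pr))),
                              by = list(reaction = pr$reaction,
                                        category = pr$category), FUN = sum)
      agg$generation <- stepRes$event$generation
      counters[[length(counters) + 1L]] <- agg
    }
    if (stepRes$event$fixed) {
      traces[[length(traces) + 1L]] <-
        c(generation = stepRes$event$generation,
          fitness = state@fitness, state@fluxes)
    }
  }
  list(state = state,
       events = if (length(events)) do.call(rbind, events) else NULL,
       mutations = if (length(muts)) do.call(rbind, muts) else NULL,
       trace = if (length(traces)) as.data.frame(do.call(rbind, traces))
               else NULL,
       counters = if (collectCounters && length(counters))
         do.call(rbind, counters) else NULL)
}
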