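## Steady-state solver for the kinetic ODE system, replacing an external
## simulation engine: stiff forward integration (deSolve::lsoda) until the
## residual is small or a time cap is hit, followed by Newton refinement
## with a finite-difference Jacobian.  Failure to converge is an in-band
## result (converged = FALSE), never an exception.

## stoichiometric matrix, species x reactions (products minus substrates)
stoichMatrix <- function(model) {
  sp <- model@species$id
  S <- matrix(0, nrow = length(sp), ncol = length(model@reactions),
              dimnames = list(sp, reactionIds(model)))
  for (j in seq_along(model@reactions)) {
    rxn <- model@reactions[[j]]
    for (k in seq_len(nrow(rxn$substrates)))
      S[rxn$substrates$species[k], j] <- S[rxn$substrates$species[k], j] -
        rxn$substrates$stoich[k]
    for (k in seq_len(nrow(rxn$products)))
      S[rxn$products$species[k], j] <- S[rxn$products$species[k], j] +
        rxn$products$stoich[k]
  }
  S
}

#' Time derivatives of the species concentrations
#'
#' Evaluates the right-hand side of the ODE system: for each species the sum
#' of producing rates minus consuming rates, weighted by stoichiometry.
#' Entries of boundary (constant-concentration) species are forced to
#' exactly zero.
#'
#' @param model a [KineticModel-class].
#' @param concentrations named numeric vector over all species.
#' @param parameterValues named numeric vector of parameter values.
#' @return named numeric vector of derivatives, one entry per species.
#' @export
odeDerivatives <- function(model, concentrations, parameterValues) {
  S <- stoichMatrix(model)
  env <- as.list(c(concentrations, parameterValues))
  v <- evalAllRates(model@reactions, env)
  d <- drop(S %*% v)
  d[model@species$is_boundary] <- 0
  stats::setNames(d, model@species$id)
}

## internal fast context shared by the solver
solverContext <- function(model, parameterValues) {
  boundary <- model@species$is_boundary
  list(
    S = stoichMatrix(model),
    boundary = boundary,
    freeIds = model@species$id[!boundary],
    allIds = model@species$id,
    params = as.list(parameterValues),
    reactions = model@reactions
  )
}

ctxRates <- function(ctx, conc) {
  env <- c(as.list(conc), ctx$params)
  evalAllRates(ctx$reactions, env)
}

ctxRHS <- function(ctx, conc) {
  d <- drop(ctx$S %*% ctxRates(ctx, conc))
  d[ctx$boundary] <- 0
  d
}

## Newton iteration on the free species; finite-difference Jacobian with
## step 1e-7 * max(|C|, 1).  Returns NULL on failure (negative iterate,
## singular Jacobian, or no convergence).
newtonRefine <- function(ctx, conc, tol, maxIter = 50L) {
  free <- !ctx$boundary
  x <- conc[free]
  for (iter in seq_len(maxIter)) {
    full <- conc; full[free] <- x
    f <- ctxRHS(ctx, full)[free]
    if (max(abs(f)) <= tol)
      return(list(conc = full, residual = max(abs(f))))
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(abs(x[j]), 1)
      xh <- x; xh[j] <- xh[j] + h
      fullh <- conc; fullh[free] <- xh
      J[, j] <- (ctxRHS(ctx, fullh)[free] - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    ## damping: halve until the residual does not blow up and stays >= 0
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (all(xn >= 0)) {
        fulln <- conc; fulln[free] <- xn
        fn <- tryCatch(ctxRHS(ctx, fulln)[free], error = function(e) NULL)
        if (!is.null(fn) && all(is.finite(fn)) &&
            max(abs(fn)) < max(abs(f)) * (1 - 1e-4 * lam) + 1e-300)
          break
      }
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- x + lam * step
  }
  NULL
}

#' Solve for the steady state of the kinetic model
#'
#' Strategy: if the initial point already satisfies the tolerance it is
#' returned; otherwise Newton refinement is attempted directly (cheap when
#' warm-started close to a root); otherwise the system is integrated with a
#' stiff solver in geometrically growing time chunks, clipping negative
#' concentrations to zero, until the residual meets the tolerance or the
#' time cap is reached, and Newton-polished.  If neither phase meets the
#' tolerance (oscillation, divergence, unbounded accumulation) the result
#' has \code{converged = FALSE}.
#'
#' @param model a [KineticModel-class].
#' @param parameterValues named numeric parameter values (defaults to the
#'   model's).
#' @param initialConcentrations named numeric start vector over all species
#'   (defaults to the model's initial concentrations).
#' @param steadyTolerance absolute tolerance on \eqn{\max_i |dC_i/dt|}
#'   (default 1e-9).
#' @param timeCap maximum integration time (default 1e6 time units).
#' @return a [SteadyStateResult-class].
#' @export
solveSteadyState <- function(model, parameterValues = NULL,
                             initialConcentrations = NULL,
                             steadyTolerance = 1e-9, timeCap = 1e6) {
  stopifnot(steadyTolerance > 0)
  if (is.null(parameterValues)) parameterValues <- parameterValues(model)
  conc <- stats::setNames(model@species$initial_concentration,
                          model@species$id)
  if (!is.null(initialConcentrations))
    conc[names(initialConcentrations)] <- initialConcentrations
  ctx <- solverContext(model, parameterValues)
  mkResult <- function(conc, converged) {
    resid <- max(abs(ctxRHS(ctx, conc)))
    new("SteadyStateResult",
        concentrations = conc[!ctx$boundary],
        fluxes = stats::setNames(ctxRates(ctx, conc),
                                 colnames(ctx$S)),
        residualNorm = resid,
        converged = converged && resid <= steadyTolerance)
  }
  f0 <- tryCatch(ctxRHS(ctx, conc), error = function(e) NULL)
  if (is.null(f0)) return(mkFailed(ctx, conc))
  if (max(abs(f0)) <= steadyTolerance) return(mkResult(conc, TRUE))
  nr <- newtonRefine(ctx, conc, steadyTolerance)
  if (!is.null(nr)) return(mkResult(nr$conc, TRUE))
  ## stiff forward integration in growing chunks
  free <- !ctx$boundary
  rhsFun <- function(t, y, parms) {
    full <- conc; full[free] <- pmax(y, 0)
    list(ctxRHS(ctx, full)[free])
  }
  y <- conc[free]
  t0 <- 0; chunk <- 1
  ok <- FALSE
  while (t0 < timeCap) {
    t1 <- min(t0 + chunk, timeCap)
    sol <- tryCatch(
      deSolve::lsoda(y, times = c(t0, t1), func = rhsFun, parms = NULL,
                     rtol = 1e-10, atol = 1e-12, maxsteps = 100000),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 2L || any(!is.finite(sol[2L, -1L])))
      break
    y <- pmax(sol[2L, -1L], 0)
    names(y) <- ctx$freeIds
    t0 <- t1
    full <- conc; full[free] <- y
    res <- tryCatch(max(abs(ctxRHS(ctx, full))), error = function(e) Inf)
    if (is.finite(res) && res <= steadyTolerance) { ok <- TRUE; break }
    chunk <- chunk * 10
  }
  full <- conc; full[free] <- y
  nr <- newtonRefine(ctx, full, steadyTolerance)
  if (!is.null(nr)) return(mkResult(nr$conc, TRUE))
  mkResult(full, ok)
}

mkFailed <- function(ctx, conc) {
  new("SteadyStateResult",
      concentrations = conc[!ctx$boundary],
      fluxes = stats::setNames(rep(NA_real_, ncol(ctx$S)), colnames(ctx$S)),
      residualNorm = Inf, converged = FALSE)
}

#' Per-reaction fluxes at a converged steady state
#'
#' Recomputes the signed reaction rates at the stored steady-state
#' concentrations; by construction these reproduce the fluxes stored on the
#' result.
#'
#' @param model a [KineticModel-class].
#' @param result a converged [SteadyStateResult-class]; calling on a
#'   non-converged result is an error.
#' @param parameterValues named numeric parameter values (defaults to the
#'   model's).
#' @return named numeric vector of fluxes.
#' @export
reactionFluxes <- function(model, result, parameterValues = NULL) {
  if (!result@converged)
    stop("reactionFluxes() called on a non-converged steady-state result",
         call. = FALSE)
  if (is.null(parameterValues)) parameterValues <- parameterValues(model)
  conc <- stats::setNames(model@species$initial_concentration,
                          model@species$id)
  conc[names(result@concentrations)] <- result@concentrations
  ctx <- solverContext(model, parameterValues)
  stats::setNames(ctxRates(ctx, conc), colnames(ctx$S))
}
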