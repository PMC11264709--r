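## Built-in toy models with analytically known steady states, used as
## solver oracles, classification/Haldane exercises, and end-to-end smoke
## inputs.  All fixtures are emitted through the ordinary model
## constructor, so they are first-class models, and can be serialized to
## the native format or minimal SBML.

#' Linear irreversible chain with a closed-form steady state
#'
#' A constant source feeds a chain of \code{n} irreversible
#' Michaelis-Menten steps:
#' \deqn{X_0 \to S_1 \to S_2 \to \dots \to S_n \to X_{out},}
#' source rate \eqn{v_0}, step rate \eqn{V_{max,i} S_i/(K_{m,i} + S_i)}.
#' The steady state is \eqn{S_i^* = K_{m,i} v_0/(V_{max,i} - v_0)} with
#' every flux equal to \eqn{v_0} (flux conservation along an unbranched
#' chain) — provided \eqn{V_{max,i} > v_0}; with \code{failure = TRUE} the
#' condition may be violated to build a deliberately unsolvable fixture
#' (unbounded accumulation).
#'
#' @param n chain length (default 3).
#' @param v0 source rate (default 1).
#' @param Vmax,Km per-step constants, recycled to length \code{n}
#'   (defaults 2 and 1).
#' @param withEnzyme parameterize each step as
#'   \eqn{k_{cat,i} E_i S_i/(K_{m,i}+S_i)} with \eqn{E_i = 1} and
#'   \eqn{k_{cat,i} = V_{max,i}}, exposing an enzyme-concentration
#'   parameter per reaction (default FALSE).
#' @param failure allow \eqn{V_{max} \le v_0} (default FALSE; otherwise an
#'   error).
#' @return list(model, steadyState (named concentrations of the free
#'   species), fluxes (named, per reaction)).
#' @export
makeLinearChain <- function(n = 3L, v0 = 1, Vmax = 2, Km = 1,
                            withEnzyme = FALSE, failure = FALSE) {
  stopifnot(n >= 1L, v0 >= 0)
  Vmax <- rep(Vmax, length.out = n)
  Km <- rep(Km, length.out = n)
  if (!failure && any(Vmax <= v0) && v0 > 0)
    stop("Vmax must exceed v0 for a solvable chain (set failure = TRUE to build the divergent fixture)",
         call. = FALSE)
  ids <- paste0("S", seq_len(n))
  species <- data.frame(
    id = c("X0", ids, "Xout"),
    initial_concentration = c(1, rep(0.5, n), 0),
    is_boundary = c(TRUE, rep(FALSE, n), TRUE),
    stringsAsFactors = FALSE)
  params <- data.frame(id = "v0", value = v0, scope = "global",
                       role = "other", mutable = FALSE,
                       stringsAsFactors = FALSE)
  reactions <- list(list(
    id = "R0",
    substrates = data.frame(species = "X0", stoich = 1),
    products = data.frame(species = "S1", stoich = 1),
    rate_text = "v0"))
  for (i in seq_len(n)) {
    sub <- ids[i]
    prod <- if (i < n) ids[i + 1L] else "Xout"
    if (withEnzyme) {
      params <- rbind(params,
        data.frame(id = c(sprintf("kcat_%d", i), sprintf("E_%d", i),
                          sprintf("Km_%d", i)),
                   value = c(Vmax[i], 1, Km[i]), scope = "global",
                   role = NA_character_, mutable = TRUE,
                   stringsAsFactors = FALSE))
      rate <- sprintf("kcat_%d*E_%d*%s/(Km_%d + %s)", i, i, sub, i, sub)
    } else {
      params <- rbind(params,
        data.frame(id = c(sprintf("Vmax_%d", i), sprintf("Km_%d", i)),
                   value = c(Vmax[i], Km[i]), scope = "global",
                   role = NA_character_, mutable = TRUE,
                   stringsAsFactors = FALSE))
      rate <- sprintf("Vmax_%d*%s/(Km_%d + %s)", i, sub, i, sub)
    }
    reactions[[length(reactions) + 1L]] <- list(
      id = sprintf("R%d", i),
      substrates = data.frame(species = sub, stoich = 1),
      products = data.frame(species = prod, stoich = 1),
      rate_text = rate)
  }
  model <- makeKineticModel(species, reactions, params)
  analytic <- if (v0 == 0) rep(0, n) else Km * v0 / (Vmax - v0)
  list(model = model,
       steadyState = stats::setNames(analytic, ids),
       fluxes = stats::setNames(rep(v0, n + 1L),
                                c("R0", sprintf("R%d", seq_len(n)))))
}

#' Reversible uni-uni chain with Haldane-consistent parameters
#'
#' A constant source feeds a chain of \code{n} reversible uni-uni
#' Michaelis-Menten steps and an irreversible drain.  Each step uses the
#' reversible rate law
#' \deqn{v_i = E_i (V_{f,i} S/K_{mS,i} - V_{r,i} P/K_{mP,i}) /
#'       (1 + S/K_{mS,i} + P/K_{mP,i}),}
#' with \eqn{V_{r,i}} derived from \eqn{(V_{f,i}, K_{eq,i}, K_{mS,i},
#' K_{mP,i})} so every Haldane identity holds exactly at construction.
#' Parameter names (\code{Vf_i}, \code{Vr_i}, \code{Keq_i}, \code{KmS_i},
#' \code{KmP_i}, \code{E_i}) classify without overrides.
#'
#' @param n number of reversible steps (default 2).
#' @param v0 source rate (default 1).
#' @param Vf,Keq,KmS,KmP per-step constants, recycled (defaults 10, 2, 1,
#'   4).
#' @param Vdrain,Kdrain constants of the irreversible drain (defaults 4
#'   and 1; \code{Vdrain} must exceed \code{v0}).
#' @param withEnzyme include an \eqn{E_i = 1} enzyme-concentration factor
#'   per reversible step (default TRUE).
#' @return list(model (already prepared: roles classified, Haldane groups
#'   built), fluxes (the steady-state flux, \code{v0}, through every
#'   reaction)).
#' @export
makeReversibleChain <- function(n = 2L, v0 = 1, Vf = 10, Keq = 2, KmS = 1,
                                KmP = 4, Vdrain = 4, Kdrain = 1,
                                withEnzyme = TRUE) {
  stopifnot(n >= 1L, v0 >= 0, Vdrain > v0)
  Vf <- rep(Vf, length.out = n); Keq <- rep(Keq, length.out = n)
  KmS <- rep(KmS, length.out = n); KmP <- rep(KmP, length.out = n)
  Vr <- Vf * KmP / (Keq * KmS)
  ids <- paste0("S", seq_len(n + 1L))
  species <- data.frame(
    id = c("X0", ids, "Xout"),
    initial_concentration = c(1, rep(1, n + 1L), 0),
    is_boundary = c(TRUE, rep(FALSE, n + 1L), TRUE),
    stringsAsFactors = FALSE)
  params <- data.frame(id = "v0", value = v0, scope = "global",
                       role = "other", mutable = FALSE,
                       stringsAsFactors = FALSE)
  reactions <- list(list(
    id = "R0",
    substrates = data.frame(species = "X0", stoich = 1),
    products = data.frame(species = "S1", stoich = 1),
    rate_text = "v0"))
  for (i in seq_len(n)) {
    sub <- ids[i]; prod <- ids[i + 1L]
    newIds <- c(sprintf("Vf_%d", i), sprintf("Vr_%d", i),
                sprintf("Keq_%d", i), sprintf("KmS_%d", i),
                sprintf("KmP_%d", i))
    newVals <- c(Vf[i], Vr[i], Keq[i], KmS[i], KmP[i])
    ## Keq does not appear in the rate law (it is implied by Vf, Vr and the
    ## Kms), so it is scoped to the reaction to stay associated with it
    newScope <- c("global", "global", sprintf("R%d", i), "global", "global")
    if (withEnzyme) {
      newIds <- c(newIds, sprintf("E_%d", i))
      newVals <- c(newVals, 1)
      newScope <- c(newScope, "global")
    }
    params <- rbind(params, data.frame(
      id = newIds, value = newVals, scope = newScope,
      role = NA_character_, mutable = TRUE, stringsAsFactors = FALSE))
    core <- sprintf("(Vf_%d*%s/KmS_%d - Vr_%d*%s/KmP_%d)/(1 + %s/KmS_%d + %s/KmP_%d)",
                    i, sub, i, i, prod, i, sub, i, prod, i)
    rate <- if (withEnzyme) sprintf("E_%d*%s", i, core) else core
    reactions[[length(reactions) + 1L]] <- list(
      id = sprintf("R%d", i),
      substrates = data.frame(species = sub, stoich = 1),
      products = data.frame(species = prod, stoich = 1),
      rate_text = rate)
  }
  reactions[[length(reactions) + 1L]] <- list(
    id = sprintf("R%d", n + 1L),
    substrates = data.frame(species = ids[n + 1L], stoich = 1),
    products = data.frame(species = "Xout", stoich = 1),
    rate_text = sprintf("Vdrain*%s/(Kdrain + %s)", ids[n + 1L],
                        ids[n + 1L]))
  params <- rbind(params, data.frame(
    id = c("Vdrain", "Kdrain"), value = c(Vdrain, Kdrain),
    scope = "global", role = c("forward_max_velocity", "binding_constant"),
    mutable = TRUE, stringsAsFactors = FALSE))
  model <- prepareModel(makeKineticModel(species, reactions, params))
  list(model = model,
       fluxes = stats::setNames(rep(v0, n + 2L),
                                c("R0", sprintf("R%d", seq_len(n + 1L)))))
}

#' Branched fixture: one input, two competing outputs
#'
#' \deqn{X_0 \to M;\quad M \to Y_1;\quad M \to Y_2,}
#' with a constant input rate \eqn{v_{in} = 2} and identical
#' Michaelis-Menten outputs (\eqn{V_{max} = 2}, \eqn{K_m = 1},
#' enzyme-parameterized).  At steady state \eqn{M^* = 1} and each output
#' carries flux 1, so the input flux equals the sum of the outputs —
#' enabling multi-target selection tests (weights, geometric mean).
#'
#' @param vin input rate (default 2).
#' @param neutralModule append a disconnected reaction between two boundary
#'   species (\eqn{X_2 \to Y_{side}}, enzyme-parameterized); its parameters
#'   mutate but cannot affect any selected flux, providing a strictly
#'   neutral mutation class (default FALSE).
#' @return list(model (prepared), steadyState, fluxes).
#' @export
makeBranchedFixture <- function(vin = 2, neutralModule = FALSE) {
  species <- data.frame(
    id = c("X0", "M", "Y1", "Y2"),
    initial_concentration = c(1, 0.5, 0, 0),
    is_boundary = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  params <- data.frame(
    id = c("vin", "kcat_1", "E_1", "Km_1", "kcat_2", "E_2", "Km_2"),
    value = c(vin, 2, 1, 1, 2, 1, 1),
    scope = "global",
    role = c("other", rep(NA_character_, 6L)),
    mutable = c(FALSE, rep(TRUE, 6L)),
    stringsAsFactors = FALSE)
  reactions <- list(
    list(id = "Rin",
         substrates = data.frame(species = "X0", stoich = 1),
         products = data.frame(species = "M", stoich = 1),
         rate_text = "vin"),
    list(id = "Rout1",
         substrates = data.frame(species = "M", stoich = 1),
         products = data.frame(species = "Y1", stoich = 1),
         rate_text = "kcat_1*E_1*M/(Km_1 + M)"),
    list(id = "Rout2",
         substrates = data.frame(species = "M", stoich = 1),
         products = data.frame(species = "Y2", stoich = 1),
         rate_text = "kcat_2*E_2*M/(Km_2 + M)"))
  if (neutralModule) {
    species <- rbind(species, data.frame(
      id = c("X2", "Yside"), initial_concentration = c(1, 0),
      is_boundary = TRUE, stringsAsFactors = FALSE))
    params <- rbind(params, data.frame(
      id = c("kcat_n", "E_n", "Km_n"), value = c(1, 1, 1),
      scope = "global", role = NA_character_, mutable = TRUE,
      stringsAsFactors = FALSE))
    reactions[[length(reactions) + 1L]] <- list(
      id = "Rside",
      substrates = data.frame(species = "X2", stoich = 1),
      products = data.frame(species = "Yside", stoich = 1),
      rate_text = "kcat_n*E_n*X2/(Km_n + X2)")
  }
  model <- prepareModel(makeKineticModel(species, reactions, params))
  ## 4 M/(1+M) = vin  =>  M* = vin/(4 - vin) for the default constants
  mStar <- vin / (4 - vin)
  list(model = model,
       steadyState = c(M = mStar),
       fluxes = c(Rin = vin, Rout1 = vin / 2, Rout2 = vin / 2))
}

#' Toy Newick trees covering both unit conventions
#'
#' @return named character vector of Newick strings: a 2-leaf tree, a
#'   3-leaf caterpillar, a 4-leaf balanced tree, and a tree with a
#'   zero-length branch (exercising the 0-generation path).
#' @export
makeToyTrees <- function() {
  c(two_leaf = "(A:1.0,B:2.0);",
    three_caterpillar = "((A:1.0,B:1.0):0.5,C:1.5);",
    four_balanced = "((A:1.0,B:1.0):0.5,(C:2.0,D:0.5):0.25);",
    zero_branch = "((A:0.0,B:1.0):0.5,C:1.0);")
}
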