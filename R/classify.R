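## Parameter-role classification and Haldane group construction.
##
## Role detection relies on informative parameter naming (KmATP, Vmax_HK,
## Keq2, ...); models with opaque names (parameter__12) fall through to role
## "other" unless the user supplies overrides.

#' Classify model parameters by biochemical role
#'
#' Assigns every parameter one of the roles \code{forward_max_velocity},
#' \code{reverse_max_velocity}, \code{catalytic_constant},
#' \code{reverse_catalytic_constant}, \code{binding_constant},
#' \code{equilibrium_constant}, \code{enzyme_concentration} or \code{other},
#' using case-insensitive name prefixes.  Explicit role annotations already
#' present on the model (e.g. from the native format) and \code{overrides}
#' take precedence over the heuristics; classification is deterministic.
#'
#' @param model a [KineticModel-class].
#' @param overrides named character vector or list mapping parameter id to
#'   role; referencing an unknown parameter id is an error.
#' @return named character vector: role per parameter id.
#' @export
classifyParameters <- function(model, overrides = NULL) {
  ids <- model@parameters$id
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), ids)
    if (length(bad))
      stop(sprintf("role override for unknown parameter(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    badRole <- setdiff(overrides, PARAM_ROLES)
    if (length(badRole))
      stop(sprintf("unknown role(s) in overrides: %s",
                   paste(badRole, collapse = ", ")), call. = FALSE)
  }
  modifierOnly <- modifierOnlySpecies(model)
  roles <- vapply(ids, function(id) roleHeuristic(id, modifierOnly),
                  character(1L))
  explicit <- !is.na(model@parameters$role)
  roles[explicit] <- model@parameters$role[explicit]
  if (!is.null(overrides)) roles[names(overrides)] <- overrides
  roles
}

## species appearing only as modifiers (typical enzyme species); a parameter
## sharing such a name is treated as an enzyme concentration
modifierOnlySpecies <- function(model) {
  inRxn <- unlist(lapply(model@reactions, function(r)
    c(r$substrates$species, r$products$species)))
  mods <- unlist(lapply(model@reactions, `[[`, "modifiers"))
  setdiff(mods, inRxn)
}

roleHeuristic <- function(id, modifierOnly = character()) {
  n <- tolower(id)
  if (id %in% modifierOnly) return("enzyme_concentration")
  if (grepl("^keq", n)) return("equilibrium_constant")
  if (grepl("^(vr|vmax_r)", n)) return("reverse_max_velocity")
  if (grepl("^(vmax|vf|v_)", n)) return("forward_max_velocity")
  if (grepl("^(kcat_r|kcatr)", n)) return("reverse_catalytic_constant")
  if (grepl("^kcat", n)) return("catalytic_constant")
  if (grepl("^(e_|conc_)", n)) return("enzyme_concentration")
  if (grepl("^km", n) || grepl("^ki", n) || grepl("^k[a-z]+_", n))
    return("binding_constant")
  "other"
}

## parameters associated with a reaction: locally scoped ones plus globals
## referenced by its rate law
reactionParameterIds <- function(model, rxn) {
  pr <- model@parameters
  local <- pr$id[pr$scope == rxn$id]
  refd <- intersect(exprIdentifiers(rxn$rate), pr$id)
  unique(c(local, refd))
}

#' Build Haldane-constrained parameter groups
#'
#' For every reaction carrying a forward and a reverse maximal velocity (or
#' catalytic constant), an equilibrium constant, and pairable Michaelis
#' constants, builds a group encoding the thermodynamic identity
#' \deqn{K_{eq} = (V_f/V_r)\, \prod K_{m,P} / \prod K_{m,S}.}
#' Pairing requires equal numbers of substrates and products; binding
#' constants are assigned to a side by name (a substrate/product species id
#' embedded in the name, or a \code{KmS}/\code{KmP} prefix), falling back to
#' declaration order.  Reactions failing the conditions yield no group and
#' their Michaelis constants mutate unconstrained; a group whose identity
#' does not hold at the model's current values (relative residual > 1e-9) is
#' skipped with a warning.
#'
#' @param model a [KineticModel-class].
#' @param roles role map from [classifyParameters()].
#' @return list of groups; each has \code{reaction}, \code{vf}, \code{vr},
#'   \code{keq}, \code{substrate_kms}, \code{product_kms},
#'   \code{reverse_is_kcat}.
#' @export
buildHaldaneGroups <- function(model, roles) {
  values <- parameterValues(model)
  groups <- list()
  for (rxn in model@reactions) {
    pid <- reactionParameterIds(model, rxn)
    r <- roles[pid]
    vf <- pid[r == "forward_max_velocity"]
    if (length(vf) == 0L) vf <- pid[r == "catalytic_constant"]
    vr <- pid[r == "reverse_max_velocity"]
    revKcat <- length(vr) == 0L
    if (revKcat) vr <- pid[r == "reverse_catalytic_constant"]
    keq <- pid[r == "equilibrium_constant"]
    kms <- pid[r == "binding_constant"]
    if (length(vf) != 1L || length(vr) != 1L || length(keq) != 1L ||
        length(kms) == 0L)
      next
    ns <- nrow(rxn$substrates); np <- nrow(rxn$products)
    if (ns != np || ns == 0L) next
    side <- kmSides(kms, rxn)
    if (is.null(side)) next
    if (length(side$sub) != length(side$prod) || length(side$sub) == 0L)
      next
    resid <- haldaneResidual(values, vf, vr, keq, side$sub, side$prod)
    if (!is.finite(resid) || resid > 1e-9) {
      warning(sprintf(
        "reaction '%s': Haldane identity violated at current values (residual %.3g); no group built",
        rxn$id, resid), call. = FALSE)
      next
    }
    groups[[length(groups) + 1L]] <- list(
      reaction = rxn$id, vf = vf, vr = vr, keq = keq,
      substrate_kms = side$sub, product_kms = side$prod,
      reverse_is_kcat = revKcat)
  }
  groups
}

## assign each binding constant to the substrate or product side
kmSides <- function(kms, rxn) {
  subs <- rxn$substrates$species; prods <- rxn$products$species
  side <- character(length(kms))
  for (i in seq_along(kms)) {
    n <- tolower(kms[i])
    hitS <- any(vapply(tolower(subs), grepl, TRUE, x = n, fixed = TRUE))
    hitP <- any(vapply(tolower(prods), grepl, TRUE, x = n, fixed = TRUE))
    side[i] <- if (hitS && !hitP) "sub" else if (hitP && !hitS) "prod"
      else if (grepl("^kms", n)) "sub" else if (grepl("^kmp", n)) "prod"
      else ""
  }
  if (all(side != ""))
    return(list(sub = kms[side == "sub"], prod = kms[side == "prod"]))
  ## fallback: equal split by declaration order
  if (length(kms) == 2L * nrow(rxn$substrates)) {
    h <- length(kms) / 2L
    return(list(sub = kms[seq_len(h)], prod = kms[-seq_len(h)]))
  }
  NULL
}

## relative residual |Keq*Vr*prod(KmS) - Vf*prod(KmP)| / (Vf*prod(KmP))
haldaneResidual <- function(values, vf, vr, keq, subKms, prodKms) {
  lhs <- values[[keq]] * values[[vr]] * prod(values[subKms])
  rhs <- values[[vf]] * prod(values[prodKms])
  abs(lhs - rhs) / abs(rhs)
}

#' Residuals of all Haldane groups at given parameter values
#'
#' @param model a prepared [KineticModel-class].
#' @param values named numeric vector of parameter values (defaults to the
#'   model's current values).
#' @return numeric vector of relative residuals, one per group.
#' @export
haldaneResiduals <- function(model, values = parameterValues(model)) {
  vapply(model@haldaneGroups, function(g)
    haldaneResidual(values, g$vf, g$vr, g$keq, g$substrate_kms,
                    g$product_kms), numeric(1L))
}

#' Recompute the dependent reverse velocity of a Haldane group
#'
#' After a mutation to a forward/reverse binding constant (or to the forward
#' maximal velocity), the reverse maximal velocity (or reverse catalytic
#' constant) is recalculated so the group identity continues to hold,
#' holding \eqn{V_f} and \eqn{K_{eq}} fixed:
#' \deqn{V_r \leftarrow V_f \prod K_{m,P} / (K_{eq} \prod K_{m,S}).}
#'
#' @param group one group from [buildHaldaneGroups()].
#' @param values named numeric vector of current parameter values (already
#'   containing the mutated value).
#' @return the updated value for the group's reverse-velocity parameter.
#' @export
applyHaldaneUpdate <- function(group, values) {
  vf <- values[[group$vf]]; keq <- values[[group$keq]]
  if (!is.finite(vf) || vf <= 0 || !is.finite(keq) || keq <= 0)
    stop(sprintf("reaction '%s': Vf and Keq must be positive for the Haldane update",
                 group$reaction), call. = FALSE)
  vf * prod(values[group$product_kms]) / (keq * prod(values[group$substrate_kms]))
}

#' Classify parameters and build Haldane groups in one step
#'
#' Convenience wrapper: runs [classifyParameters()], stores the roles on the
#' model, builds the Haldane groups, and marks dependent parameters
#' non-mutable (each group's reverse velocity, which is recomputed from the
#' constraint, and all equilibrium constants, which are thermodynamic
#' properties of the reaction rather than of the enzyme).
#'
#' @param model a [KineticModel-class].
#' @param overrides optional role overrides (see [classifyParameters()]).
#' @param exclude parameter ids to hold fixed (excluded from mutation).
#' @return the model with roles, groups and mutability flags set.
#' @export
prepareModel <- function(model, overrides = NULL, exclude = character()) {
  roles <- classifyParameters(model, overrides)
  model@parameters$role <- unname(roles[model@parameters$id])
  groups <- buildHaldaneGroups(model, roles)
  model@haldaneGroups <- groups
  dependent <- vapply(groups, `[[`, "", "vr")
  pr <- model@parameters
  pr$mutable <- pr$mutable &
    !(pr$id %in% c(dependent, exclude)) &
    pr$role != "equilibrium_constant"
  model@parameters <- pr
  validObject(model)
  model
}
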