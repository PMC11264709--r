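## Rate laws are stored as quoted R expressions restricted to the operator
## set {+, -, *, /, ^, exp} plus parentheses, numeric literals, and declared
## species/parameter identifiers.  The restriction is enforced at parse time
## so that evaluation is always a finite arithmetic expression.

RATE_OPS <- c("+", "-", "*", "/", "^", "exp", "(")

#' Parse a kinetic rate expression
#'
#' Parses an infix rate-law string into a quoted expression, admitting only
#' arithmetic operators (\code{+ - * / ^}), \code{exp()}, parentheses,
#' numbers, and identifiers.
#'
#' @param text rate law as infix text, e.g. \code{"Vmax*S/(Km+S)"}.
#' @param knownIds optional character vector of declared identifiers; any
#'   other identifier raises an error naming it.
#' @param context label used in error messages (e.g. a reaction id).
#' @return a quoted R expression (language object).
#' @export
parseRateExpression <- function(text, knownIds = NULL, context = "rate") {
  ex <- tryCatch(str2lang(text), error = function(e)
    stop(sprintf("%s: cannot parse rate expression '%s': %s",
                 context, text, conditionMessage(e)), call. = FALSE))
  checkRateExpr(ex, context)
  if (!is.null(knownIds)) {
    bad <- setdiff(exprIdentifiers(ex), knownIds)
    if (length(bad))
      stop(sprintf("%s: undeclared identifier(s) in rate law: %s",
                   context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  ex
}

checkRateExpr <- function(ex, context) {
  if (is.numeric(ex) || is.symbol(ex)) return(invisible(TRUE))
  if (is.call(ex)) {
    op <- as.character(ex[[1L]])
    if (!op %in% RATE_OPS)
      stop(sprintf("%s: unsupported operator or function '%s' in rate law",
                   context, op), call. = FALSE)
    for (i in seq_along(ex)[-1L]) checkRateExpr(ex[[i]], context)
    return(invisible(TRUE))
  }
  stop(sprintf("%s: unsupported token in rate law", context), call. = FALSE)
}

#' Identifiers referenced by an expression
#' @param ex a quoted expression.
#' @return character vector of symbol names.
#' @export
exprIdentifiers <- function(ex) {
  if (is.symbol(ex)) return(as.character(ex))
  if (is.call(ex)) {
    ids <- unlist(lapply(as.list(ex)[-1L], exprIdentifiers))
    return(unique(ids))
  }
  character()
}

#' Evaluate one reaction's rate law
#'
#' @param reaction a reaction element of a [KineticModel-class].
#' @param concentrations named numeric vector of species concentrations.
#' @param parameterValues named numeric vector of parameter values.
#' @return the signed reaction rate (finite scalar).
#' @export
evaluateRate <- function(reaction, concentrations, parameterValues) {
  v <- eval(reaction$rate, envir = as.list(c(concentrations, parameterValues)))
  if (!is.finite(v))
    stop(sprintf("non-finite rate in reaction '%s' (division by zero or overflow)",
                 reaction$id), call. = FALSE)
  v
}

## fast path used by the solver: evaluate all rates in one environment
evalAllRates <- function(reactions, env) {
  vapply(reactions, function(rxn) {
    v <- eval(rxn$rate, envir = env)
    if (!is.finite(v))
      stop(sprintf("non-finite rate in reaction '%s'", rxn$id), call. = FALSE)
    v
  }, numeric(1L))
}

exprToText <- function(ex) {
  paste(deparse(ex, width.cutoff = 500L), collapse = " ")
}
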