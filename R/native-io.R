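## Native plain-text model format.
##
## UTF-8 text with three sections, '#' comments, whitespace-insensitive:
##   species:
##     X0  init=1.0  boundary
##     S1  init=0.5
##   parameters:
##     Vmax_1 = 2.0
##     Keq_2 = 2.0  role=equilibrium_constant  scope=R2
##     v0 = 1.0  role=other  fixed
##   reactions:
##     R1: X0 -> S1   rate = v0
##     R2: S1 -> S2   rate = Vmax_1*S1/(Km_1+S1)
## Stoichiometric coefficients are written as integer prefixes ("2 S1").
## Modifier species are inferred: any species referenced by a rate law that
## is neither substrate nor product of that reaction.

#' Construct a KineticModel from parts
#'
#' Low-level constructor used by the parsers and fixture generators.
#'
#' @param species data.frame(id, initial_concentration, is_boundary).
#' @param reactions list of reactions; each needs \code{id},
#'   \code{substrates}, \code{products}, \code{rate_text} (or a quoted
#'   \code{rate}), optional \code{modifiers}.
#' @param parameters data.frame(id, value) with optional \code{scope},
#'   \code{role}, \code{mutable} columns.
#' @param units optional character annotations.
#' @return a validated [KineticModel-class].
#' @export
makeKineticModel <- function(species, reactions, parameters,
                             units = character()) {
  species$is_boundary <- as.logical(species$is_boundary)
  if (is.null(parameters$scope)) parameters$scope <- "global"
  if (is.null(parameters$role)) parameters$role <- NA_character_
  if (is.null(parameters$mutable)) parameters$mutable <- TRUE
  rownames(species) <- rownames(parameters) <- NULL
  known <- c(species$id, parameters$id)
  reactions <- lapply(reactions, function(rxn) {
    if (is.null(rxn[["rate"]]))
      rxn$rate <- parseRateExpression(rxn[["rate_text"]], known, rxn$id)
    if (is.null(rxn[["rate_text"]])) rxn$rate_text <- exprToText(rxn$rate)
    if (is.null(rxn[["modifiers"]])) {
      used <- exprIdentifiers(rxn$rate)
      rxn$modifiers <- setdiff(intersect(used, species$id),
                               c(rxn$substrates$species, rxn$products$species))
    }
    rxn
  })
  new("KineticModel", species = species, reactions = reactions,
      parameters = parameters, units = units)
}

emptySide <- function() data.frame(species = character(), stoich = numeric(),
                                   stringsAsFactors = FALSE)

parseSide <- function(text, lineNo) {
  text <- trimws(text)
  if (text == "" || text == "0") return(emptySide())
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1L]])
  sp <- character(length(terms)); st <- numeric(length(terms))
  for (i in seq_along(terms)) {
    m <- regmatches(terms[i],
                    regexec("^([0-9]+)?\\s*\\*?\\s*([A-Za-z_][A-Za-z0-9_.]*)$",
                            terms[i]))[[1L]]
    if (length(m) == 0L)
      stop(sprintf("line %d: cannot parse stoichiometric term '%s'",
                   lineNo, terms[i]), call. = FALSE)
    st[i] <- if (m[2] == "") 1 else as.numeric(m[2])
    sp[i] <- m[3]
  }
  data.frame(species = sp, stoich = st, stringsAsFactors = FALSE)
}

#' Read a model in the native plain-text format
#'
#' @param text the document as a single string, a character vector of lines,
#'   or a file path (single string naming an existing file).
#' @return a [KineticModel-class].
#' @export
parseNativeModel <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- sub("#.*$", "", text)
  section <- ""
  species <- list(); params <- list(); reactions <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    low <- tolower(ln)
    if (low %in% c("species:", "parameters:", "reactions:")) {
      section <- sub(":", "", low, fixed = TRUE)
      next
    }
    if (section == "species") {
      m <- regmatches(ln, regexec(
        "^([A-Za-z_][A-Za-z0-9_.]*)\\s+init\\s*=\\s*([-0-9.eE+]+)(\\s+boundary)?\\s*$",
        ln))[[1L]]
      if (length(m) == 0L)
        stop(sprintf("line %d: malformed species line '%s'", i, ln),
             call. = FALSE)
      species[[length(species) + 1L]] <- data.frame(
        id = m[2], initial_concentration = as.numeric(m[3]),
        is_boundary = m[4] != "", stringsAsFactors = FALSE)
    } else if (section == "parameters") {
      m <- regmatches(ln, regexec(
        "^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*([-0-9.eE+]+)(\\s+role\\s*=\\s*([a-z_]+))?(\\s+scope\\s*=\\s*([A-Za-z_][A-Za-z0-9_.]*))?(\\s+fixed)?\\s*$",
        ln))[[1L]]
      if (length(m) == 0L)
        stop(sprintf("line %d: malformed parameter line '%s'", i, ln),
             call. = FALSE)
      role <- if (m[5] == "") NA_character_ else m[5]
      if (!is.na(role) && !role %in% PARAM_ROLES)
        stop(sprintf("line %d: unknown role '%s'", i, role), call. = FALSE)
      params[[length(params) + 1L]] <- data.frame(
        id = m[2], value = as.numeric(m[3]),
        scope = if (m[7] == "") "global" else m[7],
        role = role, mutable = m[8] == "", stringsAsFactors = FALSE)
    } else if (section == "reactions") {
      m <- regmatches(ln, regexec(
        "^([A-Za-z_][A-Za-z0-9_.]*)\\s*:\\s*(.*?)->(.*?)\\s+rate\\s*=\\s*(.+)$",
        ln))[[1L]]
      if (length(m) == 0L)
        stop(sprintf("line %d: malformed reaction line '%s'", i, ln),
             call. = FALSE)
      reactions[[length(reactions) + 1L]] <- list(
        id = m[2],
        substrates = parseSide(m[3], i),
        products = parseSide(m[4], i),
        rate_text = trimws(m[5]),
        lineNo = i)
    } else {
      stop(sprintf("line %d: content before any section header: '%s'", i, ln),
           call. = FALSE)
    }
  }
  if (!length(species)) stop("no species declared", call. = FALSE)
  if (!length(reactions)) stop("no reactions declared", call. = FALSE)
  speciesDf <- do.call(rbind, species)
  paramsDf <- if (length(params)) do.call(rbind, params) else
    data.frame(id = character(), value = numeric(), scope = character(),
               role = character(), mutable = logical(),
               stringsAsFactors = FALSE)
  known <- c(speciesDf$id, paramsDf$id)
  reactions <- lapply(reactions, function(rxn) {
    rxn$rate <- tryCatch(
      parseRateExpression(rxn$rate_text, known, rxn$id),
      error = function(e) stop(sprintf("line %d: %s", rxn$lineNo,
                                       conditionMessage(e)), call. = FALSE))
    rxn$lineNo <- NULL
    rxn
  })
  makeKineticModel(speciesDf, reactions, paramsDf)
}

#' Serialize a model to the native plain-text format
#'
#' Round-trip companion of [parseNativeModel()]: the serialized document
#' re-parses to a model with identical parameter values and stoichiometry.
#'
#' @param model a [KineticModel-class].
#' @param path optional file path; when omitted the document is returned as a
#'   character vector of lines.
#' @return invisibly, the lines written (or the lines, if \code{path} is
#'   \code{NULL}).
#' @export
writeNativeModel <- function(model, path = NULL) {
  num <- function(x) sprintf("%.17g", x)
  out <- c("species:")
  for (i in seq_len(nrow(model@species))) {
    s <- model@species[i, ]
    out <- c(out, sprintf("  %s  init=%s%s", s$id,
                          num(s$initial_concentration),
                          if (s$is_boundary) "  boundary" else ""))
  }
  out <- c(out, "parameters:")
  for (i in seq_len(nrow(model@parameters))) {
    p <- model@parameters[i, ]
    out <- c(out, sprintf("  %s = %s%s%s%s", p$id, num(p$value),
                          if (!is.na(p$role)) paste0("  role=", p$role) else "",
                          if (p$scope != "global") paste0("  scope=", p$scope) else "",
                          if (!p$mutable) "  fixed" else ""))
  }
  out <- c(out, "reactions:")
  side <- function(df) {
    if (!nrow(df)) return("0")
    paste(ifelse(df$stoich == 1, df$species,
                 paste(df$stoich, df$species)), collapse = " + ")
  }
  for (rxn in model@reactions) {
    out <- c(out, sprintf("  %s: %s -> %s   rate = %s", rxn$id,
                          side(rxn$substrates), side(rxn$products),
                          rxn$rate_text))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
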