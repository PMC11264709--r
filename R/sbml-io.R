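## SBML Level 2/3 subset reader and a minimal writer, via xml2.
##
## Supported: species (boundaryCondition / constant mapped to boundary),
## global and reaction-local parameters, reactions with explicit kinetic
## laws in content MathML over {plus, minus, times, divide, power, exp},
## function definitions (inlined).  Compartments are collapsed to volume 1
## so concentrations equal amounts.  Events, rules, constraints and delays
## are out of the supported subset and raise explicit errors.

#' Read an SBML model (supported subset)
#'
#' @param x path to an SBML file, or the document as a single XML string.
#' @return a [KineticModel-class]; boundary-condition species get
#'   \code{is_boundary = TRUE} and are held constant by the solver.
#' @export
parseSBML <- function(x) {
  doc <- if (length(x) == 1L && !grepl("<", x, fixed = TRUE) &&
             file.exists(x)) xml2::read_xml(x) else xml2::read_xml(x)
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mod, "xml_missing"))
    stop("not an SBML document: no <model> element", call. = FALSE)
  for (bad in c("listOfEvents", "listOfRules", "listOfConstraints")) {
    if (!inherits(xml2::xml_find_first(mod, paste0("./", bad)),
                  "xml_missing"))
      stop(sprintf("unsupported SBML feature: %s", bad), call. = FALSE)
  }
  if (!inherits(xml2::xml_find_first(mod, ".//delay"), "xml_missing"))
    stop("unsupported SBML feature: delay", call. = FALSE)

  funDefs <- parseFunctionDefs(mod)

  spNodes <- xml2::xml_find_all(mod, "./listOfSpecies/species")
  if (!length(spNodes)) stop("SBML model declares no species", call. = FALSE)
  species <- do.call(rbind, lapply(spNodes, function(s) {
    conc <- xml2::xml_attr(s, "initialConcentration")
    if (is.na(conc)) conc <- xml2::xml_attr(s, "initialAmount")
    data.frame(
      id = xml2::xml_attr(s, "id"),
      initial_concentration = if (is.na(conc)) 0 else as.numeric(conc),
      is_boundary = isTRUE(xml2::xml_attr(s, "boundaryCondition") == "true") ||
        isTRUE(xml2::xml_attr(s, "constant") == "true"),
      stringsAsFactors = FALSE)
  }))

  gpNodes <- xml2::xml_find_all(mod, "./listOfParameters/parameter")
  globals <- if (length(gpNodes)) do.call(rbind, lapply(gpNodes, function(p)
    data.frame(id = xml2::xml_attr(p, "id"),
               value = as.numeric(xml2::xml_attr(p, "value")),
               scope = "global", role = NA_character_, mutable = TRUE,
               stringsAsFactors = FALSE))) else NULL

  params <- globals
  rxNodes <- xml2::xml_find_all(mod, "./listOfReactions/reaction")
  if (!length(rxNodes)) stop("SBML model declares no reactions", call. = FALSE)
  reactions <- list()
  for (rx in rxNodes) {
    rid <- xml2::xml_attr(rx, "id")
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop(sprintf("reaction '%s' has no kinetic law", rid), call. = FALSE)
    lp <- xml2::xml_find_all(kl, "./listOfParameters/parameter|./listOfLocalParameters/localParameter")
    rename <- character()
    if (length(lp)) {
      lpd <- do.call(rbind, lapply(lp, function(p)
        data.frame(id = xml2::xml_attr(p, "id"),
                   value = as.numeric(xml2::xml_attr(p, "value")),
                   scope = rid, role = NA_character_, mutable = TRUE,
                   stringsAsFactors = FALSE)))
      clash <- lpd$id %in% c(params$id, species$id)
      if (any(clash)) {
        rename <- stats::setNames(paste(rid, lpd$id[clash], sep = "_"),
                                  lpd$id[clash])
        lpd$id[clash] <- rename
      }
      params <- rbind(params, lpd)
    }
    math <- xml2::xml_find_first(kl, "./math/*")
    if (inherits(math, "xml_missing"))
      stop(sprintf("reaction '%s' has an empty kinetic law", rid),
           call. = FALSE)
    ex <- mathmlToExpr(math, funDefs)
    if (length(rename)) ex <- substituteSymbols(ex, lapply(rename, as.name))
    side <- function(xp) {
      refs <- xml2::xml_find_all(rx, xp)
      if (!length(refs)) return(emptySide())
      do.call(rbind, lapply(refs, function(sr) {
        st <- xml2::xml_attr(sr, "stoichiometry")
        data.frame(species = xml2::xml_attr(sr, "species"),
                   stoich = if (is.na(st)) 1 else as.numeric(st),
                   stringsAsFactors = FALSE)
      }))
    }
    mods <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"),
      "species")
    reactions[[length(reactions) + 1L]] <- list(
      id = rid,
      substrates = side("./listOfReactants/speciesReference"),
      products = side("./listOfProducts/speciesReference"),
      modifiers = mods,
      rate = ex, rate_text = exprToText(ex))
  }
  if (is.null(params))
    params <- data.frame(id = character(), value = numeric(),
                         scope = character(), role = character(),
                         mutable = logical(), stringsAsFactors = FALSE)
  ## compartments collapsed to volume 1: drop compartment symbols that leak
  ## into rate laws by binding them as parameters of value 1
  compIds <- xml2::xml_attr(
    xml2::xml_find_all(mod, "./listOfCompartments/compartment"), "id")
  used <- unique(unlist(lapply(reactions, function(r) exprIdentifiers(r$rate))))
  leak <- intersect(compIds, used)
  if (length(leak))
    params <- rbind(params, data.frame(
      id = leak, value = 1, scope = "global", role = "other",
      mutable = FALSE, stringsAsFactors = FALSE))
  makeKineticModel(species, reactions, params)
}

parseFunctionDefs <- function(mod) {
  fds <- xml2::xml_find_all(mod, "./listOfFunctionDefinitions/functionDefinition")
  defs <- list()
  for (fd in fds) {
    id <- xml2::xml_attr(fd, "id")
    lam <- xml2::xml_find_first(fd, "./math/lambda")
    if (inherits(lam, "xml_missing"))
      stop(sprintf("function definition '%s' has no lambda", id),
           call. = FALSE)
    kids <- xml2::xml_find_all(lam, "./*")
    isBvar <- xml2::xml_name(kids) == "bvar"
    args <- vapply(kids[isBvar], function(b)
      xml2::xml_text(xml2::xml_find_first(b, "./ci")), character(1L))
    body <- kids[!isBvar]
    if (length(body) != 1L)
      stop(sprintf("function definition '%s': malformed lambda body", id),
           call. = FALSE)
    defs[[id]] <- list(args = trimws(args), body = body[[1L]])
  }
  defs
}

## content MathML -> quoted R expression (subset)
mathmlToExpr <- function(node, funDefs = list()) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(parseCn(node))
  if (nm != "apply")
    stop(sprintf("unsupported MathML element <%s>", nm), call. = FALSE)
  kids <- xml2::xml_find_all(node, "./*")
  op <- xml2::xml_name(kids[[1L]])
  args <- lapply(kids[-1L], mathmlToExpr, funDefs = funDefs)
  nary <- function(sym, args) Reduce(function(a, b) call(sym, a, b), args)
  switch(op,
    plus = if (length(args) == 0L) 0 else nary("+", args),
    times = if (length(args) == 0L) 1 else nary("*", args),
    minus = if (length(args) == 1L) call("-", args[[1L]])
            else call("-", args[[1L]], args[[2L]]),
    divide = call("/", args[[1L]], args[[2L]]),
    power = call("^", args[[1L]], args[[2L]]),
    exp = call("exp", args[[1L]]),
    ci = {
      fname <- trimws(xml2::xml_text(kids[[1L]]))
      def <- funDefs[[fname]]
      if (is.null(def))
        stop(sprintf("call to unknown function '%s' in kinetic law", fname),
             call. = FALSE)
      if (length(args) != length(def$args))
        stop(sprintf("function '%s' called with %d argument(s), expects %d",
                     fname, length(args), length(def$args)), call. = FALSE)
      body <- mathmlToExpr(def$body, funDefs)
      substituteSymbols(body, stats::setNames(args, def$args))
    },
    stop(sprintf("unsupported MathML operator <%s>", op), call. = FALSE)
  )
}

parseCn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  sep <- xml2::xml_find_all(node, "./sep")
  if (length(sep)) {
    parts <- strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1L]]
    parts <- as.numeric(parts)
    if (identical(type, "rational")) return(parts[1L] / parts[2L])
    return(parts[1L] * 10^parts[2L])  # e-notation
  }
  as.numeric(trimws(xml2::xml_text(node)))
}

substituteSymbols <- function(ex, map) {
  if (is.symbol(ex)) {
    nm <- as.character(ex)
    if (nm %in% names(map)) return(map[[nm]])
    return(ex)
  }
  if (is.call(ex)) {
    for (i in seq_along(ex)[-1L])
      ex[[i]] <- substituteSymbols(ex[[i]], map)
    return(ex)
  }
  ex
}

## quoted R expression -> content MathML
exprToMathML <- function(ex) {
  if (is.numeric(ex)) return(sprintf("<cn> %.17g </cn>", ex))
  if (is.symbol(ex)) return(sprintf("<ci> %s </ci>", as.character(ex)))
  op <- as.character(ex[[1L]])
  args <- lapply(as.list(ex)[-1L], exprToMathML)
  if (op == "(") return(args[[1L]])
  tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power", "exp" = "exp",
                stop(sprintf("cannot serialize operator '%s' to MathML", op),
                     call. = FALSE))
  paste0("<apply><", tag, "/>", paste(unlist(args), collapse = ""),
         "</apply>")
}

#' Write a model as minimal SBML Level 2
#'
#' Companion of [parseSBML()]: the emitted document re-parses to a model
#' with identical species, stoichiometry and parameter values.  Role and
#' mutability annotations are not part of SBML and are not carried.
#'
#' @param model a [KineticModel-class].
#' @param path optional output path; omitted, the XML is returned as one
#'   string.
#' @return invisibly (or visibly when \code{path} is \code{NULL}) the XML
#'   text.
#' @export
writeSBML <- function(model, path = NULL) {
  esc <- function(x) x
  num <- function(x) sprintf("%.17g", x)
  sp <- vapply(seq_len(nrow(model@species)), function(i) {
    s <- model@species[i, ]
    sprintf('      <species id="%s" compartment="cell" initialConcentration="%s" boundaryCondition="%s"/>',
            esc(s$id), num(s$initial_concentration),
            if (s$is_boundary) "true" else "false")
  }, character(1L))
  glob <- model@parameters[model@parameters$scope == "global", , drop = FALSE]
  gp <- vapply(seq_len(nrow(glob)), function(i)
    sprintf('      <parameter id="%s" value="%s"/>', esc(glob$id[i]),
            num(glob$value[i])), character(1L))
  rx <- vapply(model@reactions, function(rxn) {
    side <- function(df, tag, refTag) {
      if (!nrow(df)) return("")
      refs <- sprintf('          <%s species="%s" stoichiometry="%s"/>',
                      refTag, df$species, num(df$stoich))
      sprintf("        <%s>\n%s\n        </%s>", tag,
              paste(refs, collapse = "\n"), tag)
    }
    loc <- model@parameters[model@parameters$scope == rxn$id, , drop = FALSE]
    locXml <- if (nrow(loc)) sprintf(
      "          <listOfParameters>\n%s\n          </listOfParameters>",
      paste(sprintf('            <parameter id="%s" value="%s"/>',
                    loc$id, num(loc$value)), collapse = "\n")) else ""
    mods <- if (length(rxn$modifiers)) sprintf(
      "        <listOfModifiers>\n%s\n        </listOfModifiers>",
      paste(sprintf('          <modifierSpeciesReference species="%s"/>',
                    rxn$modifiers), collapse = "\n")) else ""
    parts <- c(
      sprintf('      <reaction id="%s">', esc(rxn$id)),
      side(rxn$substrates, "listOfReactants", "speciesReference"),
      side(rxn$products, "listOfProducts", "speciesReference"),
      mods,
      "        <kineticLaw>",
      sprintf('          <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>',
              exprToMathML(rxn$rate)),
      locXml,
      "        </kineticLaw>",
      "      </reaction>")
    paste(parts[parts != ""], collapse = "\n")
  }, character(1L))
  xml <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="model">',
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>', sp, '    </listOfSpecies>',
    if (length(gp)) c('    <listOfParameters>', gp, '    </listOfParameters>'),
    '    <listOfReactions>', rx, '    </listOfReactions>',
    '  </model>',
    '</sbml>'), collapse = "\n")
  if (!is.null(path)) {
    writeLines(xml, path)
    return(invisible(xml))
  }
  xml
}
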