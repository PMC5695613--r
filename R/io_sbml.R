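#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_attr xml_name
#'   xml_text xml_ns_strip
NULL

.sbmlNS <- c(L3V1 = "http://www.sbml.org/sbml/level3/version1/core",
             L2V4 = "http://www.sbml.org/sbml/level2/version4")

# MathML for the deterministic mass-action rate law of one reaction
.kineticMathML <- function(rx) {
  r <- rx$reactants
  k <- sprintf("<ci> %s </ci>", rx$rate)
  body <- if (length(r) == 0L) {
    k
  } else if (length(r) == 1L) {
    sprintf("<apply><times/>%s<ci> %s </ci></apply>", k, r[1])
  } else if (r[1] == r[2]) {
    sprintf(paste0(
      "<apply><divide/><apply><times/>%s<ci> %s </ci>",
      "<apply><minus/><ci> %s </ci><cn> 1 </cn></apply></apply>",
      "<cn> 2 </cn></apply>"), k, r[1], r[1])
  } else {
    sprintf("<apply><times/>%s<ci> %s </ci><ci> %s </ci></apply>",
            k, r[1], r[2])
  }
  sprintf('<math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>', body)
}

.speciesRefs <- function(tag, names, level) {
  if (!length(names)) return("")
  tab <- table(names)
  refs <- sprintf(
    '<speciesReference species="%s" stoichiometry="%d"%s/>',
    names(tab), as.integer(tab),
    if (level == "L3V1") ' constant="true"' else "")
  sprintf("<listOf%s>%s</listOf%s>", tag, paste(refs, collapse = ""), tag)
}

#' Export a model to SBML
#'
#' Writes SBML Level 3 Version 1 (default) with species initial amounts as
#' counts (\code{hasOnlySubstanceUnits="true"}, so the stochastic semantics
#' are unambiguous), global parameters for the rate constants, and explicit
#' mass-action kinetic laws. A Level 2 Version 4 writer is available for
#' compatibility with older simulators.
#'
#' @param model a [KineticModel-class].
#' @param path output file path.
#' @param level \code{"L3V1"} (default) or \code{"L2V4"}.
#' @return invisibly, a list with \code{path}, \code{level}, \code{version}
#'   and \code{modelId}.
#' @export
exportSBML <- function(model, path, level = c("L3V1", "L2V4")) {
  level <- match.arg(level)
  validObject(model)
  lv <- if (level == "L3V1") c(3L, 1L) else c(2L, 4L)
  modelId <- gsub("[^A-Za-z0-9_]", "_", model@name)

  sp <- model@species
  speciesXml <- sprintf(paste0(
    '<species id="%s" compartment="cell" initialAmount="%g" ',
    'hasOnlySubstanceUnits="true" boundaryCondition="false" ',
    'constant="false"/>'), sp$name, sp$initial)
  paramXml <- sprintf(
    '<parameter id="%s" value="%.17g" constant="true"/>',
    names(model@rates), unname(model@rates))
  rxXml <- vapply(seq_along(model@reactions), function(j) {
    rx <- model@reactions[[j]]
    sprintf(paste0(
      '<reaction id="r%d" reversible="false"%s>%s%s',
      "<kineticLaw>%s</kineticLaw></reaction>"),
      j, if (level == "L3V1") ' fast="false"' else "",
      .speciesRefs("Reactants", rx$reactants, level),
      .speciesRefs("Products", rx$products, level),
      .kineticMathML(rx))
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<sbml xmlns="%s" level="%d" version="%d">',
            .sbmlNS[[level]], lv[1], lv[2]),
    sprintf('<model id="%s" name="%s">', modelId, model@name),
    '<listOfCompartments>',
    sprintf('<compartment id="cell" spatialDimensions="3" size="1" constant="true"%s/>',
            ""),
    "</listOfCompartments>",
    "<listOfSpecies>", paste(speciesXml, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste(paramXml, collapse = ""), "</listOfParameters>",
    "<listOfReactions>", paste(rxXml, collapse = ""), "</listOfReactions>",
    "</model></sbml>")
  doc <- tryCatch(read_xml(xml),
                  error = function(e) stop("internal SBML serialisation error: ",
                                           conditionMessage(e)))
  .checkSbmlStructure(doc)
  writeLines(as.character(doc), path, useBytes = TRUE)
  invisible(list(path = path, level = lv[1], version = lv[2],
                 modelId = modelId))
}

# structural validation: required SBML elements/attributes and referential
# integrity of species and parameter references
.checkSbmlStructure <- function(doc) {
  root <- xml2::xml_root(doc)
  if (xml_name(root) != "sbml" || is.na(xml_attr(root, "level")))
    stop("not an SBML document")
  d <- xml_ns_strip(read_xml(as.character(doc)))
  sp <- xml_attr(xml_find_all(d, ".//listOfSpecies/species"), "id")
  if (anyDuplicated(sp)) stop("duplicate species ids")
  pars <- xml_attr(xml_find_all(d, ".//listOfParameters/parameter"), "id")
  for (ref in xml_find_all(d, ".//speciesReference")) {
    if (!(xml_attr(ref, "species") %in% sp))
      stop("speciesReference to unknown species: ", xml_attr(ref, "species"))
  }
  invisible(TRUE)
}

.unsupported <- function(what) {
  stop("unsupported SBML construct for mass-action import: ", what,
       call. = FALSE)
}

#' Import an SBML file as a kinetic model
#'
#' Reconstructs a [KineticModel-class] from SBML with mass-action kinetic
#' laws of total reactant order at most 2. Documents using constructs
#' outside that class (assignment/rate/algebraic rules, events, function
#' definitions, reversible reactions, local kinetic-law parameters whose
#' ids shadow nothing global) are rejected with a named diagnostic.
#'
#' @param path SBML file path.
#' @return a [KineticModel-class].
#' @export
importSBML <- function(path) {
  d <- xml_ns_strip(read_xml(path))
  if (xml_name(d) != "sbml") stop("not an SBML file")
  for (bad in c("listOfRules", "listOfEvents", "listOfFunctionDefinitions",
                "listOfConstraints", "listOfInitialAssignments"))
    if (length(xml_find_all(d, paste0(".//", bad))))
      .unsupported(bad)

  spNodes <- xml_find_all(d, ".//listOfSpecies/species")
  if (!length(spNodes)) stop("no species in SBML model")
  spName <- xml_attr(spNodes, "id")
  spInit <- as.numeric(xml_attr(spNodes, "initialAmount"))
  if (anyNA(spInit)) .unsupported("species without initialAmount")
  species <- do.call(rbind, lapply(seq_along(spName), function(i)
    speciesSpec(spName[i], spInit[i])))

  parNodes <- xml_find_all(d, ".//listOfParameters/parameter")
  rates <- setNames(as.numeric(xml_attr(parNodes, "value")),
                    xml_attr(parNodes, "id"))

  rxNodes <- xml_find_all(d, ".//listOfReactions/reaction")
  if (!length(rxNodes)) stop("no reactions in SBML model")
  reactions <- lapply(rxNodes, function(node) {
    if (identical(xml_attr(node, "reversible"), "true"))
      .unsupported("reversible reaction")
    getRefs <- function(xp) {
      refs <- xml_find_all(node, xp)
      unlist(lapply(refs, function(r) {
        st <- xml_attr(r, "stoichiometry")
        st <- if (is.na(st)) 1L else as.integer(as.numeric(st))
        rep(xml_attr(r, "species"), st)
      }))
    }
    reactants <- getRefs("./listOfReactants/speciesReference")
    products <- getRefs("./listOfProducts/speciesReference")
    if (length(reactants) > 2L) .unsupported("reaction of order > 2")
    math <- xml_find_first(node, "./kineticLaw/math")
    if (inherits(math, "xml_missing")) .unsupported("reaction without kineticLaw")
    cis <- trimws(xml_text(xml_find_all(math, ".//ci")))
    rateName <- setdiff(cis, spName)
    if (length(rateName) != 1L || !(rateName %in% names(rates)))
      .unsupported(paste0("non-mass-action kinetic law (",
                          paste(cis, collapse = ", "), ")"))
    extra <- setdiff(setdiff(cis, rateName), reactants)
    if (length(extra))
      .unsupported(paste0("kinetic law references non-reactant species ",
                          paste(extra, collapse = ", ")))
    reactionSpec(if (is.null(reactants)) character(0) else reactants,
                 if (is.null(products)) character(0) else products,
                 rateName)
  })
  usedRates <- unique(vapply(reactions, `[[`, character(1), "rate"))
  mdl <- xml_find_first(d, ".//model")
  name <- xml_attr(mdl, "name")
  if (is.na(name)) name <- xml_attr(mdl, "id")
  if (is.na(name)) name <- "imported_model"
  buildModel(name, species, reactions, rates[usedRates],
             notes = paste("imported from", basename(path)))
}
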