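# SBML Level 3 Version 1 (+ fbc v2) reader/writer built on xml2.
#
# The writer emits strict fbc: flux bounds as shared constant parameters,
# GPRs as fbc:geneProductAssociation trees, the biomass reaction as the
# active maximisation objective, formulas/charges as fbc species
# attributes. The reader inverts it; writeSBML %>% readSBML is an identity
# on the supported feature set (tested).

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a network as an SBML L3V1/fbc-v2 file
#'
#' @param network a [MetabolicNetwork-class].
#' @param path output file path.
#' @param modelId model id attribute.
#' @return `path`, invisibly.
#' @export
writeSBML <- function(network, path, modelId = "model") {
  stopifnot(is(network, "MetabolicNetwork"))
  met <- network@metabolites; rxn <- network@reactions
  S <- network@stoichiometry
  # integrity: every nonzero S entry must reference a declared metabolite
  if (!identical(rownames(S), met$id))
    stop("stoichiometry references undeclared metabolites")

  num <- function(x) formatC(x, digits = 17, format = "g")
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = modelId, "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in sort(unique(met$compartment)))
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")

  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(
      ls, "species", id = paste0("M_", met$id[i]),
      name = if ("name" %in% names(met)) met$name[i] else met$id[i],
      compartment = met$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false", "fbc:charge" = as.character(met$charge[i]))
    if (nzchar(met$formula[i]))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula[i])
  }

  bndVals <- sort(unique(c(rxn$lower, rxn$upper)))
  bndIds <- stats::setNames(sprintf("fb_%d", seq_along(bndVals)), num(bndVals))
  lp <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in seq_along(bndVals))
    xml2::xml_add_child(lp, "parameter", id = unname(bndIds[i]),
                        value = num(bndVals[i]), constant = "true",
                        sboTerm = "SBO:0000625")

  writeGpa <- function(parent, node) {
    if (!is.null(node$gene)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", node$gene))
    } else {
      el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
      for (a in node$args) writeGpa(el, a)
    }
  }

  lr <- xml2::xml_add_child(mod, "listOfReactions")
  for (j in seq_len(nrow(rxn))) {
    r <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", rxn$id[j]),
      name = if ("name" %in% names(rxn)) rxn$name[j] else rxn$id[j],
      reversible = if (rxn$lower[j] < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = unname(bndIds[num(rxn$lower[j])]),
      "fbc:upperFluxBound" = unname(bndIds[num(rxn$upper[j])]))
    st <- S[, j]
    nz <- which(st != 0)
    reac <- nz[st[nz] < 0]; prod <- nz[st[nz] > 0]
    if (length(reac)) {
      el <- xml2::xml_add_child(r, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(el, "speciesReference",
                            species = paste0("M_", met$id[i]),
                            stoichiometry = num(-st[i]), constant = "true")
    }
    if (length(prod)) {
      el <- xml2::xml_add_child(r, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(el, "speciesReference",
                            species = paste0("M_", met$id[i]),
                            stoichiometry = num(st[i]), constant = "true")
    }
    tree <- parseGPR(rxn$gpr[j])
    if (!is.null(tree)) {
      gpa <- xml2::xml_add_child(r, "fbc:geneProductAssociation")
      writeGpa(gpa, tree)
    }
  }

  if (length(network@biomassId)) {
    lo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", network@biomassId),
                        "fbc:coefficient" = "1")
  }

  genes <- networkGenes(network)
  if (length(genes)) {
    lg <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                          "fbc:label" = g)
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML L3V1/fbc-v2 file into a MetabolicNetwork
#'
#' Supports the feature set emitted by [writeSBML()]: fbc flux-bound
#' parameters, species formula/charge, geneProductAssociation GPRs and the
#' active maximisation objective (taken as the biomass reaction). Exchange
#' reactions are recognised as those touching exactly one extracellular
#' species.
#'
#' @param path SBML file path.
#' @return a [MetabolicNetwork-class].
#' @export
readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .SBML_NS, fbc = .FBC_NS)
  stripPre <- function(x, pre) sub(paste0("^", pre), "", x)

  spNodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met <- data.frame(
    id = stripPre(xml2::xml_attr(spNodes, "id"), "M_"),
    name = xml2::xml_attr(spNodes, "name"),
    compartment = xml2::xml_attr(spNodes, "compartment"),
    formula = xml2::xml_attr(spNodes, "fbc:chemicalFormula", ns = ns),
    charge = as.integer(xml2::xml_attr(spNodes, "fbc:charge", ns = ns)),
    stringsAsFactors = FALSE)
  met$formula[is.na(met$formula)] <- ""
  met$charge[is.na(met$charge)] <- 0L
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]

  pNodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pNodes, "value")),
                           xml2::xml_attr(pNodes, "id"))

  readGpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(list(gene = stripPre(xml2::xml_attr(node, "fbc:geneProduct", ns = ns), "G_")))
    list(op = nm, args = lapply(xml2::xml_children(node), readGpa))
  }
  gpaToString <- function(node) {
    if (!is.null(node$gene)) return(node$gene)
    parts <- vapply(node$args, function(a) {
      s <- gpaToString(a)
      if (is.null(a$gene)) paste0("(", s, ")") else s
    }, character(1))
    paste(parts, collapse = paste0(" ", node$op, " "))
  }

  rxNodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  nr <- length(rxNodes)
  ids <- stripPre(xml2::xml_attr(rxNodes, "id"), "R_")
  rxn <- data.frame(
    id = ids, name = xml2::xml_attr(rxNodes, "name"),
    lower = unname(pvals[xml2::xml_attr(rxNodes, "fbc:lowerFluxBound", ns = ns)]),
    upper = unname(pvals[xml2::xml_attr(rxNodes, "fbc:upperFluxBound", ns = ns)]),
    gpr = "", subsystem = "", stringsAsFactors = FALSE)
  rxn$name[is.na(rxn$name)] <- rxn$id[is.na(rxn$name)]

  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_len(nr)) {
    for (sr in xml2::xml_find_all(rxNodes[[j]], "./s:listOfReactants/s:speciesReference", ns)) {
      i <- match(stripPre(xml2::xml_attr(sr, "species"), "M_"), met$id)
      ii <- c(ii, i); jj <- c(jj, j)
      xx <- c(xx, -as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    }
    for (sr in xml2::xml_find_all(rxNodes[[j]], "./s:listOfProducts/s:speciesReference", ns)) {
      i <- match(stripPre(xml2::xml_attr(sr, "species"), "M_"), met$id)
      ii <- c(ii, i); jj <- c(jj, j)
      xx <- c(xx, as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    }
    gpa <- xml2::xml_find_first(rxNodes[[j]], "./fbc:geneProductAssociation", ns)
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) rxn$gpr[j] <- gpaToString(readGpa(kids[[1]]))
    }
  }
  if (anyNA(ii)) stop("SBML reaction references an undeclared species")
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(met), nr),
                            dimnames = list(met$id, rxn$id))

  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  biomassId <- if (inherits(fo, "xml_missing")) character() else
    stripPre(xml2::xml_attr(fo, "fbc:reaction", ns = ns), "R_")

  touch <- Matrix::colSums(S != 0)
  exch <- character()
  for (j in which(touch == 1)) {
    i <- which(S[, j] != 0)
    if (met$compartment[i] == "e") exch <- c(exch, rxn$id[j])
  }

  new("MetabolicNetwork", metabolites = met, reactions = rxn,
      stoichiometry = S, biomassId = biomassId, exchangeIds = exch)
}
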