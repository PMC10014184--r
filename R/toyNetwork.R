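# Deterministic toy network: carnitine shuttle + mitochondrial beta-oxidation
# plus an alternative glycolytic route to the biomass precursor.
#
# The network carries an activated fatty acid across three compartments
# (extracellular "e", cytosol "c", mitochondrion "m"): uptake, cytosolic
# activation to the acyl-CoA, the carnitine shuttle into the mitochondrion,
# an iterative beta-oxidation cascade shortening the chain by one acetyl
# unit per round, and release of acetyl units that feed biomass. A glucose
# branch produces the same biomass precursor, so growth never depends on the
# fatty-acid branch. Elemental compositions are built from fixed moieties
# (acetyl unit C2H4O2, CoA, carnitine, ...) so that every internal reaction
# is mass- and charge-balanced by construction; all species are modelled as
# neutral.

.MOIETIES <- list(
  ac   = c(C = 2,  H = 4,  O = 2),
  coa  = c(C = 21, H = 36, N = 7, O = 16, P = 3, S = 1),
  carn = c(C = 7,  H = 15, N = 1, O = 3),
  glc  = c(C = 6,  H = 12, O = 6),
  o2   = c(O = 2),
  co2  = c(C = 1,  O = 2),
  h2o  = c(H = 2,  O = 1),
  nh4  = c(H = 4,  N = 1),
  pi   = c(H = 3,  O = 4, P = 1)
)

.addComp <- function(...) {
  vs <- list(...)
  # accept both vectors and (nested) lists of vectors
  flat <- list()
  for (v in vs) if (is.list(v)) flat <- c(flat, v) else flat <- c(flat, list(v))
  out <- c()
  for (v in flat) for (el in names(v))
    out[el] <- (if (el %in% names(out)) out[el] else 0) + v[el]
  out[out != 0]
}

.formulaString <- function(comp) {
  if (!length(comp)) return("")
  els <- names(comp)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(el) {
    n <- comp[[el]]
    if (n == 1) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' Generate the toy carnitine-shuttle / beta-oxidation network
#'
#' Builds a deterministic three-compartment metabolic network with a
#' fatty-acid branch (uptake, cytosolic activation by an isozyme family,
#' carnitine shuttle, `nRounds` rounds of mitochondrial beta-oxidation by
#' multi-subunit complexes, acetyl-unit release) and an alternative glucose
#' branch, both feeding a balanced biomass formation reaction. Activation
#' and shuttle steps carry `or`-rules over several isozymes; each
#' beta-oxidation round carries an `and`-rule over three subunits,
#' mirroring the association patterns typical of these pathways.
#'
#' @param nRounds number of beta-oxidation rounds (chain length of the
#'   fatty acid in acetyl units is `nRounds + 1`); must be >= 1.
#' @param maxFlux default flux bound magnitude (flux units).
#' @param uptake default maximal uptake for medium exchanges.
#' @return a [MetabolicNetwork-class]; growth on [defaultMedium()] is
#'   feasible, and remains feasible with the whole fatty-acid branch removed.
#' @examples
#' net <- generateToyNetwork()
#' optimizeGrowth(net, defaultMedium(net))@objective > 0
#' @export
generateToyNetwork <- function(nRounds = 3, maxFlux = 100, uptake = 10) {
  if (!is.numeric(nRounds) || length(nRounds) != 1L || nRounds < 1 ||
      nRounds != round(nRounds))
    stop("nRounds must be a positive integer")
  nRounds <- as.integer(nRounds)
  K <- nRounds + 1L                     # chain length in acetyl units

  mets <- list(); comps <- list()
  addMet <- function(id, name, compartment, comp) {
    mets[[id]] <<- data.frame(id = id, name = name, compartment = compartment,
                              stringsAsFactors = FALSE)
    comps[[id]] <<- comp
  }
  M <- .MOIETIES
  faComp <- .addComp(rep(list(M$ac), K))
  acylComp <- function(k) .addComp(c(rep(list(M$ac), k), list(M$coa)))

  # extracellular
  addMet("fa_e", "fatty acid", "e", faComp)
  addMet("glc_e", "glucose", "e", M$glc)
  addMet("o2_e", "oxygen", "e", M$o2)
  addMet("co2_e", "carbon dioxide", "e", M$co2)
  addMet("h2o_e", "water", "e", M$h2o)
  addMet("nh4_e", "ammonium", "e", M$nh4)
  addMet("pi_e", "phosphate", "e", M$pi)
  # cytosol
  addMet("fa_c", "fatty acid", "c", faComp)
  addMet("glc_c", "glucose", "c", M$glc)
  addMet("o2_c", "oxygen", "c", M$o2)
  addMet("co2_c", "carbon dioxide", "c", M$co2)
  addMet("h2o_c", "water", "c", M$h2o)
  addMet("nh4_c", "ammonium", "c", M$nh4)
  addMet("pi_c", "phosphate", "c", M$pi)
  addMet("coa_c", "coenzyme A", "c", M$coa)
  addMet("carn_c", "carnitine", "c", M$carn)
  addMet("facoa_c", "acyl-CoA", "c", acylComp(K))
  addMet("facarn_c", "acyl-carnitine", "c", .addComp(faComp, M$carn))
  addMet("prec_c", "biomass precursor", "c", M$ac)
  # mitochondrion
  addMet("facarn_m", "acyl-carnitine", "m", .addComp(faComp, M$carn))
  addMet("carn_m", "carnitine", "m", M$carn)
  addMet("coa_m", "coenzyme A", "m", M$coa)
  for (k in seq(K, 2L)) addMet(sprintf("acyl%dcoa_m", k),
                               sprintf("acyl-CoA (C%d)", 2L * k), "m", acylComp(k))
  addMet("accoa_m", "acetyl-CoA", "m", acylComp(1L))
  addMet("prec_m", "biomass precursor", "m", M$ac)
  # biomass species
  bioComp <- .addComp(M$ac, M$ac, M$nh4, M$pi)
  addMet("biomass_c", "biomass", "c", bioComp)
  addMet("biomass_e", "biomass", "e", bioComp)

  metTab <- do.call(rbind, mets)
  metTab$formula <- vapply(comps[metTab$id], .formulaString, character(1))
  metTab$charge <- 0L
  rownames(metTab) <- NULL

  rxns <- list(); trip <- list()
  addRxn <- function(id, name, stoich, lower, upper, gpr = "", subsystem = "") {
    rxns[[id]] <<- data.frame(id = id, name = name, lower = lower, upper = upper,
                              gpr = gpr, subsystem = subsystem, stringsAsFactors = FALSE)
    trip[[id]] <<- stoich
  }
  ex <- function(met, lower, upper)
    addRxn(paste0("EX_", met), paste("exchange of", met),
           stats::setNames(-1, met), lower, upper, subsystem = "exchange")

  ex("fa_e", -uptake, maxFlux)
  ex("glc_e", -uptake, maxFlux)
  ex("o2_e", -2 * uptake, maxFlux)
  ex("co2_e", 0, maxFlux)
  ex("h2o_e", -maxFlux, maxFlux)
  ex("nh4_e", -uptake, maxFlux)
  ex("pi_e", -uptake, maxFlux)
  ex("biomass_e", 0, maxFlux)

  addRxn("FAT", "fatty acid transport", c(fa_e = -1, fa_c = 1), 0, maxFlux,
         "fatpA or fatpB", "fatty acid uptake")
  addRxn("GLCT", "glucose transport", c(glc_e = -1, glc_c = 1), 0, maxFlux,
         "glctA", "glucose uptake")
  addRxn("O2T", "oxygen diffusion", c(o2_e = -1, o2_c = 1), -maxFlux, maxFlux,
         "o2tA")
  addRxn("CO2T", "carbon dioxide diffusion", c(co2_c = -1, co2_e = 1), -maxFlux,
         maxFlux, "co2tA")
  addRxn("H2OT", "water diffusion", c(h2o_c = -1, h2o_e = 1), -maxFlux, maxFlux,
         "aqpA")
  addRxn("NH4T", "ammonium transport", c(nh4_e = -1, nh4_c = 1), 0, maxFlux,
         "nh4tA")
  addRxn("PIT", "phosphate transport", c(pi_e = -1, pi_c = 1), 0, maxFlux,
         "pitA")
  addRxn("BIOT", "biomass export", c(biomass_c = -1, biomass_e = 1), 0, maxFlux,
         "secA")

  addRxn("FACS", "fatty acid activation (cytosol)",
         c(fa_c = -1, coa_c = -1, facoa_c = 1), 0, maxFlux,
         "facsA or facsB or facsC", "fatty acid activation")
  addRxn("CPT1", "carnitine acyltransferase (cytosol)",
         c(facoa_c = -1, carn_c = -1, facarn_c = 1, coa_c = 1), 0, maxFlux,
         "cshA1 or cshA2", "carnitine shuttle")
  addRxn("CACT", "acyl-carnitine translocase",
         c(facarn_c = -1, facarn_m = 1), 0, maxFlux,
         "cactA or cactB", "carnitine shuttle")
  addRxn("CPT2", "carnitine acyltransferase (mitochondrion)",
         c(facarn_m = -1, coa_m = -1,
           stats::setNames(1, sprintf("acyl%dcoa_m", K)), carn_m = 1),
         0, maxFlux, "cshB1 or cshB2", "carnitine shuttle")
  addRxn("CRET", "carnitine return",
         c(carn_m = -1, carn_c = 1), 0, maxFlux,
         "cactA or cactB", "carnitine shuttle")

  for (i in seq_len(nRounds)) {
    k <- K - i + 1L                     # chain length entering round i
    subIn <- sprintf("acyl%dcoa_m", k)
    st <- stats::setNames(c(-1, -1), c(subIn, "coa_m"))
    if (k - 1L == 1L) {
      st["accoa_m"] <- 2      # final round: the shortened chain *is* acetyl-CoA
    } else {
      st[sprintf("acyl%dcoa_m", k - 1L)] <- 1
      st["accoa_m"] <- 1
    }
    addRxn(sprintf("BOX%d", i), sprintf("beta-oxidation round %d", i),
           st, 0, maxFlux,
           sprintf("boxA%d and boxB%d and boxC%d", i, i, i), "beta-oxidation")
  }

  addRxn("THIO", "acetyl unit release",
         c(accoa_m = -1, prec_m = 1, coa_m = 1), 0, maxFlux,
         "thioA and thioB", "beta-oxidation")
  addRxn("PRET", "precursor export from mitochondrion",
         c(prec_m = -1, prec_c = 1), 0, maxFlux, "pretA")
  addRxn("GLYC", "glycolytic precursor formation",
         c(glc_c = -1, prec_c = 3), 0, maxFlux,
         "glyA or glyB", "glycolysis")
  addRxn("RESP", "precursor oxidation",
         c(prec_c = -1, o2_c = -2, co2_c = 2, h2o_c = 2), 0, maxFlux,
         "respA and respB", "respiration")
  addRxn("BIOMASS", "biomass formation",
         c(prec_c = -2, nh4_c = -1, pi_c = -1, biomass_c = 1), 0, maxFlux,
         "", "biomass")

  rxnTab <- do.call(rbind, rxns)
  rownames(rxnTab) <- NULL

  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_len(nrow(rxnTab))) {
    st <- trip[[rxnTab$id[j]]]
    st <- st[st != 0]
    ii <- c(ii, match(names(st), metTab$id))
    jj <- c(jj, rep(j, length(st)))
    xx <- c(xx, unname(st))
  }
  if (anyNA(ii)) stop("reaction references an undeclared metabolite")
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metTab), nrow(rxnTab)),
                            dimnames = list(metTab$id, rxnTab$id))

  new("MetabolicNetwork",
      metabolites = metTab, reactions = rxnTab, stoichiometry = S,
      biomassId = "BIOMASS",
      exchangeIds = grep("^EX_", rxnTab$id, value = TRUE))
}

#' Default growth medium of the toy network
#'
#' Maximal uptake rates (flux units) for the medium components: glucose,
#' fatty acid, oxygen, phosphate, ammonium and water.
#'
#' @param network a [MetabolicNetwork-class] (used to check the exchanges exist).
#' @param uptake base uptake rate.
#' @return named numeric vector, exchange reaction id -> maximal uptake.
#' @export
defaultMedium <- function(network, uptake = 10) {
  med <- c(EX_glc_e = uptake, EX_fa_e = uptake, EX_o2_e = 2 * uptake,
           EX_pi_e = uptake, EX_nh4_e = uptake, EX_h2o_e = 10 * uptake)
  med[names(med) %in% exchangeReactions(network)]
}

#' Reactions and genes of the toy fatty-acid branch
#'
#' Ids of the reactions forming the carnitine-shuttle / beta-oxidation
#' branch (uptake, activation, shuttle, oxidation rounds, acetyl release)
#' and the genes appearing in their GPR rules. Used by the proteome
#' simulator to plant the disease-elevated cluster.
#'
#' @param network a toy network from [generateToyNetwork()].
#' @return list with elements `reactions` and `genes`.
#' @export
fattyAcidBranch <- function(network) {
  ids <- reactions(network)$id
  branch <- c("EX_fa_e", "FAT", "FACS", "CPT1", "CACT", "CPT2", "CRET",
              grep("^BOX", ids, value = TRUE), "THIO", "PRET")
  branch <- intersect(branch, ids)
  genes <- unique(unlist(lapply(reactions(network)$gpr[match(branch, ids)], gprGenes)))
  list(reactions = branch, genes = genes)
}
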