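#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t colSums rowSums
#' @importClassesFrom Matrix Matrix dgCMatrix
#' @importFrom stats median setNames rnorm rlnorm
#' @importFrom utils read.table write.table combn head tail
NULL

#' MetabolicNetwork: a compartmentalised stoichiometric model
#'
#' Container for a constraint-based metabolic network: metabolite and
#' reaction annotation tables, the sparse stoichiometric matrix S
#' (metabolites x reactions), flux bounds, gene-protein-reaction (GPR)
#' boolean rules, and the identities of the biomass and exchange reactions.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of `"e"`, `"c"`, `"m"`, ...), `formula` (elemental composition
#'   string, Hill-ordered) and `charge` (integer).
#' @slot reactions data.frame with columns `id`, `name`, `lower`, `upper`
#'   (flux bounds, mmol/gDW/h in arbitrary units), `gpr` (boolean rule over
#'   gene symbols, `""` when none) and `subsystem`.
#' @slot stoichiometry sparse `dgCMatrix`, rows = metabolites, columns =
#'   reactions, entries = stoichiometric coefficients (negative = consumed).
#' @slot biomassId id of the biomass formation reaction.
#' @slot exchangeIds ids of the exchange reactions (each touches exactly one
#'   extracellular species; negative flux = uptake).
#'
#' @seealso [generateToyNetwork()], [readSBML()], [writeSBML()]
#' @export
setClass("MetabolicNetwork", slots = c(
  metabolites   = "data.frame",
  reactions     = "data.frame",
  stoichiometry = "Matrix",
  biomassId     = "character",
  exchangeIds   = "character"
))

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  met <- object@metabolites; rxn <- object@reactions; S <- object@stoichiometry
  if (!all(c("id", "compartment", "formula", "charge") %in% names(met)))
    msg <- c(msg, "metabolites must have id/compartment/formula/charge columns")
  if (!all(c("id", "lower", "upper", "gpr") %in% names(rxn)))
    msg <- c(msg, "reactions must have id/lower/upper/gpr columns")
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msg <- c(msg, "stoichiometry dimensions do not match annotation tables")
  else {
    if (!identical(rownames(S), met$id)) msg <- c(msg, "S rownames != metabolite ids")
    if (!identical(colnames(S), rxn$id)) msg <- c(msg, "S colnames != reaction ids")
  }
  if (any(rxn$lower > rxn$upper)) msg <- c(msg, "lower bound exceeds upper bound")
  if (length(object@biomassId) > 1L)
    msg <- c(msg, "biomassId must name at most one reaction")
  else if (length(object@biomassId) == 1L) {
    if (!(object@biomassId %in% rxn$id))
      msg <- c(msg, "biomassId must name an existing reaction")
    else if (rxn$upper[match(object@biomassId, rxn$id)] <= 0)
      msg <- c(msg, "biomass reaction must have upper bound > 0")
  }
  if (!all(object@exchangeIds %in% rxn$id))
    msg <- c(msg, "exchangeIds must exist among reactions")
  else if (length(object@exchangeIds) && nrow(S) == nrow(met)) {
    for (ex in object@exchangeIds) {
      touched <- which(S[, ex] != 0)
      if (length(touched) != 1L)
        msg <- c(msg, sprintf("exchange %s must touch exactly one metabolite", ex))
      else if (met$compartment[touched] != "e")
        msg <- c(msg, sprintf("exchange %s must touch an extracellular species", ex))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ContextModel: an expression-conditioned subnetwork of a parent network
#'
#' One context-specific model: the subset of parent reactions retained by
#' expression-driven extraction, the reactions added back by growth
#' gap-filling, and the growth medium it is simulated on.
#'
#' @slot parent the generic [MetabolicNetwork-class] it was extracted from.
#' @slot kept ids of reactions retained by extraction.
#' @slot gapfilled ids of reactions added by gap-filling (disjoint from kept).
#' @slot medium named numeric vector: exchange reaction id -> maximal uptake.
#' @slot sampleId sample the model belongs to.
#' @slot group experimental group of the sample.
#' @export
setClass("ContextModel", slots = c(
  parent    = "MetabolicNetwork",
  kept      = "character",
  gapfilled = "character",
  medium    = "numeric",
  sampleId  = "character",
  group     = "character"
))

setValidity("ContextModel", function(object) {
  msg <- character()
  ids <- object@parent@reactions$id
  if (!all(object@kept %in% ids)) msg <- c(msg, "kept reactions missing from parent")
  if (!all(object@gapfilled %in% ids)) msg <- c(msg, "gapfilled reactions missing from parent")
  if (length(intersect(object@kept, object@gapfilled)))
    msg <- c(msg, "kept and gapfilled sets must be disjoint")
  if (length(object@medium) && is.null(names(object@medium)))
    msg <- c(msg, "medium must be a named vector of uptake limits")
  if (length(msg)) msg else TRUE
})

#' FluxState: a steady-state flux distribution
#'
#' @slot fluxes named numeric vector of reaction fluxes (flux units).
#' @slot objective value of the optimisation objective that produced it
#'   (growth rate for FBA, total absolute deviation for LAD fits).
#' @slot status solver status string (`"optimal"` etc.).
#' @export
setClass("FluxState", slots = c(
  fluxes    = "numeric",
  objective = "numeric",
  status    = "character"
))

setMethod("show", "MetabolicNetwork", function(object) {
  cat(sprintf("MetabolicNetwork: %d metabolites x %d reactions\n",
              nrow(object@metabolites), nrow(object@reactions)))
  cat(sprintf("  compartments: %s\n",
              paste(sort(unique(object@metabolites$compartment)), collapse = ", ")))
  cat(sprintf("  biomass: %s | exchanges: %d | reactions with GPR: %d\n",
              if (length(object@biomassId)) object@biomassId else "<none>",
              length(object@exchangeIds),
              sum(nzchar(object@reactions$gpr))))
})

setMethod("show", "ContextModel", function(object) {
  cat(sprintf("ContextModel [%s, %s]: %d kept + %d gap-filled of %d parent reactions\n",
              object@sampleId, object@group, length(object@kept),
              length(object@gapfilled), nrow(object@parent@reactions)))
})

setMethod("show", "FluxState", function(object) {
  cat(sprintf("FluxState: %d reactions, objective %.6g, status %s\n",
              length(object@fluxes), object@objective, object@status))
})
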