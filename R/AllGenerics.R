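#' Accessors for network and context-model objects
#'
#' Standard accessors: `metabolites()` and `reactions()` return the
#' annotation tables, `stoichiometry()` the sparse S matrix, `bounds()` a
#' two-column matrix of flux bounds, `gprRules()` the named vector of GPR
#' strings, `biomassReaction()` / `exchangeReactions()` the special reaction
#' ids. For a [ContextModel-class], `keptReactions()`, `gapfilledReactions()`
#' and `growthMedium()` expose the extraction result, and `asNetwork()`
#' materialises the context as a standalone [MetabolicNetwork-class].
#'
#' @param x a `MetabolicNetwork` or `ContextModel`.
#' @return See individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("bounds", function(x) standardGeneric("bounds"))
#' @rdname accessors
#' @export
setGeneric("gprRules", function(x) standardGeneric("gprRules"))
#' @rdname accessors
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))
#' @rdname accessors
#' @export
setGeneric("exchangeReactions", function(x) standardGeneric("exchangeReactions"))
#' @rdname accessors
#' @export
setGeneric("keptReactions", function(x) standardGeneric("keptReactions"))
#' @rdname accessors
#' @export
setGeneric("gapfilledReactions", function(x) standardGeneric("gapfilledReactions"))
#' @rdname accessors
#' @export
setGeneric("growthMedium", function(x) standardGeneric("growthMedium"))
#' @rdname accessors
#' @export
setGeneric("asNetwork", function(x) standardGeneric("asNetwork"))

#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicNetwork", function(x) x@metabolites)
#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicNetwork", function(x) x@reactions)
#' @rdname accessors
#' @export
setMethod("stoichiometry", "MetabolicNetwork", function(x) x@stoichiometry)
#' @rdname accessors
#' @export
setMethod("bounds", "MetabolicNetwork", function(x) {
  cbind(lower = stats::setNames(x@reactions$lower, x@reactions$id),
        upper = x@reactions$upper)
})
#' @rdname accessors
#' @export
setMethod("gprRules", "MetabolicNetwork", function(x)
  stats::setNames(x@reactions$gpr, x@reactions$id))
#' @rdname accessors
#' @export
setMethod("biomassReaction", "MetabolicNetwork", function(x) x@biomassId)
#' @rdname accessors
#' @export
setMethod("exchangeReactions", "MetabolicNetwork", function(x) x@exchangeIds)

#' @rdname accessors
#' @export
setMethod("keptReactions", "ContextModel", function(x) x@kept)
#' @rdname accessors
#' @export
setMethod("gapfilledReactions", "ContextModel", function(x) x@gapfilled)
#' @rdname accessors
#' @export
setMethod("growthMedium", "ContextModel", function(x) x@medium)
#' @rdname accessors
#' @export
setMethod("asNetwork", "ContextModel", function(x)
  subnetwork(x@parent, union(x@kept, x@gapfilled)))
#' @rdname accessors
#' @export
setMethod("metabolites", "ContextModel", function(x) metabolites(asNetwork(x)))
#' @rdname accessors
#' @export
setMethod("reactions", "ContextModel", function(x) reactions(asNetwork(x)))

#' Restrict a network to a reaction subset
#'
#' Drops all reactions outside `reactionIds` and any metabolite no longer
#' touched by a remaining reaction. Biomass and exchange bookkeeping is
#' retained where the corresponding reactions survive.
#'
#' @param network a [MetabolicNetwork-class].
#' @param reactionIds character vector of reaction ids to keep.
#' @return a [MetabolicNetwork-class].
#' @export
subnetwork <- function(network, reactionIds) {
  stopifnot(is(network, "MetabolicNetwork"))
  missing <- setdiff(reactionIds, network@reactions$id)
  if (length(missing))
    stop("unknown reaction ids: ", paste(missing, collapse = ", "))
  if (!length(reactionIds))
    return(new("MetabolicNetwork",
               metabolites = network@metabolites[0, , drop = FALSE],
               reactions = network@reactions[0, , drop = FALSE],
               stoichiometry = network@stoichiometry[0, 0, drop = FALSE],
               biomassId = character(), exchangeIds = character()))
  keep <- network@reactions$id %in% reactionIds
  S <- network@stoichiometry[, keep, drop = FALSE]
  metKeep <- Matrix::rowSums(S != 0) > 0
  S <- S[metKeep, , drop = FALSE]
  bid <- intersect(network@biomassId, colnames(S))
  new("MetabolicNetwork",
      metabolites = network@metabolites[metKeep, , drop = FALSE],
      reactions = network@reactions[keep, , drop = FALSE],
      stoichiometry = S,
      biomassId = bid,
      exchangeIds = intersect(network@exchangeIds, colnames(S)))
}
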