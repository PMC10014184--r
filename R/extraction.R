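# Expression-driven extraction of context-specific models.
#
# Each reaction receives an evidence weight from the sample's proteome via
# its GPR (isozymes add, complex subunits take the minimum), log-scaled
# against the sample's median reaction-level expression. Extraction chooses
# the reaction subset maximising total evidence subject to every included
# reaction being able to carry steady-state flux within the subset. Because
# excluding a reaction can only block others (never unblock them), the
# optimum always keeps every non-negative-weight reaction that remains
# unblocked; the search space is therefore the subsets of negative-weight
# reactions, each completed by its flux-consistent closure. Small instances
# are solved exactly by enumeration over that space, larger ones by greedy
# pruning.

#' Score reactions against a sample's expression
#'
#' GPR rules are evaluated with `or` = sum (isozyme capacities add) and
#' `and` = min (a complex is limited by its scarcest subunit), giving a
#' reaction-level expression e_j. The evidence weight is
#' `w_j = clip(ln(e_j / tau), -wMax, wMax)`: positive above the threshold
#' `tau`, negative below. Reactions without a GPR get a small negative
#' weight (weak evidence against); exchange and biomass reactions are
#' neutral (weight 0).
#'
#' @param network a [MetabolicNetwork-class].
#' @param expression named numeric vector, gene -> abundance, for one sample.
#' @param tau expression threshold (> 0); default: median reaction-level
#'   expression of the GPR-bearing reactions of this sample.
#' @param wMax clipping bound for |w|.
#' @param noGprWeight weight of GPR-less internal reactions.
#' @return data.frame: `reaction`, `expression` (e_j, NA where no GPR),
#'   `weight`, `provenance` in `{"gpr", "no-gpr", "exchange", "biomass"}`.
#' @export
scoreReactions <- function(network, expression, tau = NULL, wMax = 5,
                           noGprWeight = -0.1) {
  rxn <- reactions(network)
  if (!any(names(expression) %in% networkGenes(network)))
    stop("expression covers no gene of the network")
  ej <- vapply(rxn$gpr, function(g) {
    v <- evalGPR(g, expression)
    if (is.na(v)) NA_real_ else v
  }, numeric(1), USE.NAMES = FALSE)
  if (is.null(tau)) tau <- stats::median(ej, na.rm = TRUE)
  if (!is.finite(tau) || tau <= 0) stop("invalid threshold: tau must be > 0")

  prov <- ifelse(rxn$id %in% exchangeReactions(network), "exchange",
          ifelse(rxn$id %in% biomassReaction(network), "biomass",
          ifelse(is.na(ej), "no-gpr", "gpr")))
  w <- ifelse(prov == "gpr",
              pmin(pmax(suppressWarnings(log(ej / tau)), -wMax), wMax),
              ifelse(prov == "no-gpr", noGprWeight, 0))
  w[prov == "gpr" & ej <= 0] <- -wMax
  data.frame(reaction = rxn$id, expression = ej, weight = w,
             provenance = prov, row.names = NULL, stringsAsFactors = FALSE)
}

# score of a reaction set
.setScore <- function(w, ids) sum(w[ids])

#' Extract a context-specific model from evidence weights
#'
#' Maximises the summed evidence weight of the included reactions subject
#' to flux consistency: every included reaction must be able to carry
#' nonzero steady-state flux using only included reactions. `method
#' = "exact"` enumerates all exclusion subsets of negative-weight reactions
#' (each completed by its flux-consistent closure) and is guaranteed
#' optimal; `"greedy"` iteratively drops the most negative-weight reaction
#' whose removal (with closure) improves the objective. `"auto"` uses the
#' exact search up to `exactLimit` negative-weight candidates, greedy
#' beyond (with a message).
#'
#' @param network the parent [MetabolicNetwork-class].
#' @param scores result of [scoreReactions()] (or a named weight vector
#'   covering all reactions).
#' @param medium optional named uptake vector constraining exchanges during
#'   the consistency checks (default: bounds as stored).
#' @param requiredTasks optional list of functional requirements the model
#'   must keep; currently `list(biomass = vMin)` demands biomass flux >=
#'   vMin. Default `NULL`: growth is restored later by [gapfillGrowth()].
#' @param method `"auto"`, `"exact"` or `"greedy"`.
#' @param exactLimit largest negative-candidate count attempted exactly.
#' @param sampleId,group metadata stored in the result.
#' @param cacheEnv optional environment memoising consistency closures
#'   across calls on the same network/medium (used by [runPipeline()];
#'   samples of the same group typically revisit identical subnetworks).
#' @return a [ContextModel-class] (gap-fill set empty).
#' @export
extractContext <- function(network, scores, medium = NULL, requiredTasks = NULL,
                           method = c("auto", "exact", "greedy"),
                           exactLimit = 12L, sampleId = "sample", group = "",
                           cacheEnv = NULL) {
  method <- match.arg(method)
  w <- if (is.data.frame(scores)) stats::setNames(scores$weight, scores$reaction)
       else scores
  ids <- reactions(network)$id
  if (!all(ids %in% names(w))) stop("scores must cover all reactions")
  w <- w[ids]
  if (any(!is.finite(w))) stop("non-finite reaction weights")

  vMin <- if (!is.null(requiredTasks$biomass)) requiredTasks$biomass else NULL

  memo <- function(key, compute) {
    if (is.null(cacheEnv)) return(compute())
    if (!exists(key, envir = cacheEnv, inherits = FALSE))
      assign(key, compute(), envir = cacheEnv)
    get(key, envir = cacheEnv, inherits = FALSE)
  }
  closure <- function(sub) {
    if (!length(sub)) return(character())
    sub <- sort(sub)
    memo(paste0("c|", paste(sub, collapse = ",")),
         function() fluxConsistentSet(subnetwork(network, sub), medium))
  }
  taskOk <- function(sub) {
    if (is.null(vMin)) return(TRUE)
    if (!length(intersect(biomassReaction(network), sub))) return(FALSE)
    memo(paste0("t|", paste(sort(sub), collapse = ",")),
         function() .canGrow(subnetwork(network, sub), medium, vMin))
  }
  base <- closure(ids)
  if (!is.null(vMin) && !taskOk(base))
    stop("extraction infeasible: required tasks fail on the full consistent network")

  negatives <- base[w[base] < 0]
  if (method == "auto")
    method <- if (length(negatives) <= exactLimit) "exact" else "greedy"
  if (method == "exact" && length(negatives) > exactLimit) {
    message("exact extraction limited to ", exactLimit,
            " candidates; falling back to greedy")
    method <- "greedy"
  }

  if (method == "exact") {
    best <- base; bestScore <- .setScore(w, base)
    nn <- length(negatives)
    if (nn > 0) {
      for (mask in seq_len(2^nn - 1)) {
        excl <- negatives[bitwAnd(mask, 2^(seq_len(nn) - 1)) > 0]
        sub <- closure(setdiff(base, excl))
        if (!taskOk(sub)) next
        sc <- .setScore(w, sub)
        if (sc > bestScore + 1e-12 ||
            (abs(sc - bestScore) <= 1e-12 && length(sub) < length(best))) {
          best <- sub; bestScore <- sc
        }
      }
    }
    kept <- best
  } else {
    cur <- base
    failed <- character()
    repeat {
      cand <- setdiff(cur[w[cur] < 0], failed)
      if (!length(cand)) break
      cand <- cand[order(w[cand])]           # most negative first
      improved <- FALSE
      for (j in cand) {
        sub <- closure(setdiff(cur, j))
        if (.setScore(w, sub) > .setScore(w, cur) + 1e-12 && taskOk(sub)) {
          cur <- sub; improved <- TRUE; break
        }
        failed <- c(failed, j)
      }
      if (!improved) break
    }
    kept <- cur
  }

  new("ContextModel", parent = network, kept = sort(kept),
      gapfilled = character(),
      medium = if (is.null(medium)) stats::setNames(numeric(), character()) else medium,
      sampleId = sampleId, group = group)
}

#' Gap-fill a context model to restore in-silico growth
#'
#' Adds a minimum-cardinality set of parent-network reactions to the
#' context so that biomass flux >= `vMin` is feasible on the medium. With
#' at most `exactLimit` candidate reactions the minimum is found by
#' exhaustive enumeration over subset sizes; beyond that, an
#' irreducible set is computed by opening all candidates and greedily
#' removing redundant ones (minimal, though not guaranteed
#' minimum-cardinality).
#'
#' @param context a [ContextModel-class].
#' @param medium named uptake vector (default: the context's medium).
#' @param vMin growth requirement (flux units).
#' @param exactLimit largest candidate count attempted exhaustively.
#' @param cacheEnv optional memoisation environment (see [extractContext()]).
#' @return the context with `gapfilled` filled in; idempotent.
#' @export
gapfillGrowth <- function(context, medium = NULL, vMin = 1e-3, exactLimit = 12L,
                          cacheEnv = NULL) {
  stopifnot(is(context, "ContextModel"))
  if (is.null(medium)) medium <- if (length(context@medium)) context@medium else NULL
  parent <- context@parent
  have <- union(context@kept, context@gapfilled)
  grows <- function(sub) {
    compute <- function() .canGrow(subnetwork(parent, sub), medium, vMin)
    if (is.null(cacheEnv)) return(compute())
    key <- paste0("g|", paste(sort(sub), collapse = ","))
    if (!exists(key, envir = cacheEnv, inherits = FALSE))
      assign(key, compute(), envir = cacheEnv)
    get(key, envir = cacheEnv, inherits = FALSE)
  }
  if (grows(have)) return(context)
  if (!grows(reactions(parent)$id))
    stop("gapfill infeasible: the parent network cannot reach the growth requirement")

  cand <- sort(setdiff(reactions(parent)$id, have))
  added <- NULL
  if (length(cand) <= exactLimit) {
    for (k in seq_along(cand)) {
      sets <- utils::combn(cand, k, simplify = FALSE)
      ok <- vapply(sets, function(s) grows(c(have, s)), logical(1))
      if (any(ok)) { added <- sets[[which(ok)[1]]]; break }
    }
  } else {
    # single additions first (the common repair), then irreducible shrink
    single <- cand[vapply(cand, function(s) grows(c(have, s)), logical(1))]
    if (length(single)) {
      added <- single[1]
    } else {
      added <- cand
      for (s in rev(cand)) {
        trial <- setdiff(added, s)
        if (grows(c(have, trial))) added <- trial
      }
    }
  }
  if (is.null(added)) stop("gapfill infeasible: no addition set restores growth")
  methods::initialize(context, gapfilled = sort(union(context@gapfilled, added)))
}
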