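# Flux estimation by least absolute deviation (LAD) against
# expression-derived targets, and per-metabolite flux-sum profiling.

#' Expression-derived flux targets
#'
#' Maps reaction-level expression linearly onto flux targets:
#' `d_j = ub_j * e_j / max_k e_k` for GPR-bearing internal reactions
#' (the most expressed reaction is targeted at its upper bound). Reactions
#' without a GPR, exchanges and the biomass reaction carry no target and
#' are excluded from the LAD objective.
#'
#' @param context a [ContextModel-class] (or [MetabolicNetwork-class]).
#' @param scores result of [scoreReactions()] on the parent network (its
#'   `expression` column supplies e_j), or a named expression vector per
#'   reaction.
#' @return named numeric vector of targets over the targeted reactions.
#' @export
expressionTargets <- function(context, scores) {
  net <- .asNetworkObj(context)
  ej <- if (is.data.frame(scores)) {
    prov <- stats::setNames(scores$provenance, scores$reaction)
    e <- stats::setNames(scores$expression, scores$reaction)
    e[prov %in% c("exchange", "biomass")] <- NA
    e
  } else scores
  rxn <- reactions(net)
  ids <- setdiff(rxn$id[nzchar(rxn$gpr)],
                 c(exchangeReactions(net), biomassReaction(net)))
  ids <- ids[!is.na(ej[ids])]
  if (!length(ids) || max(ej[ids]) <= 0)
    stop("no usable expression: all targeted reactions have zero expression")
  ub <- stats::setNames(rxn$upper, rxn$id)[ids]
  ub * ej[ids] / max(ej[ids])
}

#' Least-absolute-deviation flux fit
#'
#' Solves `min sum_j |v_j - d_j|` over the targeted reactions subject to
#' steady state `S v = 0`, flux bounds, medium uptake limits and biomass
#' flux >= `vMin`, as a linear program with split deviation variables.
#' Deviations are measured on the net flux.
#'
#' @param context a [ContextModel-class] (or network).
#' @param targets named target vector from [expressionTargets()].
#' @param medium named uptake limits (default: the context's medium).
#' @param vMin minimal biomass flux enforced during the fit.
#' @return a [FluxState-class]; `objective` is the summed absolute deviation.
#' @export
ladFit <- function(context, targets, medium = NULL, vMin = 1e-3) {
  if (is(context, "ContextModel") && is.null(medium) && length(context@medium))
    medium <- context@medium
  net <- .asNetworkObj(context)
  bnd <- .effectiveBounds(net, medium)
  ids <- net@reactions$id
  tgt <- targets[names(targets) %in% ids]
  if (!length(tgt)) stop("no targets overlap the model's reactions")
  S <- as.matrix(net@stoichiometry)
  m <- nrow(S); n <- ncol(S); k <- length(tgt)
  jt <- match(names(tgt), ids)

  lb <- bnd$lb; ub <- bnd$ub
  if (length(net@biomassId)) {
    jb <- match(net@biomassId, ids)
    lb[jb] <- max(lb[jb], vMin)
    if (lb[jb] > ub[jb]) stop("growth requirement exceeds the biomass upper bound")
  }

  # v_j - ePlus_j + eMinus_j = d_j for targeted j
  D <- matrix(0, k, n); D[cbind(seq_len(k), jt)] <- 1
  Aeq <- rbind(cbind(S, matrix(0, m, 2 * k)),
               cbind(D, -diag(k), diag(k)))
  beq <- c(numeric(m), unname(tgt))
  span <- max(abs(c(lb, ub))) + max(abs(tgt))
  lbv <- c(lb, numeric(2 * k))
  ubv <- c(ub, rep(2 * span, 2 * k))
  obj <- c(numeric(n), rep(1, 2 * k))
  res <- solveLP(obj, Aeq, beq, lbv, ubv, maximize = FALSE)
  if (res$status != "optimal") {
    fs <- optimizeGrowth(net, medium)
    stop("LAD fit infeasible (solver status ", res$status,
         "; growth check: ", fs@status, ")")
  }
  new("FluxState", fluxes = stats::setNames(res$x[seq_len(n)], ids),
      objective = res$objval, status = "optimal")
}

#' Flux-sum profile of a flux distribution
#'
#' The flux-sum of a metabolite is its total production at steady state,
#' `Phi_i = sum_j max(S_ij v_j, 0)`, equal to half its total absolute
#' turnover `0.5 * sum_j |S_ij v_j|`; it measures how much of the
#' metabolite is (re)generated per unit time and serves as a proxy for the
#' metabolite's importance.
#'
#' @param context a [ContextModel-class] (or network) the flux belongs to.
#' @param flux a [FluxState-class].
#' @param tol steady-state tolerance on `|S v|`.
#' @return named numeric vector, metabolite id -> flux-sum (>= 0).
#' @export
fluxSum <- function(context, flux, tol = 1e-6) {
  net <- .asNetworkObj(context)
  v <- flux@fluxes[net@reactions$id]
  if (anyNA(v)) stop("flux state does not cover the model's reactions")
  S <- as.matrix(net@stoichiometry)
  resid <- max(abs(S %*% v))
  if (resid > tol)
    stop("flux state violates steady state (max |S v| = ", format(resid), ")")
  P <- S * rep(v, each = nrow(S))           # S_ij * v_j
  phi <- rowSums(pmax(P, 0))
  stats::setNames(phi, net@metabolites$id)
}
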