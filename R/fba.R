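# Constraint-based simulation helpers built on the internal LP engine.

# Effective bounds of a network under a medium: exchanges listed in the
# medium may take up at most the stated rate (lower = -uptake); all other
# exchanges are secretion-only.
.effectiveBounds <- function(network, medium = NULL) {
  rxn <- network@reactions
  lb <- rxn$lower; ub <- rxn$upper
  names(lb) <- names(ub) <- rxn$id
  if (!is.null(medium)) {
    ex <- network@exchangeIds
    lb[ex] <- pmax(lb[ex], 0)
    common <- intersect(names(medium), ex)
    lb[common] <- -abs(medium[common])
  }
  list(lb = lb, ub = ub)
}

.asNetworkObj <- function(x) {
  if (is(x, "ContextModel")) asNetwork(x) else x
}

#' Maximise growth of a network or context model (FBA)
#'
#' Solves max v_biomass subject to S v = 0 and flux bounds, with exchange
#' bounds set from `medium` when given.
#'
#' @param x a [MetabolicNetwork-class] or [ContextModel-class].
#' @param medium named uptake-limit vector (defaults to the context's own
#'   medium for a `ContextModel`, or the bounds as stored).
#' @return a [FluxState-class]; `objective` is the growth rate (0-length
#'   flux vector and status `"infeasible"` when the LP has no solution).
#' @export
optimizeGrowth <- function(x, medium = NULL) {
  if (is(x, "ContextModel") && is.null(medium) && length(x@medium)) medium <- x@medium
  net <- .asNetworkObj(x)
  if (!length(net@biomassId)) stop("network has no biomass reaction")
  bnd <- .effectiveBounds(net, medium)
  obj <- as.numeric(net@reactions$id == net@biomassId)
  res <- solveLP(obj, as.matrix(net@stoichiometry), numeric(nrow(net@metabolites)),
                 bnd$lb, bnd$ub, maximize = TRUE)
  if (res$status != "optimal")
    return(new("FluxState", fluxes = numeric(), objective = NA_real_, status = res$status))
  new("FluxState", fluxes = stats::setNames(res$x, net@reactions$id),
      objective = res$objval, status = "optimal")
}

# Maximal flux-consistent reaction subset: ids of reactions that can carry
# |v| >= tol in some steady-state solution of the (sub)network under the
# medium. One capped-activation LP certifies most forward-capable reactions
# at once; the remainder are settled with individual max/min LPs.
fluxConsistentSet <- function(network, medium = NULL, tol = 1e-6) {
  net <- .asNetworkObj(network)
  bnd0 <- .effectiveBounds(net, medium)

  # cheap sound pre-filter: a metabolite lacking any possible producer or
  # any possible consumer blocks all its reactions; iterate to fixpoint
  S0 <- net@stoichiometry
  alive <- rep(TRUE, ncol(S0))
  repeat {
    Sa <- S0[, alive, drop = FALSE]
    lb <- bnd0$lb[alive]; ub <- bnd0$ub[alive]
    prod <- (Sa > 0) %*% Matrix::Diagonal(x = as.numeric(ub > 0)) +
            (Sa < 0) %*% Matrix::Diagonal(x = as.numeric(lb < 0))
    cons <- (Sa < 0) %*% Matrix::Diagonal(x = as.numeric(ub > 0)) +
            (Sa > 0) %*% Matrix::Diagonal(x = as.numeric(lb < 0))
    bad <- (Matrix::rowSums(prod) == 0 | Matrix::rowSums(cons) == 0) &
      Matrix::rowSums(Sa != 0) > 0
    if (!any(bad)) break
    dead <- Matrix::colSums(abs(Sa[bad, , drop = FALSE])) > 0
    if (!any(dead)) break
    alive[alive] <- !dead
  }
  if (!any(alive)) return(character())
  keepIds <- net@reactions$id[alive]
  sub <- subnetwork(net, keepIds)
  bnd <- .effectiveBounds(sub, medium)
  S <- as.matrix(sub@stoichiometry)
  m <- nrow(S); n <- ncol(S)
  ids <- sub@reactions$id
  cap <- 1e-3
  consistent <- logical(n)

  # batch certification for irreversible reactions: maximise sum of capped
  # activations z_j (0 <= z_j <= cap, z_j <= v_j). The coupling v_j >= z_j
  # is only valid where v_j >= 0 is already a bound, so reversible
  # reactions are settled individually below.
  J <- which(bnd$lb >= 0)
  if (length(J)) {
    k <- length(J)
    D <- matrix(0, k, n); D[cbind(seq_len(k), J)] <- 1
    Aeq <- rbind(cbind(S, matrix(0, m, 2 * k)),
                 cbind(D, -diag(k), -diag(k)))        # v_J - z - s = 0
    beq <- numeric(m + k)
    big <- 2 * max(abs(c(bnd$lb, bnd$ub))) + cap
    lbv <- c(bnd$lb, numeric(k), numeric(k))
    ubv <- c(bnd$ub, rep(cap, k), rep(big, k))
    obj <- c(numeric(n), rep(1, k), numeric(k))
    res <- solveLP(obj, Aeq, beq, lbv, ubv, maximize = TRUE)
    if (!is.null(res$x) && res$status == "optimal")
      consistent[J] <- res$x[n + seq_len(k)] > tol
  }
  # settle reversibles and any uncertified irreversible individually
  for (j in which(!consistent)) {
    obj <- as.numeric(seq_len(n) == j)
    hi <- solveLP(obj, S, numeric(m), bnd$lb, bnd$ub, maximize = TRUE)
    if (hi$status != "optimal") return(character())   # no steady state at all
    if (hi$objval >= tol) { consistent[j] <- TRUE; next }
    if (bnd$lb[j] < 0) {
      lo <- solveLP(obj, S, numeric(m), bnd$lb, bnd$ub, maximize = FALSE)
      if (lo$status == "optimal" && lo$objval <= -tol) consistent[j] <- TRUE
    }
  }
  ids[consistent]
}

# Can the network reach biomass flux >= vMin on the medium?
.canGrow <- function(network, medium = NULL, vMin = 1e-3) {
  net <- .asNetworkObj(network)
  if (!length(net@biomassId)) return(FALSE)   # biomass reaction absent
  fs <- optimizeGrowth(net, medium)
  fs@status == "optimal" && fs@objective >= vMin - 1e-9
}
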