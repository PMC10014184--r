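# Model quality metrics in the spirit of community model-testing suites:
# stoichiometric consistency, elemental and charge balance, metabolite
# connectivity.

.parseFormula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(f)) return(NULL)
  out <- numeric(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- gsub("[^0-9]", "", t)
    out[el] <- (if (el %in% names(out)) out[el] else 0) + if (nzchar(n)) as.numeric(n) else 1
  }
  out
}

#' Quality metrics of a network or context model
#'
#' * `stoichiometric_consistency`: fraction of metabolites in the maximal
#'   subset admitting strictly positive molecular masses `m` with
#'   `S_int' m = 0` over the non-exchange reactions (LP test; a value of 1
#'   means no metabolite can be created from nothing).
#' * `mass_balanced_fraction` / `charge_balanced_fraction`: fraction of
#'   non-exchange reactions whose elemental composition / charge sums to
#'   zero, over the reactions whose participants are all annotated
#'   (missing annotation shrinks the denominator with a warning).
#' * `metabolite_connectivity`: fraction of metabolites participating in at
#'   least one reaction.
#'
#' @param x a [MetabolicNetwork-class] or [ContextModel-class].
#' @return list of the four fractions, each in `[0, 1]`.
#' @export
qcModel <- function(x) {
  net <- .asNetworkObj(x)
  S <- as.matrix(net@stoichiometry)
  met <- net@metabolites
  internal <- setdiff(colnames(S), net@exchangeIds)
  Si <- S[, internal, drop = FALSE]
  nm <- nrow(S)

  # stoichiometric consistency: max sum z, z_i <= m_i, z_i <= 1,
  # Si' m = 0, 0 <= m <= big; metabolites left at zero are re-tested
  # individually by maximising their own mass.
  big <- 1e3
  consistent <- logical(nm)
  if (ncol(Si)) {
    # z <= m encoded as m - z - s = 0 with surplus s >= 0
    k <- nm
    Aeq <- rbind(cbind(t(Si), matrix(0, ncol(Si), 2 * k)),
                 cbind(diag(k), -diag(k), -diag(k)))
    beq <- c(numeric(ncol(Si)), numeric(k))
    lb <- c(numeric(nm), numeric(k), numeric(k))
    ub <- c(rep(big, nm), rep(1, k), rep(2 * big, k))
    obj <- c(numeric(nm), rep(1, k), numeric(k))
    res <- solveLP(obj, Aeq, beq, lb, ub, maximize = TRUE)
    if (res$status == "optimal") consistent <- res$x[seq_len(nm)] > 1e-7
    for (i in which(!consistent)) {
      obj1 <- numeric(nm); obj1[i] <- 1
      r1 <- solveLP(obj1, t(Si), numeric(ncol(Si)), numeric(nm), rep(big, nm),
                    maximize = TRUE)
      if (r1$status == "optimal" && r1$objval > 1e-7) consistent[i] <- TRUE
    }
  } else consistent <- rep(TRUE, nm)

  comp <- lapply(met$formula, .parseFormula)
  annotated <- !vapply(comp, is.null, logical(1))
  els <- unique(unlist(lapply(comp[annotated], names)))
  C <- matrix(0, nm, length(els), dimnames = list(met$id, els))
  for (i in which(annotated)) C[i, names(comp[[i]])] <- comp[[i]]

  massOk <- chargeOk <- rep(NA, length(internal))
  for (jj in seq_along(internal)) {
    st <- Si[, jj]
    part <- which(st != 0)
    if (all(annotated[part]))
      massOk[jj] <- max(abs(as.vector(t(C[part, , drop = FALSE]) %*% st[part]))) < 1e-9
    chargeOk[jj] <- abs(sum(st[part] * met$charge[part])) < 1e-9
  }
  if (anyNA(massOk))
    warning(sum(is.na(massOk)), " reactions lack full formula annotation; ",
            "mass balance reported over the annotated subset")

  frac <- function(x) if (!length(stats::na.omit(x))) NA_real_ else mean(x, na.rm = TRUE)
  list(
    stoichiometric_consistency = mean(consistent),
    mass_balanced_fraction = frac(massOk),
    charge_balanced_fraction = frac(chargeOk),
    metabolite_connectivity = mean(rowSums(S != 0) > 0))
}

#' Per-group content statistics of context models
#'
#' Mean reaction and metabolite counts per group (metabolites are
#' compartment-qualified: the same species in different compartments counts
#' separately) and seven-region presence Venn counts over the per-group
#' union sets.
#'
#' @param models list of [ContextModel-class] objects with group labels.
#' @return list: `perModel` (sample, group, nReactions, nMetabolites),
#'   `meanCounts` (per-group means), `reactionVenn`, `metaboliteVenn`.
#' @export
modelStats <- function(models) {
  if (!length(models)) stop("no models supplied")
  groups <- vapply(models, function(m) m@group, character(1))
  nets <- lapply(models, asNetwork)
  perModel <- data.frame(
    sample = vapply(models, function(m) m@sampleId, character(1)),
    group = groups,
    nReactions = vapply(nets, function(n) nrow(n@reactions), integer(1)),
    nMetabolites = vapply(nets, function(n) nrow(n@metabolites), integer(1)),
    stringsAsFactors = FALSE)
  meanCounts <- do.call(rbind, lapply(split(perModel, perModel$group), function(d)
    data.frame(group = d$group[1], meanReactions = mean(d$nReactions),
               meanMetabolites = mean(d$nMetabolites))))
  rownames(meanCounts) <- NULL

  bySet <- function(what) {
    sets <- lapply(split(seq_along(models), groups), function(idx)
      unique(unlist(lapply(nets[idx], function(n)
        if (what == "rxn") n@reactions$id else n@metabolites$id))))
    presenceVenn(sets[unique(groups)])
  }
  out <- list(perModel = perModel, meanCounts = meanCounts)
  if (length(unique(groups)) == 3L) {
    out$reactionVenn <- bySet("rxn")
    out$metaboliteVenn <- bySet("met")
  }
  out
}
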