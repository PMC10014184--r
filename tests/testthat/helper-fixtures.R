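# Shared fixtures, cached across test files within a run.

.cache <- new.env(parent = emptyenv())

.memo <- function(key, compute) {
  if (!exists(key, envir = .cache, inherits = FALSE))
    assign(key, compute(), envir = .cache)
  get(key, envir = .cache, inherits = FALSE)
}

toyNet <- function() .memo("net", function() generateToyNetwork())

toySim <- function(seed = 1) .memo(paste0("sim", seed), function()
  simulateProteome(toyNet(), seed = seed))

# small hand-built network used for exhaustive oracles: two alternative
# routes from an uptaken substrate to an exported product (<= 12 reactions)
tinyNet <- function() .memo("tiny", function() {
  mets <- data.frame(
    id = c("a_e", "a_c", "b_c", "c_c", "c_e"),
    name = c("A", "A", "B", "C", "C"),
    compartment = c("e", "c", "c", "c", "e"),
    formula = c("C2", "C2", "C2", "C2", "C2"),
    charge = 0L, stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_a", "TA", "R1", "ALT", "R2", "TC", "EX_c"),
    name = c("A exchange", "A transport", "conversion", "alt conversion",
             "product formation", "C transport", "C exchange"),
    lower = c(-10, 0, 0, 0, 0, 0, 0),
    upper = c(10, 10, 10, 10, 10, 10, 10),
    gpr = c("", "", "g1", "g2", "g3", "", ""),
    subsystem = "", stringsAsFactors = FALSE)
  S <- Matrix::sparseMatrix(
    i = c(1,  1, 2,  2, 3,  2, 3,  3, 4,  4, 5,  5),
    j = c(1,  2, 2,  3, 3,  4, 4,  5, 5,  6, 6,  7),
    x = c(-1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1),
    dims = c(5, 7), dimnames = list(mets$id, rxns$id))
  new("MetabolicNetwork", metabolites = mets, reactions = rxns,
      stoichiometry = S, biomassId = "R2", exchangeIds = c("EX_a", "EX_c"))
})

# straight three-reaction chain (uptake -> conversion -> export)
chainNet <- function() .memo("chain", function() {
  mets <- data.frame(id = c("s_e", "s_c", "p_c", "p_e"),
                     name = c("S", "S", "P", "P"),
                     compartment = c("e", "c", "c", "e"),
                     formula = "C", charge = 0L, stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_s", "UPT", "CONV", "OUT", "EX_p"),
                     name = c("S exchange", "uptake", "conversion",
                              "export", "P exchange"),
                     lower = c(-10, 0, 0, 0, 0), upper = c(10, 10, 10, 10, 10),
                     gpr = c("", "", "gc", "", ""),
                     subsystem = "", stringsAsFactors = FALSE)
  S <- Matrix::sparseMatrix(
    i = c(1,  1, 2,  2, 3,  3, 4,  4),
    j = c(1,  2, 2,  3, 3,  4, 4,  5),
    x = c(-1, -1, 1, -1, 1, -1, 1, -1),
    dims = c(4, 5), dimnames = list(mets$id, rxns$id))
  new("MetabolicNetwork", metabolites = mets, reactions = rxns,
      stoichiometry = S, biomassId = "CONV", exchangeIds = c("EX_s", "EX_p"))
})

# end-to-end pipeline runs at the study design (3/9/6), shared between the
# restoration-recovery and model-content acceptance checks
endToEndRuns <- function(nSeeds = 20) .memo(paste0("e2e", nSeeds), function() {
  net <- toyNet()
  lapply(seq_len(nSeeds), function(seed) {
    sim <- simulateProteome(net, seed = seed)
    res <- runPipeline(net, sim$proteome, proteomeStats = FALSE)
    list(truth = sim$truth,
         recovery = restorationRecovery(res$comparison, sim$truth),
         meanCounts = res$modelStats$meanCounts,
         comparison = res$comparison)
  })
})

# a random vertex of the same flux polytope ladFit optimises over
.randomFeasiblePoint <- function(net, medium, seed) {
  set.seed(seed)
  bnd <- fluxrestore:::.effectiveBounds(net, medium)
  lb <- bnd$lb
  jb <- biomassReaction(net)
  lb[jb] <- max(lb[jb], 1e-3)
  S <- as.matrix(stoichiometry(net))
  r <- fluxrestore:::solveLP(stats::rnorm(ncol(S)), S, numeric(nrow(S)),
                             lb, bnd$ub, maximize = TRUE)
  stats::setNames(r$x, reactions(net)$id)
}

# independent Mann-Whitney enumeration oracle (no ties): distribution of U
# over all assignments of the pooled values to the x-positions
enumWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  idx <- utils::combn(n1 + n2, n1)
  r <- rank(pooled)
  Us <- apply(idx, 2L, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pLe <- mean(Us <= uObs); pGe <- mean(Us >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# independent one-way ANOVA via explicit sum-of-squares decomposition
ssAnova <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2)))
  dfb <- nlevels(g) - 1; dfw <- length(y) - nlevels(g)
  f <- (ssb / dfb) / (ssw / dfw)
  c(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# independent Tukey-Kramer p for one pairwise contrast
tkP <- function(y, g, g1, g2) {
  g <- factor(g)
  mse <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2))) /
    (length(y) - nlevels(g))
  m <- tapply(y, g, mean); n <- tapply(y, g, length)
  se <- sqrt(mse / 2 * (1 / n[[g1]] + 1 / n[[g2]]))
  q <- abs(m[[g1]] - m[[g2]]) / se
  stats::ptukey(q, nlevels(g), length(y) - nlevels(g), lower.tail = FALSE)
}

# Exhaustive-enumeration oracle for extraction: enumerates *all* reaction
# subsets of a small network and applies the same feasibility notion
# (every kept reaction can carry flux), independently of the package's
# search strategy.
.allSubsets <- function(ids) {
  n <- length(ids)
  lapply(seq_len(2^n) - 1L, function(mask) ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
}

.oracleBest <- function(net, w, requireGrowth = FALSE, vMin = 1e-3) {
  # without a growth requirement the empty model (score 0) is admissible
  best <- character(); bestScore <- if (requireGrowth) -Inf else 0
  for (sub in .allSubsets(reactions(net)$id)) {
    if (!length(sub)) next
    subNet <- subnetwork(net, sub)
    cons <- fluxConsistentSet(subNet)
    if (!setequal(cons, sub)) next                    # some member is blocked
    if (requireGrowth &&
        !(biomassReaction(net) %in% sub &&
            optimizeGrowth(subNet)@objective >= vMin - 1e-9)) next
    sc <- sum(w[sub])
    if (sc > bestScore + 1e-12) { best <- sub; bestScore <- sc }
  }
  list(set = best, score = bestScore)
}

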