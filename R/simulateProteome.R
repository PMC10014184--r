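# Synthetic three-group proteome with planted ground truth.
#
# Groups follow the control / disease / treated design (WT_VEH, AD_VEH,
# AD_NFP). Four response clusters are planted on a log2 scale:
#   cluster 1: elevated in disease, renormalised by treatment (all genes of
#              the toy fatty-acid branch live here, plus extras)
#   cluster 4: the mirrored decrease/restoration
#   clusters 2/3: disease-insensitive but shifted by the treatment
#              (possible side-effect pattern)
# plus a null background. Abundances are log-normal around the group mean
# with a fixed coefficient of variation.

#' Simulate a three-group proteome over a network's genes
#'
#' @param network [MetabolicNetwork-class] whose GPR genes seed the planted
#'   clusters: fatty-acid-branch genes go to cluster 1 (disease-elevated,
#'   treatment-restored), respiration/glycolysis genes to cluster 4
#'   (disease-suppressed, treatment-restored).
#' @param groupSizes named integer vector of replicate counts for
#'   `WT_VEH`, `AD_VEH`, `AD_NFP`; every group needs >= 2 samples.
#' @param effect planted effect size, log2 units; 0 plants nothing.
#' @param clusterSize number of extra (non-network) proteins per cluster.
#' @param nBackground number of null background proteins.
#' @param cv coefficient of variation of the log-normal abundance noise.
#' @param baselineMean,baselineSD log2 location/spread of per-protein
#'   baseline abundances.
#' @param clusterOffset log2 offset of cluster-1 (below) and cluster-4
#'   (above) baselines relative to the bulk, so that restored proteins sit
#'   on the informative side of the median expression used for reaction
#'   scoring.
#' @param seed integer seed; identical inputs give identical output.
#' @return list with `proteome` (a
#'   [SummarizedExperiment::SummarizedExperiment-class] with assay
#'   `abundance` and colData column `group`) and `truth` (list with
#'   `cluster_of_protein`, `active_reactions_by_group`,
#'   `restored_metabolites`).
#' @examples
#' net <- generateToyNetwork()
#' sim <- simulateProteome(net, seed = 1)
#' dim(sim$proteome)
#' @export
simulateProteome <- function(network,
                             groupSizes = c(WT_VEH = 3L, AD_VEH = 9L, AD_NFP = 6L),
                             effect = 3, clusterSize = 25L, nBackground = 400L,
                             cv = 0.2, baselineMean = 20, baselineSD = 1.5,
                             clusterOffset = 2, seed = 1L) {
  if (!all(c("WT_VEH", "AD_VEH", "AD_NFP") %in% names(groupSizes)))
    stop("groupSizes must name WT_VEH, AD_VEH and AD_NFP")
  groupSizes <- groupSizes[c("WT_VEH", "AD_VEH", "AD_NFP")]
  if (any(groupSizes < 2)) stop("invalid design: every group needs >= 2 samples")

  fb <- fattyAcidBranch(network)
  allGenes <- networkGenes(network)
  c4genes <- intersect(c("respA", "respB"), allGenes)
  otherGenes <- setdiff(allGenes, c(fb$genes, c4genes))

  extra <- function(tag, n) if (n > 0) sprintf("p%s_%02d", tag, seq_len(n)) else character()
  clusterProteins <- list(
    `1` = c(fb$genes, extra("c1", clusterSize)),
    `2` = extra("c2", clusterSize),
    `3` = extra("c3", clusterSize),
    `4` = c(c4genes, extra("c4", clusterSize))
  )
  background <- c(otherGenes,
                  if (nBackground > 0) sprintf("bg_%04d", seq_len(nBackground)))
  proteins <- c(unlist(clusterProteins, use.names = FALSE), background)

  groups <- rep(names(groupSizes), groupSizes)
  samples <- unlist(lapply(names(groupSizes), function(g)
    sprintf("%s_%d", g, seq_len(groupSizes[[g]]))))

  set.seed(as.integer(seed))
  mu0 <- stats::rnorm(length(proteins), baselineMean, baselineSD)
  names(mu0) <- proteins

  # per-protein, per-group mean shifts in log2 units
  shift <- matrix(0, length(proteins), 3,
                  dimnames = list(proteins, names(groupSizes)))
  if (effect != 0) {
    c1 <- clusterProteins[["1"]]; c2 <- clusterProteins[["2"]]
    c3 <- clusterProteins[["3"]]; c4 <- clusterProteins[["4"]]
    shift[c1, ] <- rep(c(-clusterOffset, -clusterOffset + effect, -clusterOffset),
                       each = length(c1))
    shift[c4, ] <- rep(c(clusterOffset, clusterOffset - effect, clusterOffset),
                       each = length(c4))
    if (length(c2)) shift[c2, "AD_NFP"] <- effect
    if (length(c3)) shift[c3, "AD_NFP"] <- -effect
  }

  sdlog <- sqrt(log(1 + cv^2))
  mean2 <- mu0 + shift[, groups, drop = FALSE]   # proteins x samples, log2
  ab <- 2^mean2 * exp(matrix(stats::rnorm(length(proteins) * length(samples),
                                          0, sdlog),
                             length(proteins), length(samples)))
  dimnames(ab) <- list(proteins, samples)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab),
    colData = S4Vectors::DataFrame(sample = samples,
                                   group = factor(groups, levels = names(groupSizes)),
                                   row.names = samples))

  clusterOf <- stats::setNames(rep("none", length(proteins)), proteins)
  if (effect != 0)
    for (k in names(clusterProteins)) clusterOf[clusterProteins[[k]]] <- k

  S <- network@stoichiometry
  branchOnly <- vapply(seq_len(nrow(S)), function(i) {
    touching <- colnames(S)[which(S[i, ] != 0)]
    length(touching) > 0 && all(touching %in% fb$reactions)
  }, logical(1))
  restored <- if (effect != 0) metabolites(network)$id[branchOnly] else character()

  allRxn <- reactions(network)$id
  core <- setdiff(allRxn, fb$reactions)
  suppressed <- allRxn[vapply(reactions(network)$gpr, function(g)
    length(gprGenes(g)) > 0 && all(gprGenes(g) %in% c4genes), logical(1))]
  truth <- list(
    cluster_of_protein = clusterOf,
    active_reactions_by_group = list(WT_VEH = core, AD_VEH = setdiff(allRxn, suppressed),
                                     AD_NFP = core),
    restored_metabolites = restored)

  list(proteome = se, truth = truth)
}

#' Per-sample gene expression vectors from a proteome
#'
#' @param proteome `SummarizedExperiment` as from [simulateProteome()] or
#'   [readProteomeTSV()].
#' @return named list, sample id -> named numeric vector of abundances.
#' @export
sampleExpression <- function(proteome) {
  ab <- SummarizedExperiment::assay(proteome, "abundance")
  stats::setNames(lapply(seq_len(ncol(ab)), function(j)
    stats::setNames(ab[, j], rownames(ab))), colnames(ab))
}
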