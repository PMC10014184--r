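# Differential-proteome statistics: row Z-scores, three-group one-way ANOVA
# with BH-FDR, hierarchical clustering of the significant proteins into four
# response clusters, Tukey-Kramer post-hoc selection of treatment-regulated
# proteins, and presence Venn counts.

#' Row Z-score normalisation
#'
#' Centres and scales every protein row to mean 0, population standard
#' deviation 1 (divisor n, the usual heatmap convention). Constant rows
#' cannot be scaled; they are mapped to all-zero and flagged.
#'
#' @param proteome `SummarizedExperiment` with assay `abundance`, or a
#'   plain numeric matrix.
#' @return same shape as the input: for a `SummarizedExperiment`, a copy
#'   gaining assay `zscore` and rowData column `constantRow`; for a matrix,
#'   the Z-scored matrix with attribute `constantRow`.
#' @export
zscoreNormalize <- function(proteome) {
  mat <- if (is.matrix(proteome)) proteome
         else SummarizedExperiment::assay(proteome, "abundance")
  if (!length(mat)) stop("empty abundance matrix")
  mu <- rowMeans(mat)
  sdp <- sqrt(rowMeans((mat - mu)^2))          # population SD
  constant <- sdp == 0
  z <- (mat - mu) / ifelse(constant, 1, sdp)
  z[constant, ] <- 0
  if (is.matrix(proteome)) {
    attr(z, "constantRow") <- constant
    return(z)
  }
  out <- proteome
  SummarizedExperiment::assays(out)$zscore <- z
  SummarizedExperiment::rowData(out)$constantRow <- constant
  out
}

.permutations4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (d in setdiff(1:4, c(a, b)))
    out[[length(out) + 1L]] <- c(a, b, d, setdiff(1:4, c(a, b, d)))
  out
}

.designGroups <- function(proteome) {
  g <- SummarizedExperiment::colData(proteome)$group
  if (is.null(g)) stop("colData must contain a 'group' column")
  droplevels(as.factor(g))
}

#' Per-protein one-way ANOVA with BH-FDR
#'
#' Fixed-effects one-way ANOVA (equal-variance F test) per protein across
#' the design groups, Benjamini-Hochberg step-up adjustment over all tested
#' proteins, and significance at adjusted p < `alpha`.
#'
#' @param proteome `SummarizedExperiment` with assay `abundance` and
#'   colData `group`.
#' @param alpha FDR level (default 0.05).
#' @param log2transform analyse log2 abundances (recommended for intensity
#'   data; the F test assumptions hold far better on the log scale).
#' @return data.frame: `protein`, `F`, `p`, `q`, `significant`.
#' @export
anovaBH <- function(proteome, alpha = 0.05, log2transform = TRUE) {
  grp <- .designGroups(proteome)
  if (nlevels(grp) < 2) stop("invalid design: need >= 2 groups")
  if (any(table(grp) < 2)) stop("invalid design: every group needs >= 2 samples")
  mat <- SummarizedExperiment::assay(proteome, "abundance")
  if (log2transform) mat <- log2(mat)
  res <- t(apply(mat, 1L, function(y) {
    ft <- stats::oneway.test(y ~ grp, var.equal = TRUE)
    c(ft$statistic, ft$p.value)
  }))
  q <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(protein = rownames(mat), F = unname(res[, 1]), p = unname(res[, 2]),
             q = unname(q), significant = unname(q < alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster differentially expressed proteins
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward's
#' minimum-variance linkage) of Z-scored rows of the significant proteins, cut at `k`
#' clusters. For `k = 4` the clusters are relabelled into the conventional
#' semantics -- 1 = elevated in disease (restored under treatment), 4 =
#' suppressed in disease, 2/3 = disease-insensitive but shifted by
#' treatment (2 up, 3 down) -- by matching cluster centroids to the four
#' archetype group-mean patterns (best label permutation by cosine
#' similarity).
#'
#' @param proteome `SummarizedExperiment` with assay `abundance` and
#'   colData `group`.
#' @param dep result of [anovaBH()]; rows with `significant == TRUE` are
#'   clustered.
#' @param k number of clusters (default 4).
#' @return list: `assignment` (named integer vector over significant
#'   proteins), `heatmap` (Z-score matrix in dendrogram order), `tree`
#'   (the `hclust` object), `centroids` (cluster x group mean Z-scores).
#' @export
clusterDEPs <- function(proteome, dep, k = 4L) {
  sig <- dep$protein[dep$significant]
  if (length(sig) < k)
    stop("degenerate clustering: fewer significant proteins (", length(sig),
         ") than clusters (", k, ")")
  z <- zscoreNormalize(log2(SummarizedExperiment::assay(proteome, "abundance")))
  z <- z[sig, , drop = FALSE]
  tree <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)

  grp <- .designGroups(proteome)
  centroids <- t(vapply(seq_len(k), function(cl) {
    rows <- z[raw == cl, , drop = FALSE]
    tapply(colMeans(rows), grp, mean)[levels(grp)]
  }, numeric(nlevels(grp))))
  colnames(centroids) <- levels(grp)

  relabel <- seq_len(k)
  if (k == 4L && all(c("WT_VEH", "AD_VEH", "AD_NFP") %in% colnames(centroids))) {
    # archetype group-mean patterns of the four response clusters
    # (1: disease-up restored, 2/3: treatment-shifted only, 4: mirror of 1),
    # centred by the group-size-weighted mean; label assignment maximises
    # total cosine similarity over all permutations, which is robust to
    # small noisy clusters.
    ord <- c("WT_VEH", "AD_VEH", "AD_NFP")
    wts <- table(grp)[ord]
    arch <- rbind(`1` = c(0, 1, 0), `2` = c(0, 0, 1),
                  `3` = c(0, 0, -1), `4` = c(1, 0, 1))
    norm1 <- function(v) {
      v <- v - sum(v * wts) / sum(wts)
      n <- sqrt(sum(v^2)); if (n > 0) v / n else v
    }
    A <- t(apply(arch, 1L, norm1))
    Cm <- t(apply(centroids[, ord, drop = FALSE], 1L, norm1))
    sim <- Cm %*% t(A)                       # cluster x archetype
    perms <- .permutations4()
    tot <- vapply(perms, function(p) sum(sim[cbind(seq_len(4L), p)]), numeric(1))
    relabel <- perms[[which.max(tot)]]
  }
  assignment <- stats::setNames(relabel[raw], sig)
  rownames(centroids) <- relabel
  list(assignment = assignment,
       heatmap = z[tree$order, , drop = FALSE],
       tree = tree,
       centroids = centroids[order(relabel), , drop = FALSE])
}

#' Tukey-Kramer selection of treatment-regulated proteins
#'
#' For each protein (by default: each ANOVA-significant protein), runs
#' Tukey's honestly-significant-difference test over the three groups
#' (Tukey-Kramer correction under unequal group sizes) and selects proteins
#' whose treated-vs-disease contrast (`AD_NFP` vs `AD_VEH`) is significant
#' at `alpha` (strict inequality), split by the sign of the difference.
#'
#' @param proteome `SummarizedExperiment` (three groups required).
#' @param alpha significance level for the Tukey contrast.
#' @param dep optional [anovaBH()] result; when supplied, only significant
#'   proteins are tested (the conventional ANOVA-then-post-hoc chain).
#' @param log2transform analyse log2 abundances.
#' @return list: `upregulated`, `downregulated` (disjoint protein id
#'   vectors, treated relative to disease), `table` (per-protein contrast
#'   estimate and adjusted p).
#' @export
tukeySelect <- function(proteome, alpha = 0.05, dep = NULL, log2transform = TRUE) {
  grp <- .designGroups(proteome)
  if (nlevels(grp) != 3L)
    stop("unsupported design: Tukey selection expects exactly 3 groups")
  if (any(table(grp) < 2)) stop("invalid design: every group needs >= 2 samples")
  mat <- SummarizedExperiment::assay(proteome, "abundance")
  if (log2transform) mat <- log2(mat)
  if (!is.null(dep)) mat <- mat[dep$protein[dep$significant], , drop = FALSE]

  res <- lapply(rownames(mat), function(pr) {
    y <- mat[pr, ]
    hsd <- stats::TukeyHSD(stats::aov(y ~ grp))$grp
    key <- intersect(c("AD_NFP-AD_VEH", "AD_VEH-AD_NFP"), rownames(hsd))[1]
    est <- hsd[key, "diff"] * (if (key == "AD_NFP-AD_VEH") 1 else -1)
    c(diff = unname(est), p = unname(hsd[key, "p adj"]))
  })
  tab <- data.frame(protein = rownames(mat), do.call(rbind, res),
                    row.names = NULL, stringsAsFactors = FALSE)
  sel <- tab$p < alpha
  list(upregulated = tab$protein[sel & tab$diff > 0],
       downregulated = tab$protein[sel & tab$diff < 0],
       table = tab)
}

#' Three-set presence Venn counts
#'
#' Counts the seven intersection regions of three sets.
#'
#' @param sets named list of three character vectors.
#' @return named integer vector over the regions, names like `"A"`,
#'   `"A&B"`, `"A&B&C"` built from the set names; the counts sum to the
#'   size of the union.
#' @export
presenceVenn <- function(sets) {
  if (length(sets) != 3L) stop("presenceVenn expects exactly three sets")
  if (is.null(names(sets))) names(sets) <- c("A", "B", "C")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  regions <- unlist(lapply(seq_len(3L), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}
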