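# Three-group comparison of reaction fluxes and metabolite flux-sums, and
# the restoration classification: entities whose value rises in disease
# relative to control and falls back under treatment (or the mirror
# pattern), with significance from two Wilcoxon rank-sum tests.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U with midrank ties. The p-value is exact (by
#' enumeration of arrangements) when both samples are small and there are
#' no ties, and uses the normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param x,y numeric replicate vectors (each >= 2 values).
#' @return list: `U` (the Mann-Whitney U statistic of `x`), `p`
#'   (two-sided), `exact` (logical).
#' @export
wilcoxonRankSum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("invalid sample: need >= 2 values per group")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 10
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Restoration classification of one entity
#'
#' Compares a control group (`wt`), a disease group (`ad`) and a treated
#' disease group (`nfp`). With group medians m: the pattern
#' `m_ad > m_wt` and `m_nfp < m_ad` is a *decreased* flux-sum (elevated in
#' disease, lowered again by treatment); when additionally both rank-sum
#' tests (disease vs control, treated vs disease) reject at `alpha`, it is
#' *significantly decreased*. The mirror pattern gives (significantly)
#' *increased*; anything else is *unchanged*.
#'
#' @param wt,ad,nfp numeric replicate values per group.
#' @param alpha per-test significance level.
#' @return list: `label` in `unchanged`, `decreased_flux_sum`,
#'   `significantly_decreased_flux_sum`, `increased_flux_sum`,
#'   `significantly_increased_flux_sum`; `p_ad_vs_wt`, `p_nfp_vs_ad`;
#'   group medians.
#' @export
classifyRestoration <- function(wt, ad, nfp, alpha = 0.05) {
  mWT <- stats::median(wt); mAD <- stats::median(ad); mNFP <- stats::median(nfp)
  p1 <- wilcoxonRankSum(ad, wt)$p
  p2 <- wilcoxonRankSum(nfp, ad)$p
  label <- "unchanged"
  if (mAD > mWT && mNFP < mAD) {
    label <- if (p1 < alpha && p2 < alpha)
      "significantly_decreased_flux_sum" else "decreased_flux_sum"
  } else if (mAD < mWT && mNFP > mAD) {
    label <- if (p1 < alpha && p2 < alpha)
      "significantly_increased_flux_sum" else "increased_flux_sum"
  }
  list(label = label, p_ad_vs_wt = p1, p_nfp_vs_ad = p2,
       medians = c(WT_VEH = mWT, AD_VEH = mAD, AD_NFP = mNFP))
}

#' Compare fluxes and flux-sums across the three groups
#'
#' Builds one comparison record per reaction (net flux) and per
#' compartment-qualified metabolite (flux-sum) across all samples. An
#' entity absent from a sample's context model contributes 0 (no capacity)
#' and is flagged. Records are sorted by the absolute disease-vs-treated
#' median difference, descending, so the strongest treatment responses
#' come first.
#'
#' @param fluxStates named list, sample -> [FluxState-class].
#' @param fluxSums named list, sample -> named flux-sum vector.
#' @param design data.frame with columns `sample`, `group` (levels
#'   `WT_VEH`, `AD_VEH`, `AD_NFP`).
#' @param alpha per-test significance level.
#' @return data.frame: `entity`, `kind` (`"flux"`/`"flux_sum"`), group
#'   medians, `p_ad_vs_wt`, `p_nfp_vs_ad`, `label`, `imputed` (TRUE when
#'   the entity was missing from at least one model).
#' @export
compareAll <- function(fluxStates, fluxSums, design, alpha = 0.05) {
  req <- c("WT_VEH", "AD_VEH", "AD_NFP")
  if (!all(design$group %in% req) || !all(req %in% design$group))
    stop("design must contain exactly the groups ", paste(req, collapse = ", "))
  if (!all(design$sample %in% names(fluxStates)) ||
      !all(design$sample %in% names(fluxSums)))
    stop("alignment error: every design sample needs a flux state and flux-sum profile")

  samples <- design$sample
  groupOf <- stats::setNames(as.character(design$group), samples)

  gather <- function(valuesList, kind) {
    entities <- sort(unique(unlist(lapply(valuesList, names))))
    mat <- matrix(0, length(entities), length(samples),
                  dimnames = list(entities, samples))
    miss <- matrix(FALSE, length(entities), length(samples),
                   dimnames = list(entities, samples))
    for (s in samples) {
      v <- valuesList[[s]]
      hit <- intersect(entities, names(v))
      mat[hit, s] <- v[hit]
      miss[setdiff(entities, names(v)), s] <- TRUE
    }
    do.call(rbind, lapply(entities, function(en) {
      vals <- split(mat[en, ], groupOf[samples])
      cl <- classifyRestoration(vals$WT_VEH, vals$AD_VEH, vals$AD_NFP, alpha)
      data.frame(entity = en, kind = kind,
                 median_wt = cl$medians[["WT_VEH"]],
                 median_ad = cl$medians[["AD_VEH"]],
                 median_nfp = cl$medians[["AD_NFP"]],
                 p_ad_vs_wt = cl$p_ad_vs_wt, p_nfp_vs_ad = cl$p_nfp_vs_ad,
                 label = cl$label, imputed = any(miss[en, ]),
                 stringsAsFactors = FALSE)
    }))
  }

  fluxVals <- lapply(fluxStates, function(fs) fs@fluxes)
  tab <- rbind(gather(fluxVals, "flux"), gather(fluxSums, "flux_sum"))
  tab <- tab[order(-abs(tab$median_ad - tab$median_nfp)), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Two-dimensional embedding of samples
#'
#' UMAP projection of a samples x features matrix, for proteome abundance
#' profiles (`nNeighbors = 5` is the conventional default here) or binary
#' reaction-presence profiles of context models (`nNeighbors = 11`).
#' Deterministic for a fixed seed.
#'
#' @param mat numeric matrix, samples in rows.
#' @param nNeighbors neighbourhood size; must be < number of samples.
#' @param seed integer seed.
#' @param ... passed to [uwot::umap()].
#' @return samples x 2 coordinate matrix.
#' @export
embedSamples <- function(mat, nNeighbors = 5, seed = 1L, ...) {
  if (nNeighbors >= nrow(mat))
    stop("invalid parameter: nNeighbors must be smaller than the sample count")
  set.seed(as.integer(seed))
  coords <- uwot::umap(as.matrix(mat), n_neighbors = nNeighbors,
                       n_threads = 1, n_sgd_threads = 0, ...)
  rownames(coords) <- rownames(mat)
  colnames(coords) <- c("dim1", "dim2")
  coords
}
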