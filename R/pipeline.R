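# End-to-end analysis: proteome statistics, per-sample context models,
# LAD flux fitting, flux-sum profiling and the three-group restoration
# comparison.

#' Run the full proteome-to-flux pipeline
#'
#' For every sample: score reactions from its expression profile, extract a
#' context-specific model, gap-fill it to guarantee growth on the medium,
#' fit fluxes by least absolute deviation against expression-derived
#' targets and compute flux-sums. Then compare reactions and metabolites
#' across the three groups and classify restoration. Proteome-level
#' statistics (ANOVA + BH, clustering, Tukey selection) are computed
#' alongside.
#'
#' @param network generic [MetabolicNetwork-class].
#' @param proteome `SummarizedExperiment` with assay `abundance` and
#'   colData `group` (levels `WT_VEH`, `AD_VEH`, `AD_NFP`).
#' @param medium named uptake vector (default [defaultMedium()] of the
#'   network).
#' @param alpha significance level used throughout.
#' @param vMin growth requirement for gap-filling and flux fitting.
#' @param k number of proteome clusters.
#' @param extractionMethod passed to [extractContext()].
#' @param proteomeStats compute the proteome statistics block (set FALSE to
#'   skip when only the flux side is needed).
#' @return list: `models`, `fluxStates`, `fluxSums`, `comparison`,
#'   `modelStats`, and (unless disabled) `dep`, `clusters`, `regulated`.
#' @export
runPipeline <- function(network, proteome, medium = defaultMedium(network),
                        alpha = 0.05, vMin = 1e-3, k = 4L,
                        extractionMethod = "greedy", proteomeStats = TRUE) {
  cd <- SummarizedExperiment::colData(proteome)
  design <- data.frame(sample = rownames(cd), group = as.character(cd$group),
                       stringsAsFactors = FALSE)
  expr <- sampleExpression(proteome)
  cache <- new.env(parent = emptyenv())

  models <- list(); fluxStates <- list(); fluxSums <- list(); scoresBySample <- list()
  for (s in design$sample) {
    sc <- scoreReactions(network, expr[[s]])
    ctx <- extractContext(network, sc, medium = medium,
                          requiredTasks = list(biomass = vMin),
                          method = extractionMethod,
                          sampleId = s, group = design$group[design$sample == s],
                          cacheEnv = cache)
    ctx <- gapfillGrowth(ctx, medium = medium, vMin = vMin, cacheEnv = cache)
    tgt <- expressionTargets(ctx, sc)
    fs <- ladFit(ctx, tgt, medium = medium, vMin = vMin)
    models[[s]] <- ctx
    scoresBySample[[s]] <- sc
    fluxStates[[s]] <- fs
    fluxSums[[s]] <- fluxSum(ctx, fs)
  }

  out <- list(models = models, fluxStates = fluxStates, fluxSums = fluxSums,
              scores = scoresBySample,
              comparison = compareAll(fluxStates, fluxSums, design, alpha = alpha),
              modelStats = modelStats(models), design = design)

  if (proteomeStats) {
    dep <- anovaBH(proteome, alpha = alpha)
    out$dep <- dep
    out$clusters <- tryCatch(clusterDEPs(proteome, dep, k = k), error = function(e) NULL)
    out$regulated <- tukeySelect(proteome, alpha = alpha, dep = dep)
  }
  out
}

#' Recovery of planted restored metabolites
#'
#' Given a pipeline comparison table and the simulator's planted truth,
#' computes which fraction of the planted disease-elevated,
#' treatment-normalised metabolites received the significantly-decreased
#' flux-sum label, and the false-discovery fraction among all metabolites
#' so labelled.
#'
#' @param comparison comparison table from [compareAll()]/[runPipeline()].
#' @param truth truth list from [simulateProteome()].
#' @return list: `recall`, `falseDiscovery`, `called` (labelled ids).
#' @export
restorationRecovery <- function(comparison, truth) {
  fsum <- comparison[comparison$kind == "flux_sum", ]
  called <- fsum$entity[fsum$label == "significantly_decreased_flux_sum"]
  planted <- truth$restored_metabolites
  list(recall = if (length(planted)) mean(planted %in% called) else NA_real_,
       falseDiscovery = if (length(called)) mean(!(called %in% planted)) else 0,
       called = called)
}
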