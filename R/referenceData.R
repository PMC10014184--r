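#' Mouse carnitine-shuttle / beta-oxidation gene-reaction associations
#'
#' The nine gene-reaction association rules of the mitochondrial carnitine
#' shuttle and beta-oxidation pathway in mouse (generic-model reaction ids
#' with their isozyme `or`-rules and complex `and`-rules), shipped as a
#' plain-text table. The toy network's synthetic GPR patterns are modelled
#' on these rules, and `carnitinePathwayGenes()` tallies the distinct gene
#' symbols they reference.
#'
#' @return `carnitinePathwayTable()`: data.frame with columns `reaction`,
#'   `pathway`, `gpr`. `carnitinePathwayGenes()`: character vector of the
#'   unique gene symbols across all nine rules.
#' @export
carnitinePathwayTable <- function() {
  path <- system.file("extdata", "carnitine_pathway_gpr.tsv",
                      package = "fluxrestore", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname carnitinePathwayTable
#' @export
carnitinePathwayGenes <- function() {
  tab <- carnitinePathwayTable()
  unique(unlist(lapply(tab$gpr, gprGenes)))
}
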