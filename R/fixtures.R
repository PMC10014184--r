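# Plain-text fixture plumbing: proteome/design TSV, truth JSON, and the
# bundled write-everything/read-everything pair used by tests and examples.

#' Write / read a proteome matrix as TSV
#'
#' The TSV has a first column `protein` followed by one column per sample;
#' the companion design table maps `sample` to `group`.
#'
#' @param proteome `SummarizedExperiment` with assay `abundance` and
#'   colData column `group`.
#' @param path matrix TSV path.
#' @param designPath design TSV path (written/read alongside).
#' @return `writeProteomeTSV`: paths invisibly; `readProteomeTSV`: the
#'   `SummarizedExperiment`.
#' @export
writeProteomeTSV <- function(proteome, path, designPath) {
  ab <- SummarizedExperiment::assay(proteome, "abundance")
  # %.17g survives the decimal round-trip bit-exactly
  txt <- matrix(sprintf("%.17g", ab), nrow(ab), dimnames = dimnames(ab))
  df <- data.frame(protein = rownames(ab), txt, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(proteome)
  utils::write.table(
    data.frame(sample = rownames(cd), group = as.character(cd$group)),
    designPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, designPath))
}

#' @rdname writeProteomeTSV
#' @export
readProteomeTSV <- function(path, designPath) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  ab <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(ab) <- "double"
  rownames(ab) <- df$protein
  design <- utils::read.table(designPath, sep = "\t", header = TRUE,
                              colClasses = "character")
  ab <- ab[, design$sample, drop = FALSE]
  lev <- intersect(c("WT_VEH", "AD_VEH", "AD_NFP"), unique(design$group))
  if (!length(lev)) lev <- unique(design$group)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab),
    colData = S4Vectors::DataFrame(sample = design$sample,
                                   group = factor(design$group, levels = lev),
                                   row.names = design$sample))
}

#' Write a complete fixture set
#'
#' Serialises a network (SBML), proteome + design (TSV) and planted truth
#' (JSON) into a directory; [readFixtures()] round-trips them.
#'
#' @param network a [MetabolicNetwork-class].
#' @param proteome `SummarizedExperiment` (see [simulateProteome()]).
#' @param truth truth list (see [simulateProteome()]).
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeFixtures <- function(network, proteome, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSBML(network, file.path(dir, "network.xml"))
  writeProteomeTSV(proteome, file.path(dir, "proteome.tsv"),
                   file.path(dir, "design.tsv"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname writeFixtures
#' @export
readFixtures <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(network = readSBML(file.path(dir, "network.xml")),
       proteome = readProteomeTSV(file.path(dir, "proteome.tsv"),
                                  file.path(dir, "design.tsv")),
       truth = truth)
}
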