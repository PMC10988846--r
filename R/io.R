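# Plain-text I/O matching the study input schemas: rule files, pathway maps,
# and the TSV matrices/tables consumed by the personalization module.

.writeTsv <- function(df, path, rowNames = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = rowNames,
              col.names = if (rowNames) NA else TRUE)
}

.readMatrixTsv <- function(path) {
  as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Produces exactly the files the personalization stage consumes:
#' `rules.bnet`, `pathway_map.tsv` (when pathway groups exist),
#' `mutations.tsv` (sample, gene, effect), `cnv_lrr.tsv` (gene x sample
#' log-ratios), `expression.tsv` (gene x sample raw expression) and
#' `metadata.tsv` (sample, group, tissue).
#'
#' @param cohort A `SyntheticCohort` from [simulateCohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeRules(cohort$network, file.path(dir, "rules.bnet"))
  if (length(pathwayGroups(cohort$network)))
    writePathwayMap(cohort$network, file.path(dir, "pathway_map.tsv"))
  .writeTsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  .writeTsv(as.data.frame(cohort$lrr), file.path(dir, "cnv_lrr.tsv"),
            rowNames = TRUE)
  .writeTsv(as.data.frame(cohort$expressionRaw),
            file.path(dir, "expression.tsv"), rowNames = TRUE)
  .writeTsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' Inverse of [writeCohort()]; the returned object feeds [cohortProfiles()]
#' unchanged.
#'
#' @param dir Directory containing the cohort TSV files.
#' @param cnv `"lrr"` if `cnv_lrr.tsv` holds log-ratios (discretized later),
#'   `"ploidy"` if it already holds categories in -2..2.
#' @return A list of class `SyntheticCohort`.
#' @export
readCohort <- function(dir, cnv = c("lrr", "ploidy")) {
  cnv <- match.arg(cnv)
  pmap <- file.path(dir, "pathway_map.tsv")
  network <- readRules(file.path(dir, "rules.bnet"),
                       pathwayFile = if (file.exists(pmap)) pmap else NULL)
  mutations <- read.delim(file.path(dir, "mutations.tsv"),
                          stringsAsFactors = FALSE)
  cn <- .readMatrixTsv(file.path(dir, "cnv_lrr.tsv"))
  expressionRaw <- .readMatrixTsv(file.path(dir, "expression.tsv"))
  metadata <- read.delim(file.path(dir, "metadata.tsv"),
                         stringsAsFactors = FALSE)
  out <- list(network = network, genes = rownames(expressionRaw),
              mutations = mutations, expressionRaw = expressionRaw,
              metadata = metadata)
  if (cnv == "lrr") out$lrr <- cn else out$ploidy <- cn
  structure(out, class = "SyntheticCohort")
}

#' Write methylation-integration inputs to TSV files
#'
#' Writes `beta.tsv` (probe x sample), `dmrs.tsv`, `probe_positions.tsv`,
#' `meth_expression.tsv` and `meth_metadata.tsv`.
#'
#' @param meth A `SyntheticMethylation` from [simulateMethylationCoupling()].
#' @param dir Output directory.
#' @return Invisibly, the directory path.
#' @export
writeMethylation <- function(meth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeTsv(as.data.frame(meth$beta), file.path(dir, "beta.tsv"),
            rowNames = TRUE)
  .writeTsv(meth$dmrs, file.path(dir, "dmrs.tsv"))
  .writeTsv(data.frame(probe = names(meth$positions),
                       pos = unname(meth$positions)),
            file.path(dir, "probe_positions.tsv"))
  .writeTsv(as.data.frame(meth$expression),
            file.path(dir, "meth_expression.tsv"), rowNames = TRUE)
  .writeTsv(meth$metadata, file.path(dir, "meth_metadata.tsv"))
  invisible(dir)
}

#' Read mutation, CNV, expression and metadata TSVs individually
#'
#' @param path File path.
#' @return `readMutations()` and `readMetadata()`: data.frames;
#'   `readOmicsMatrix()`: a numeric matrix with genes (or probes) as rows.
#' @name omics-io
#' @export
readMutations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "gene", "effect") %in% names(df)))
  df
}

#' @rdname omics-io
#' @export
readMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(df)))
  df
}

#' @rdname omics-io
#' @export
readOmicsMatrix <- function(path) .readMatrixTsv(path)
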