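# Methylation array summaries and methylation-expression correlation:
# beta/M-value conversion with intensity offset, representative-probe
# selection per DMR, and Spearman correlation stratified by tissue and group.
# Coordinates follow the 1-based inclusive array-annotation convention.

#' M-value from methylated/unmethylated intensities
#'
#' `M = log2((meth + a) / (unmeth + a))` with constant offset `a` (default
#' 100).
#'
#' @param meth,unmeth Non-negative intensity vectors.
#' @param a Positive offset.
#' @return Numeric vector of M-values.
#' @examples
#' mValue(300, 100)  # log2(400/200) = 1
#' @export
mValue <- function(meth, unmeth, a = 100) {
  if (any(meth < 0) || any(unmeth < 0)) stop("intensities must be >= 0")
  if (a <= 0) stop("'a' must be positive")
  log2((meth + a) / (unmeth + a))
}

#' Beta-value from methylated/unmethylated intensities
#'
#' `beta = meth / (meth + unmeth + a)` with constant offset `a` (default
#' 100); strictly below 1 for finite intensities since `a > 0`.
#'
#' @inheritParams mValue
#' @return Numeric vector of beta-values in \[0, 1).
#' @examples
#' betaValue(100, 100)  # 100/300
#' @export
betaValue <- function(meth, unmeth, a = 100) {
  if (any(meth < 0) || any(unmeth < 0)) stop("intensities must be >= 0")
  if (a <= 0) stop("'a' must be positive")
  meth / (meth + unmeth + a)
}

#' Representative probe of a DMR
#'
#' Among the member probes of a differentially methylated region, picks the
#' one with the largest probe-wise beta-value range across samples. Exact
#' ties resolve to the lowest genomic coordinate (or, lacking coordinates,
#' the first probe in member order), which makes the choice deterministic.
#'
#' @param probes Character vector of member probe ids (non-empty).
#' @param betaMatrix Probe x sample matrix of beta-values containing every
#'   member probe.
#' @param positions Optional named numeric vector of probe genomic
#'   coordinates (1-based) used for tie-breaking.
#' @return The representative probe id.
#' @export
selectRepresentativeProbe <- function(probes, betaMatrix, positions = NULL) {
  if (!length(probes)) stop("DMR has no member probes")
  missing <- setdiff(probes, rownames(betaMatrix))
  if (length(missing))
    stop("probe(s) missing from the beta matrix: ",
         paste(missing, collapse = ", "))
  b <- betaMatrix[probes, , drop = FALSE]
  rng <- apply(b, 1L, function(z) max(z) - min(z))
  best <- which(rng == max(rng))
  if (length(best) > 1L && !is.null(positions)) {
    pos <- positions[probes[best]]
    best <- best[order(pos)][1L]
  } else {
    best <- best[1L]
  }
  probes[best]
}

#' Correlate DMR methylation with gene expression, stratified
#'
#' Spearman correlation between a representative probe's per-sample
#' beta-values and matched normalized expression, computed overall and
#' within each (tissue, group) stratum. Strata with fewer than 3 paired
#' samples are skipped (reported via message). The p-value is exact for
#' n < 10 without ties and the t-approximation otherwise, as in
#' [stats::cor.test()].
#'
#' @param beta Named per-sample beta-values of the representative probe.
#' @param expression Named per-sample expression values (same sample ids).
#' @param strata data.frame with columns `sample`, `tissue`, `group`.
#' @param gene,dmr Identifiers copied into the output.
#' @return data.frame with one row per stratum (plus `overall`): `gene`,
#'   `dmr`, `tissue`, `group`, `rho`, `p_value`, `n`.
#' @export
correlateDmrExpression <- function(beta, expression, strata,
                                   gene = NA_character_,
                                   dmr = NA_character_) {
  common <- intersect(names(beta), names(expression))
  if (!length(common)) stop("no overlapping samples between beta and expression")
  strata <- strata[strata$sample %in% common, , drop = FALSE]
  combos <- unique(strata[, c("tissue", "group")])
  combos <- rbind(data.frame(tissue = "overall", group = "overall",
                             stringsAsFactors = FALSE), combos)
  parts <- lapply(seq_len(nrow(combos)), function(i) {
    ti <- combos$tissue[i]; gr <- combos$group[i]
    ids <- if (ti == "overall") common
           else strata$sample[strata$tissue == ti & strata$group == gr]
    ids <- intersect(ids, common)
    if (length(ids) < 3L) {
      message("stratum (", ti, ", ", gr, ") skipped: n = ", length(ids),
              " < 3")
      return(NULL)
    }
    ct <- suppressWarnings(
      cor.test(beta[ids], expression[ids], method = "spearman"))
    data.frame(gene = gene, dmr = dmr, tissue = ti, group = gr,
               rho = unname(ct$estimate), p_value = ct$p.value,
               n = length(ids), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    stop("no stratum reached the minimum of 3 paired samples")
  rownames(out) <- NULL
  out
}

#' Correlate every DMR in a table with its leading gene's expression
#'
#' Convenience wrapper: for each DMR row, selects the representative probe
#' and runs [correlateDmrExpression()] against the leading gene. Gene/DMR
#' pairs whose gene is absent from the expression matrix are skipped. Raw
#' p-values are reported alongside an optional BH adjustment across all
#' returned records.
#'
#' @param dmrs data.frame with columns `region_id`, `leading_gene`, `probes`
#'   (comma-separated probe ids, as written by the cohort generator).
#' @param betaMatrix Probe x sample beta matrix.
#' @param expressionMatrix Gene x sample normalized expression matrix.
#' @param strata data.frame (`sample`, `tissue`, `group`).
#' @param positions Optional probe coordinate vector for tie-breaks.
#' @param adjust Add a BH-adjusted column across records?
#' @return data.frame of correlation records (one per DMR x stratum).
#' @export
correlateAllDmrs <- function(dmrs, betaMatrix, expressionMatrix, strata,
                             positions = NULL, adjust = TRUE) {
  parts <- lapply(seq_len(nrow(dmrs)), function(i) {
    g <- dmrs$leading_gene[i]
    if (!g %in% rownames(expressionMatrix)) return(NULL)
    probes <- strsplit(dmrs$probes[i], ",", fixed = TRUE)[[1L]]
    rep <- selectRepresentativeProbe(probes, betaMatrix, positions)
    b <- betaMatrix[rep, ]
    e <- expressionMatrix[g, ]
    rec <- correlateDmrExpression(b, e, strata, gene = g,
                                  dmr = dmrs$region_id[i])
    rec$representative_probe <- rep
    rec
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) stop("no DMR could be matched to expression")
  if (adjust) out$adjusted_p <- bhAdjust(out$p_value)
  rownames(out) <- NULL
  out
}
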