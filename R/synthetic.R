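# Synthetic fixtures: the frozen toy AR network, random Boolean networks,
# two-group multi-omics cohorts with planted effects, and coupled
# methylation-expression data. Everything is deterministic given the seed;
# the generators match the structure and schemas of the study inputs, not
# empirical marginals of any real dataset.

# Run code under a given seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

.TOY_AR_RULES <- paste(
  "targets, factors",
  "Androgen, !Androgen",
  "GF, !GF",
  "AR, Androgen",
  "AR_ERG, AR & GF",
  "ZBTB17, AR",
  "TGFB, !AR",
  "SMAD, TGFB & !AR",
  "IDH1, !AR & GF",
  "CyclinD, (AR | GF) & !SMAD",
  "Proliferation, CyclinD",
  sep = "\n")

.TOY_AR_PATHWAYS <- c(
  Androgen = "Input", GF = "Input",
  AR = "AR", AR_ERG = "AR", ZBTB17 = "AR",
  TGFB = "TGF_beta", SMAD = "TGF_beta",
  IDH1 = "IDH1",
  CyclinD = "Cell_cycle", Proliferation = "Cell_cycle")

#' The frozen toy AR signaling network
#'
#' A hand-curated 10-node Boolean model of AR signaling used as the fixed
#' test fixture: two fluctuating input nodes (Androgen, GF; self-negating
#' two-state nodes whose stationary ON-probability equals their
#' expression-derived up-rate fraction, mimicking fluctuating ligand
#' availability), AR driven by
#' androgen, AR positively regulating the AR_ERG fusion node and ZBTB17, and
#' repressing the branches feeding SMAD (via TGFB) and IDH1, plus a small
#' cell-cycle arm (CyclinD, Proliferation) inhibited by SMAD. Knocking out
#' AR therefore lowers AR_ERG/ZBTB17 activity and raises SMAD/IDH1 activity.
#' The network (and its pathway map) is byte-stable across runs.
#'
#' @return A [BooleanNetwork-class] with pathway groups.
#' @examples
#' toyARNetwork()
#' @export
toyARNetwork <- function() {
  parseRules(.TOY_AR_RULES, pathways = .TOY_AR_PATHWAYS)
}

# Random non-constant truth table over k regulators that semantically
# depends on every one of them.
.randomDependentTT <- function(k) {
  repeat {
    tt <- sample(0:1, 2^k, replace = TRUE)
    if (all(tt == tt[1L])) next
    idx <- 0:(2^k - 1L)
    dep <- vapply(seq_len(k), function(j)
      any(tt[idx + 1L] != tt[bitwXor(idx, bitwShiftL(1L, j - 1L)) + 1L]),
      logical(1))
    if (all(dep)) return(tt)
  }
}

.ttToExpression <- function(regs, tt) {
  k <- length(regs)
  ones <- which(tt == 1L) - 1L
  terms <- vapply(ones, function(s) {
    bits <- bitwAnd(bitwShiftR(s, 0:(k - 1L)), 1L)
    lits <- ifelse(bits == 1L, regs, paste0("!", regs))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

#' Generate a random Boolean network
#'
#' Each node receives 1..`maxRegulators` distinct regulators (self-loops
#' allowed) and a random non-constant rule that semantically depends on every
#' listed regulator (no vacuous literals). Reproducible from `seed`.
#'
#' @param nNodes Number of nodes (>= 1).
#' @param maxRegulators Upper bound on regulators per node (1 <= k <=
#'   nNodes).
#' @param seed Integer seed.
#' @return A [BooleanNetwork-class].
#' @export
generateRandomNetwork <- function(nNodes, maxRegulators = 2L, seed = 1L) {
  if (nNodes < 1L) stop("'nNodes' must be >= 1")
  if (maxRegulators < 1L || maxRegulators > nNodes)
    stop("'maxRegulators' must lie in [1, nNodes]")
  .withSeed(seed, {
    nn <- paste0("N", seq_len(nNodes))
    rules <- lapply(nn, function(v) {
      k <- sample.int(maxRegulators, 1L)
      regs <- sample(nn, k)
      tt <- .randomDependentTT(k)
      logicRule(v, .ttToExpression(regs, tt))
    })
    booleanNetwork(rules)
  })
}

.CHANNELS <- c("mutation_rate", "cnv", "expression_shift",
               "methylation_coupling")

#' Specify a synthetic two-group cohort
#'
#' @param nPerGroup Samples per group (>= 3).
#' @param groupLabels Pair of group labels.
#' @param network The [BooleanNetwork-class] the cohort is generated for.
#' @param plantedEffects List of planted group-A effects, each a list with
#'   fields `target` (gene/node), `channel` (one of `mutation_rate`, `cnv`,
#'   `expression_shift`, `methylation_coupling`), `magnitude`, and (for
#'   mutations) optional `effect`.
#' @param noiseSd Log-scale expression noise SD.
#' @param extraGenes Extra gene symbols outside the network (exercising the
#'   ignored-gene path of personalization).
#' @param nonGeneNodes Network nodes without a measurable transcript,
#'   excluded from the omics gene universe: ligand/stimulus inputs (no
#'   mRNA of their own) and fusion nodes (no single gene symbol).
#' @param seed Integer seed.
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(nPerGroup = 10L, groupLabels = c("AA", "EA"),
                       network = toyARNetwork(), plantedEffects = list(),
                       noiseSd = 0.5,
                       extraGenes = c("GSTP1", "TP53", "PTEN"),
                       nonGeneNodes = c("AR_ERG", "Androgen", "GF"),
                       seed = 1L) {
  stopifnot(nPerGroup >= 3L, length(groupLabels) == 2L,
            is(network, "BooleanNetwork"), noiseSd >= 0)
  genes <- c(setdiff(nodes(network), nonGeneNodes), extraGenes)
  for (pe in plantedEffects) {
    stopifnot(is.list(pe), !is.null(pe$target), !is.null(pe$channel),
              !is.null(pe$magnitude))
    if (!pe$channel %in% .CHANNELS)
      stop("unknown effect channel '", pe$channel, "'")
    if (!is.finite(pe$magnitude)) stop("effect magnitudes must be finite")
    if (!pe$target %in% genes)
      stop("planted target '", pe$target, "' is not in the gene universe")
  }
  structure(list(nPerGroup = as.integer(nPerGroup),
                 groupLabels = as.character(groupLabels),
                 network = network, plantedEffects = plantedEffects,
                 noiseSd = noiseSd, genes = genes,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

.effectsOn <- function(spec, channel) {
  keep <- vapply(spec$plantedEffects, function(pe) pe$channel == channel,
                 logical(1))
  spec$plantedEffects[keep]
}

#' Simulate a two-group multi-omics cohort
#'
#' Per sample: mutations are per-gene Bernoulli draws (baseline rate 0.02,
#' reflecting the low per-gene somatic mutation frequency of primary
#' prostate tumors,
#' group-A rate replaced where a `mutation_rate` effect is planted, with the
#' planted functional effect, default inactivating); copy-number log-ratios
#' are Normal(shift, 0.3) with a group-A mean shift where a `cnv` effect is
#' planted; raw expression is log-normal around gene-level log-means drawn
#' once per cohort from Normal(3, 1), with a group-A log-scale shift where an
#' `expression_shift` effect is planted and noise SD `noiseSd`. Fully
#' reproducible from the spec seed; without planted effects the two groups
#' are exchangeable.
#'
#' @param spec A [cohortSpec()] object.
#' @return A list of class `SyntheticCohort`: `network`, `genes`,
#'   `mutations` (long data.frame: sample, gene, effect), `lrr` (gene x
#'   sample matrix), `expressionRaw` (gene x sample matrix), `metadata`
#'   (sample, group, tissue).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  .withSeed(spec$seed, {
    genes <- spec$genes
    nG <- length(genes)
    samples <- paste0(rep(spec$groupLabels, each = spec$nPerGroup), "_",
                      sprintf("%02d", seq_len(spec$nPerGroup)))
    groups <- rep(spec$groupLabels, each = spec$nPerGroup)
    nS <- length(samples)
    isA <- groups == spec$groupLabels[1L]

    # per-gene baseline mutation effect labels and rates
    effectOf <- setNames(sample(c("activating", "inactivating", "unknown"),
                                nG, replace = TRUE), genes)
    rate <- matrix(0.02, nG, nS, dimnames = list(genes, samples))
    for (pe in .effectsOn(spec, "mutation_rate")) {
      rate[pe$target, isA] <- pe$magnitude
      effectOf[pe$target] <- if (is.null(pe$effect)) "inactivating"
                             else pe$effect
    }
    hit <- matrix(rbinom(nG * nS, 1L, as.vector(rate)), nG, nS,
                  dimnames = list(genes, samples))
    idx <- which(hit == 1L, arr.ind = TRUE)
    mutations <- data.frame(sample = samples[idx[, 2L]],
                            gene = genes[idx[, 1L]],
                            effect = unname(effectOf[genes[idx[, 1L]]]),
                            stringsAsFactors = FALSE)
    mutations <- mutations[order(mutations$sample, mutations$gene), ,
                           drop = FALSE]
    rownames(mutations) <- NULL

    # copy-number log-ratios (FACETS-style lRR)
    mu <- matrix(0, nG, nS, dimnames = list(genes, samples))
    for (pe in .effectsOn(spec, "cnv")) mu[pe$target, isA] <- pe$magnitude
    lrr <- mu + matrix(rnorm(nG * nS, sd = 0.3), nG, nS)
    dimnames(lrr) <- list(genes, samples)

    # log-normal expression with optional planted group shift
    base <- rnorm(nG, mean = 3, sd = 1)
    shift <- matrix(0, nG, nS, dimnames = list(genes, samples))
    for (pe in .effectsOn(spec, "expression_shift"))
      shift[pe$target, isA] <- pe$magnitude
    logx <- base + shift + matrix(rnorm(nG * nS, sd = spec$noiseSd), nG, nS)
    expressionRaw <- exp(logx)
    dimnames(expressionRaw) <- list(genes, samples)

    metadata <- data.frame(sample = samples, group = groups,
                           tissue = "tumor", stringsAsFactors = FALSE)
    structure(list(network = spec$network, genes = genes,
                   mutations = mutations, lrr = lrr,
                   expressionRaw = expressionRaw, metadata = metadata),
              class = "SyntheticCohort")
  })
}

#' Patient profiles from a synthetic (or file-loaded) cohort
#'
#' Normalizes expression across the cohort, discretizes log-ratios to ploidy
#' and assembles one [PatientProfile-class] per sample. The cohort
#' normalization is the only cross-sample coupling: a sample's profile does
#' not depend on other samples' mutations or CNVs.
#'
#' @param cohort A `SyntheticCohort` (or a list with the same elements).
#' @param normalization Passed to [normalizeExpression()].
#' @return Named list of [PatientProfile-class] objects.
#' @export
cohortProfiles <- function(cohort, normalization = "minmax") {
  expr <- normalizeExpression(cohort$expressionRaw, method = normalization)
  if (!is.null(cohort$ploidy)) {
    ploidy <- cohort$ploidy
    storage.mode(ploidy) <- "integer"
  } else {
    ploidy <- apply(cohort$lrr, 2L, discretizeLrr)
    rownames(ploidy) <- rownames(cohort$lrr)
  }
  md <- cohort$metadata
  out <- lapply(seq_len(nrow(md)), function(i) {
    s <- md$sample[i]
    m <- cohort$mutations[cohort$mutations$sample == s,
                          c("gene", "effect"), drop = FALSE]
    rownames(m) <- NULL
    patientProfile(s, md$group[i], mutations = m,
                   ploidy = setNames(ploidy[, s], rownames(ploidy)),
                   expression = setNames(expr[, s], rownames(expr)))
  })
  names(out) <- md$sample
  out
}

#' Simulate coupled methylation and expression data
#'
#' Generates a probe x sample beta matrix, a DMR table (3-10 member probes
#' per gene, 1-based inclusive coordinates) and a matched expression matrix
#' over `2 groups x 2 tissues x nPerGroup` samples. For each planted
#' `methylation_coupling` effect, the representative probe's beta is a
#' monotone-decreasing noisy function of the gene's expression with target
#' Spearman |rho| equal to the magnitude (Gaussian copula, latent Pearson
#' correlation `2*sin(pi*rho/6)`), independently within each (tissue, group)
#' stratum; magnitude 1 is the noise-free strictly decreasing link and
#' magnitude 0 is independence. Uncoupled genes are independent of
#' expression. Beta values lie strictly inside (0, 1).
#'
#' @param spec A [cohortSpec()] with at least one `methylation_coupling`
#'   effect (its `nPerGroup` is the per-stratum sample count here).
#' @return A list of class `SyntheticMethylation`: `beta`, `dmrs`,
#'   `positions`, `expression`, `metadata`.
#' @export
simulateMethylationCoupling <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  eff <- .effectsOn(spec, "methylation_coupling")
  if (!length(eff))
    stop("spec contains no methylation_coupling effect")
  rho <- setNames(vapply(eff, `[[`, numeric(1), "magnitude"),
                  vapply(eff, `[[`, character(1), "target"))
  if (any(rho < 0 | rho > 1))
    stop("target |rho| must lie in [0, 1]")
  .withSeed(spec$seed + 1L, {
    genes <- spec$genes
    tissues <- c("tumor", "non_tumor")
    md <- expand.grid(rep = seq_len(spec$nPerGroup),
                      group = spec$groupLabels, tissue = tissues,
                      stringsAsFactors = FALSE)
    samples <- paste0(md$group, "_", substr(md$tissue, 1L, 1L), "_",
                      sprintf("%02d", md$rep))
    metadata <- data.frame(sample = samples, group = md$group,
                           tissue = md$tissue, stringsAsFactors = FALSE)
    nS <- length(samples)

    base <- rnorm(length(genes), 3, 1)
    expression <- exp(base + matrix(rnorm(length(genes) * nS,
                                          sd = max(spec$noiseSd, 0.1)),
                                    length(genes), nS))
    dimnames(expression) <- list(genes, samples)

    betaRows <- list(); posAll <- numeric(0); dmrRows <- list()
    probeCounter <- 0L
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      nP <- sample(3:10, 1L)
      probes <- paste0("cg", sprintf("%07d", probeCounter + seq_len(nP)))
      probeCounter <- probeCounter + nP
      chrom <- paste0("chr", 1L + (gi - 1L) %% 22L)
      start <- 1000000L + gi * 50000L
      pos <- start + sort(sample.int(4000L, nP))
      b <- matrix(NA_real_, nP, nS, dimnames = list(probes, samples))
      repIdx <- 1L  # by construction the widest-range probe comes first
      if (g %in% names(rho) && rho[g] > 0) {
        r <- 2 * sin(pi * rho[g] / 6)
        lat <- numeric(nS)
        for (ti in tissues) for (gr in spec$groupLabels) {
          ids <- which(metadata$tissue == ti & metadata$group == gr)
          z <- scale(log(expression[g, ids]))[, 1L]
          lat[ids] <- -(r * z + sqrt(1 - r^2) * rnorm(length(ids)))
        }
        b[repIdx, ] <- 0.05 + 0.9 * plogis(1.5 * lat)
        mid <- mean(b[repIdx, ])
        for (j in seq_len(nP)[-repIdx])
          b[j, ] <- pmin(pmax(mid + rnorm(nS, sd = 0.02), 0.01), 0.99)
      } else {
        for (j in seq_len(nP))
          b[j, ] <- plogis(rnorm(nS, mean = rnorm(1L, 0, 1), sd = 1))
      }
      probeDiff <- vapply(seq_len(nP), function(j) {
        mean(b[j, metadata$tissue == "tumor"]) -
          mean(b[j, metadata$tissue == "non_tumor"])
      }, numeric(1))
      betaRows[[gi]] <- b
      posAll <- c(posAll, setNames(pos, probes))
      dmrRows[[gi]] <- data.frame(
        region_id = paste0("DMR_", g), chrom = chrom,
        start = min(pos), end = max(pos),
        probes = paste(probes, collapse = ","),
        leading_gene = g,
        maxdiff = probeDiff[which.max(abs(probeDiff))],
        meandiff = mean(probeDiff),
        fisher_p = runif(1L, 1e-6, 0.04),
        stringsAsFactors = FALSE)
    }
    beta <- do.call(rbind, betaRows)
    dmrs <- do.call(rbind, dmrRows)
    rownames(dmrs) <- NULL
    structure(list(beta = beta, dmrs = dmrs, positions = posAll,
                   expression = expression, metadata = metadata),
              class = "SyntheticMethylation")
  })
}
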