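# Omics-driven model personalization: copy-number discretization, cohort
# expression normalization, discrete forcings from mutations/CNV, and the
# expression-to-rate transfer that yields a subject-specific model.

#' Discretize FACETS log-ratios to ploidy categories
#'
#' Total step function mapping a segment log copy-ratio (lRR) to the five
#' ploidy categories: -2 for lRR <= -1.1; -1 for -1.1 < lRR <= -0.2; 0 for
#' -0.2 < lRR <= 0.2; 1 for 0.2 < lRR <= 0.7; 2 for lRR > 0.7. Upper bounds
#' are inclusive except the open top class.
#'
#' @param lrr Numeric vector of finite log-ratios.
#' @return Integer vector of categories in -2..2.
#' @examples
#' discretizeLrr(c(-1.2, 0, 0.7, 0.8))
#' @export
discretizeLrr <- function(lrr) {
  if (any(!is.finite(lrr))) stop("lRR values must be finite")
  breaks <- c(-Inf, -1.1, -0.2, 0.2, 0.7, Inf)
  as.integer(cut(lrr, breaks = breaks, labels = -2:2, right = TRUE)) - 3L
}

#' Normalize an expression matrix to \[0, 1\] across the cohort
#'
#' Per-gene min-max scaling across samples (default) or rank-percentile
#' scaling. Genes constant across the cohort map to 0.5 by convention.
#'
#' @param raw Non-negative gene x sample matrix with at least 2 samples.
#' @param method `"minmax"` (default) or `"rank"` (percentile of the sample
#'   rank, midranks for ties).
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
normalizeExpression <- function(raw, method = c("minmax", "rank")) {
  method <- match.arg(method)
  raw <- as.matrix(raw)
  if (ncol(raw) < 2L)
    stop("cohort normalization needs at least 2 samples")
  if (any(raw < 0)) stop("expression values must be non-negative")
  out <- t(apply(raw, 1L, function(z) {
    if (max(z) == min(z)) return(rep(0.5, length(z)))
    if (method == "minmax") (z - min(z)) / (max(z) - min(z))
    else (rank(z) - 1) / (length(z) - 1)
  }))
  dimnames(out) <- dimnames(raw)
  out
}

#' Construct a patient profile
#'
#' @param sampleId Sample identifier.
#' @param group Group label (e.g. `"AA"` / `"EA"`).
#' @param mutations data.frame with columns `gene`, `effect`
#'   (`activating`/`inactivating`/`unknown`); may be empty.
#' @param ploidy Named integer vector of ploidy categories in -2..2.
#' @param expression Named numeric vector of cohort-normalized expression in
#'   \[0, 1\].
#' @return A [PatientProfile-class].
#' @export
patientProfile <- function(sampleId, group,
                           mutations = data.frame(gene = character(0),
                                                  effect = character(0)),
                           ploidy = integer(0), expression = numeric(0)) {
  pl <- as.integer(ploidy)
  names(pl) <- names(ploidy)
  p <- new("PatientProfile", sampleId = as.character(sampleId),
           group = as.character(group), mutations = mutations,
           ploidy = pl, expression = expression)
  validObject(p)
  p
}

# Map omics gene names onto network nodes through an optional alias table
# (data.frame omics_gene, network_node). Exact name match otherwise.
.mapGene <- function(genes, alias) {
  if (is.null(alias) || !nrow(alias)) return(genes)
  i <- match(genes, alias[[1L]])
  out <- genes
  out[!is.na(i)] <- alias[[2L]][i[!is.na(i)]]
  out
}

#' Derive hard node forcings from discrete omics
#'
#' An inactivating mutation or deep deletion (ploidy -2) forces a node to 0;
#' an activating mutation or high amplification (ploidy +2) forces it to 1.
#' Mutations of unknown effect and single-copy changes contribute nothing.
#' Under the default `"mutation_first"` policy, contradictory evidence (e.g.
#' activating mutation plus deep deletion) resolves in favor of the mutation
#' with a warning; under `"strict"` it is an error. Genes absent from the
#' network are ignored (reported via message).
#'
#' @param profile A [PatientProfile-class].
#' @param network A [BooleanNetwork-class].
#' @param policy `"mutation_first"` or `"strict"`.
#' @param alias Optional data.frame (omics_gene, network_node) applied before
#'   matching; fusion nodes such as AR_ERG have no single gene and are never
#'   forced from omics unless aliased explicitly.
#' @return Named integer vector of forced values (0/1), possibly empty.
#' @export
applyDiscreteForcings <- function(profile, network,
                                  policy = c("mutation_first", "strict"),
                                  alias = NULL) {
  policy <- match.arg(policy)
  nn <- nodes(network)
  mutF <- integer(0)
  m <- profile@mutations
  if (nrow(m)) {
    m$node <- .mapGene(as.character(m$gene), alias)
    known <- m[m$effect != "unknown", , drop = FALSE]
    off <- unique(known$node[!(known$node %in% nn)])
    if (length(off))
      message("mutated genes absent from the network ignored: ",
              paste(off, collapse = ", "))
    known <- known[known$node %in% nn, , drop = FALSE]
    if (nrow(known)) {
      val <- ifelse(known$effect == "activating", 1L, 0L)
      conflict <- tapply(val, known$node, function(v) length(unique(v)) > 1L)
      if (any(conflict)) {
        bad <- names(conflict)[conflict]
        if (policy == "strict")
          stop("conflicting mutation effects for: ",
               paste(bad, collapse = ", "))
        warning("conflicting mutation effects for ",
                paste(bad, collapse = ", "),
                "; keeping the first call per gene")
        known <- known[!duplicated(known$node), , drop = FALSE]
        val <- ifelse(known$effect == "activating", 1L, 0L)
      }
      mutF <- tapply(val, known$node, `[`, 1L)
      mutF <- setNames(as.integer(mutF), names(mutF))
    }
  }
  cnvF <- integer(0)
  pl <- profile@ploidy
  if (length(pl)) {
    names(pl) <- .mapGene(names(pl), alias)
    extreme <- pl[abs(pl) == 2L]
    off <- setdiff(names(extreme), nn)
    if (length(off))
      message("CNV genes absent from the network ignored: ",
              paste(off, collapse = ", "))
    extreme <- extreme[names(extreme) %in% nn]
    cnvF <- setNames(as.integer(ifelse(extreme > 0, 1L, 0L)), names(extreme))
  }
  both <- intersect(names(mutF), names(cnvF))
  disagree <- both[mutF[both] != cnvF[both]]
  if (length(disagree)) {
    if (policy == "strict")
      stop("mutation and copy-number evidence disagree for: ",
           paste(disagree, collapse = ", "))
    warning("mutation and copy-number evidence disagree for ",
            paste(disagree, collapse = ", "),
            "; mutation effect takes precedence")
  }
  out <- c(mutF, cnvF[setdiff(names(cnvF), names(mutF))])
  out[order(match(names(out), nn))]
}

#' Expression-to-dynamics transfer: transition rates and initial state
#'
#' For a node with cohort-normalized expression `x` (clamped to
#' \[0.01, 0.99\]): up rate `scale * x`, down rate `scale * (1 - x)`, and
#' initial ON-probability `x` -- higher expression means a higher propensity
#' to be (and start) ON. Nodes without expression data receive the neutral
#' defaults `up = down = scale/2` and initial probability 0.5.
#'
#' @param profile A [PatientProfile-class] (expression already normalized).
#' @param network A [BooleanNetwork-class].
#' @param scale Positive global rate scale (reciprocal arbitrary time).
#' @param alias Optional gene-to-node alias table.
#' @return List with named numeric vectors `up`, `down`, `initialP`, each
#'   over all network nodes.
#' @export
deriveRatesAndInitial <- function(profile, network, scale = 1, alias = NULL) {
  if (!is.numeric(scale) || scale <= 0) stop("'scale' must be positive")
  nn <- nodes(network)
  x <- rep(0.5, length(nn))
  names(x) <- nn
  e <- profile@expression
  if (length(e)) {
    names(e) <- .mapGene(names(e), alias)
    hit <- intersect(names(e), nn)
    x[hit] <- pmin(pmax(e[hit], 0.01), 0.99)
  }
  list(up = scale * x, down = scale * (1 - x), initialP = x)
}

#' Build a subject-specific Boolean model
#'
#' Composes [applyDiscreteForcings()] and [deriveRatesAndInitial()]:
#' forcings override rates and initial probabilities (a forced node has no
#' rates and starts at its forced value). Deterministic: identical profiles
#' give identical models.
#'
#' @inheritParams applyDiscreteForcings
#' @param scale Positive global rate scale.
#' @return A validated [PersonalizedModel-class].
#' @examples
#' net <- parseRules("A, B\nB, !A")
#' prof <- patientProfile("s1", "AA")
#' buildPersonalizedModel(prof, net)
#' @export
buildPersonalizedModel <- function(profile, network,
                                   policy = c("mutation_first", "strict"),
                                   scale = 1, alias = NULL) {
  fz <- applyDiscreteForcings(profile, network, policy, alias)
  ri <- deriveRatesAndInitial(profile, network, scale, alias)
  free <- setdiff(nodes(network), names(fz))
  init <- ri$initialP
  if (length(fz)) init[names(fz)] <- as.numeric(fz)
  m <- new("PersonalizedModel", network = network, forcings = fz,
           upRates = ri$up[free], downRates = ri$down[free],
           initialP = init)
  validObject(m)
  m
}

#' Apply additional forcings on top of a personalized model
#'
#' Used for in-silico perturbations (e.g. fixing AR to 0 to mimic AR
#' inhibition): the new forcings override any existing dynamics for the
#' targeted nodes; other parameters are untouched.
#'
#' @param model A [PersonalizedModel-class].
#' @param forcings Named vector of 0/1 values over existing nodes.
#' @return A new [PersonalizedModel-class].
#' @export
applyPerturbation <- function(model, forcings) {
  nn <- nodes(model)
  if (!length(forcings)) return(model)
  if (is.null(names(forcings)) || !all(names(forcings) %in% nn))
    stop("perturbation targets must be network nodes")
  if (!all(forcings %in% c(0, 1))) stop("forced values must be 0/1")
  fz <- model@forcings
  fz[names(forcings)] <- as.integer(forcings)
  free <- setdiff(nn, names(fz))
  init <- model@initialP
  init[names(fz)] <- as.numeric(fz)
  up <- model@upRates; down <- model@downRates
  keepU <- intersect(free, names(up))
  # newly-forced nodes drop out of the rate set; newly-freed cannot occur
  m <- new("PersonalizedModel", network = model@network, forcings = fz,
           upRates = up[keepU], downRates = down[keepU], initialP = init)
  validObject(m)
  m
}
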