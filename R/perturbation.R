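# In-silico knockout experiments: paired before/after simulation, the
# percent change in AUC per node, and the filtered Mann-Whitney /
# Benjamini-Hochberg comparison between patient groups.

#' Percent change in AUC after a perturbation
#'
#' `(aucAp - aucBp) / aucBp * 100`. When the baseline AUC falls below
#' `floor`, the ratio is undefined and `NA` is returned instead of a
#' near-division-by-zero explosion.
#'
#' @param aucBp,aucAp Non-negative AUCs before/after perturbation
#'   (vectorized).
#' @param floor Positive guard on the baseline AUC; the pipeline uses
#'   `1e-3 * tMax`.
#' @return Numeric vector of percent changes, `NA` where undefined.
#' @examples
#' deltaAuc(0.5, 1.0)  # +100
#' @export
deltaAuc <- function(aucBp, aucAp, floor = 1e-9) {
  if (any(aucBp < 0, na.rm = TRUE) || any(aucAp < 0, na.rm = TRUE))
    stop("AUC values must be non-negative")
  stopifnot(floor > 0)
  out <- (aucAp - aucBp) / aucBp * 100
  out[aucBp < floor] <- NA_real_
  out
}

#' Simulate a model before and after a perturbation
#'
#' Runs the baseline model and the model with the perturbation forcings
#' applied on top, computes per-node AUCs and their percent change, and
#' records steady-state attainment for both runs. By default the same seed
#' drives both runs (common random numbers, reducing the Monte Carlo variance
#' of the difference); `pairedSeeds = FALSE` gives the perturbed run an
#' independent stream. With `engine = "auto"` the exact master-equation
#' solver is used whenever the non-forced state space fits under `cap`, and
#' the trajectory ensemble otherwise.
#'
#' @param model A [PersonalizedModel-class].
#' @param perturbation Named 0/1 vector of nodes to force (e.g. `c(AR = 0)`).
#' @param config A [simConfig()] object.
#' @param engine `"auto"`, `"exact"` or `"gillespie"`.
#' @param cap Exact-solver cap on non-forced nodes.
#' @param pairedSeeds Use a common seed for the two runs?
#' @return data.frame with columns `node`, `auc_bp`, `auc_ap`, `delta_pct`,
#'   `steady_bp`, `steady_ap`. A warning (not an error) is raised when a run
#'   has nodes short of steady state.
#' @export
simulatePair <- function(model, perturbation, config = simConfig(),
                         engine = c("auto", "exact", "gillespie"),
                         cap = 12L, pairedSeeds = TRUE) {
  engine <- match.arg(engine)
  perturbed <- applyPerturbation(model, perturbation)
  if (engine == "auto") {
    nFree <- length(model@upRates)
    engine <- if (nFree <= cap) "exact" else "gillespie"
  }
  cfgAp <- config
  if (!pairedSeeds) cfgAp$seed <- config$seed + 1000003L
  run <- function(m, cfg) {
    if (engine == "exact") exactMasterEquation(m, cfg, cap = cap)
    else estimateActivity(m, cfg)
  }
  bp <- run(model, config)
  ap <- run(perturbed, cfgAp)
  ssBp <- detectSteadyState(bp, config)
  ssAp <- detectSteadyState(ap, config)
  if (!all(ssBp$reached) || !all(ssAp$reached))
    warning("steady state not reached for some nodes within tMax")
  aucBp <- computeAuc(bp)
  aucAp <- computeAuc(ap)
  data.frame(node = names(aucBp),
             auc_bp = unname(aucBp), auc_ap = unname(aucAp),
             delta_pct = deltaAuc(unname(aucBp), unname(aucAp),
                                  floor = 1e-3 * config$tMax),
             steady_bp = ssBp$reached, steady_ap = ssAp$reached,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run a knockout experiment across a patient cohort
#'
#' Builds a personalized model per profile, simulates the before/after pair,
#' and stacks the per-node records into one long table.
#'
#' @param profiles List of [PatientProfile-class] objects.
#' @param network A [BooleanNetwork-class].
#' @param perturbation Named 0/1 vector of forced nodes (default: AR
#'   knockout).
#' @param config A [simConfig()] object.
#' @param engine,cap,pairedSeeds Passed to [simulatePair()].
#' @param policy,scale,alias Passed to [buildPersonalizedModel()].
#' @return data.frame: `sample`, `group`, `node`, `auc_bp`, `auc_ap`,
#'   `delta_pct`, `steady_bp`, `steady_ap`.
#' @export
runKnockoutStudy <- function(profiles, network, perturbation = c(AR = 0),
                             config = simConfig(),
                             engine = c("auto", "exact", "gillespie"),
                             cap = 12L, pairedSeeds = TRUE,
                             policy = "mutation_first", scale = 1,
                             alias = NULL) {
  engine <- match.arg(engine)
  parts <- lapply(profiles, function(p) {
    m <- buildPersonalizedModel(p, network, policy = policy, scale = scale,
                                alias = alias)
    rec <- simulatePair(m, perturbation, config, engine = engine, cap = cap,
                        pairedSeeds = pairedSeeds)
    cbind(sample = p@sampleId, group = p@group, rec,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test for two samples
#'
#' U is computed from rank sums with midrank ties. The p-value is two-sided:
#' exact by enumeration of labelings when there are no ties and
#' `n_A * n_B <= 400`, and the tie-corrected normal approximation (with
#' continuity correction) otherwise.
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @return List with `U` (statistic for `groupA`) and `p`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  useExact <- !ties && length(groupA) * length(groupB) <= 400L
  wt <- suppressWarnings(
    wilcox.test(groupA, groupB, exact = useExact, correct = TRUE))
  p <- wt$p.value
  # degenerate case (e.g. every observation tied): no evidence against the null
  if (is.nan(p)) p <- 1
  list(U = unname(wt$statistic), p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values, monotone-enforced and capped at 1,
#' returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Compare per-node knockout response between two patient groups
#'
#' For each node, the per-sample percent changes in AUC are split by group.
#' A node is admitted to testing when at least one group's median absolute
#' change reaches `thresholdPct` (default 3%). Admitted nodes are compared
#' with the two-sided Mann-Whitney U test and adjusted by Benjamini-Hochberg
#' across exactly the tested set; significance is called at adjusted
#' p < `alpha`. Undefined (NA) per-sample changes are dropped from that
#' node's comparison.
#'
#' @param records Long data.frame as returned by [runKnockoutStudy()]
#'   (columns `sample`, `node`, `delta_pct`; `group` optional if `metadata`
#'   given).
#' @param metadata Optional data.frame (`sample`, `group`) overriding/
#'   supplying group labels. Exactly two groups must be present.
#' @param thresholdPct Median-|deltaAUC| admission filter, percent.
#' @param alpha Significance level on the adjusted p-value.
#' @param pathways Optional named character vector of node pathway labels.
#' @return data.frame with one row per node: `node`, `pathway`,
#'   `median_delta_A`, `median_delta_B` (groups in label sort order), `n_A`,
#'   `n_B`, `u_statistic`, `p_value`, `adjusted_p`, `tested`, `significant`.
#' @export
compareGroups <- function(records, metadata = NULL, thresholdPct = 3,
                          alpha = 0.05, pathways = NULL) {
  df <- records
  if (!is.null(metadata)) {
    df$group <- metadata$group[match(df$sample, metadata$sample)]
  }
  if (!"group" %in% names(df))
    stop("group labels missing: supply 'metadata' or a 'group' column")
  groups <- sort(unique(df$group))
  if (length(groups) != 2L)
    stop(length(groups), " group labels found; run pairwise comparisons ",
         "with exactly two groups")
  nodesU <- unique(df$node)
  res <- lapply(nodesU, function(v) {
    sub <- df[df$node == v & !is.na(df$delta_pct), , drop = FALSE]
    a <- sub$delta_pct[sub$group == groups[1L]]
    b <- sub$delta_pct[sub$group == groups[2L]]
    medA <- if (length(a)) median(a) else NA_real_
    medB <- if (length(b)) median(b) else NA_real_
    tested <- isTRUE(max(abs(c(medA, medB)), na.rm = TRUE) >= thresholdPct) &&
      length(a) > 0L && length(b) > 0L
    u <- p <- NA_real_
    if (tested) {
      mw <- mannWhitneyU(a, b)
      u <- mw$U; p <- mw$p
    }
    data.frame(node = v,
               pathway = if (!is.null(pathways) && v %in% names(pathways))
                 unname(pathways[v]) else NA_character_,
               median_delta_A = medA, median_delta_B = medB,
               n_A = length(a), n_B = length(b),
               u_statistic = u, p_value = p,
               tested = tested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- NA_real_
  if (any(out$tested))
    out$adjusted_p[out$tested] <- bhAdjust(out$p_value[out$tested])
  out$significant <- !is.na(out$adjusted_p) & out$adjusted_p < alpha
  rownames(out) <- NULL
  out <- out[, c("node", "pathway", "median_delta_A", "median_delta_B",
                 "n_A", "n_B", "u_statistic", "p_value", "adjusted_p",
                 "tested", "significant")]
  attr(out, "groups") <- groups
  out
}
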