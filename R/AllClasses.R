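# S4 classes for the central objects: logic rules, networks, patient
# profiles, personalized models, and activity-curve ensembles.

.NODE_NAME_RE <- "^[A-Za-z0-9_]+$"

# a parsed rule body: a call/symbol, or a bare numeric for the constant
# rules "0" / "1"
setClassUnion("BoolExpr", c("language", "numeric"))

#' LogicRule: a Boolean update rule for one node
#'
#' A target node together with a Boolean formula over node names using
#' `&`, `|`, `!`, parentheses and the constants `0`/`1`
#' (precedence `!` > `&` > `|`).
#'
#' @slot target Character scalar, the regulated node.
#' @slot expr A quoted R language object holding the parsed formula.
#'
#' @seealso [parseRules()], [evaluateRule()], [ruleLiterals()]
#' @exportClass LogicRule
setClass("LogicRule",
  representation(target = "character", expr = "BoolExpr"))

setValidity("LogicRule", function(object) {
  if (length(object@target) != 1L || !grepl(.NODE_NAME_RE, object@target))
    return("'target' must be a single identifier matching [A-Za-z0-9_]+")
  ok <- tryCatch({ .checkRuleAst(object@expr); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  TRUE
})

#' BooleanNetwork: a Boolean logical model of a signaling network
#'
#' An ordered set of named nodes, one [LogicRule-class] per node, and an
#' optional node-to-pathway grouping. The signed influence graph (every
#' regulator of every rule, annotated by the parity of negations it appears
#' under) is derivable from the rules alone via [influenceGraph()].
#'
#' @slot nodes Character vector of unique node names; order is stable.
#' @slot rules Named list of [LogicRule-class] objects, one per node, in node
#'   order.
#' @slot pathways Named character vector mapping (a subset of) nodes to
#'   pathway labels; may be empty.
#'
#' @seealso [parseRules()], [writeRules()], [influenceGraph()],
#'   [toyARNetwork()]
#' @exportClass BooleanNetwork
setClass("BooleanNetwork",
  representation(nodes = "character", rules = "list",
                 pathways = "character"))

setValidity("BooleanNetwork", function(object) {
  n <- object@nodes
  if (length(n) == 0L) return("network must contain at least one node")
  if (anyDuplicated(n)) return(paste0("duplicate node name: ",
                                      n[duplicated(n)][1L]))
  if (!all(grepl(.NODE_NAME_RE, n)))
    return("node names must match [A-Za-z0-9_]+")
  if (length(object@rules) != length(n) ||
      !identical(names(object@rules), n))
    return("exactly one rule per node, in node order")
  for (i in seq_along(n)) {
    r <- object@rules[[i]]
    if (!is(r, "LogicRule")) return("all rules must be LogicRule objects")
    if (r@target != n[i]) return(paste0("rule ", i, " targets '", r@target,
                                        "' but is stored under '", n[i], "'"))
    vars <- .exprVars(r@expr)
    bad <- setdiff(vars, n)
    if (length(bad))
      return(paste0("rule for '", r@target, "' references undeclared node '",
                    bad[1L], "'"))
  }
  if (length(object@pathways)) {
    if (is.null(names(object@pathways)) || any(names(object@pathways) == ""))
      return("'pathways' must be a named character vector")
  }
  TRUE
})

#' PatientProfile: one patient's omics summary
#'
#' Holds the per-sample inputs the personalization step consumes: annotated
#' mutation calls, discretized copy-number ploidy, and cohort-normalized
#' expression in \[0, 1\].
#'
#' @slot sampleId Character scalar sample identifier.
#' @slot group Character scalar group label (e.g. "AA"/"EA").
#' @slot mutations data.frame with columns `gene` and `effect`
#'   (`activating`/`inactivating`/`unknown`).
#' @slot ploidy Named integer vector, values in -2..2.
#' @slot expression Named numeric vector, values in \[0, 1\].
#'
#' @seealso [patientProfile()], [buildPersonalizedModel()]
#' @exportClass PatientProfile
setClass("PatientProfile",
  representation(sampleId = "character", group = "character",
                 mutations = "data.frame", ploidy = "integer",
                 expression = "numeric"))

setValidity("PatientProfile", function(object) {
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    return("'sampleId' must be a non-empty string")
  if (length(object@group) != 1L || !nzchar(object@group))
    return("'group' label must be present")
  m <- object@mutations
  if (!all(c("gene", "effect") %in% names(m)))
    return("'mutations' needs columns gene, effect")
  if (nrow(m) && !all(m$effect %in% c("activating", "inactivating", "unknown")))
    return("mutation effects must be activating/inactivating/unknown")
  if (length(object@ploidy)) {
    if (is.null(names(object@ploidy)))
      return("'ploidy' must be a named vector")
    if (!all(object@ploidy %in% (-2L:2L)))
      return("ploidy values must lie in {-2,-1,0,1,2}")
  }
  if (length(object@expression)) {
    if (is.null(names(object@expression)))
      return("'expression' must be a named vector")
    if (any(object@expression < 0 | object@expression > 1))
      return("expression values must lie in [0, 1]")
  }
  TRUE
})

#' PersonalizedModel: a subject-specific Boolean model
#'
#' A [BooleanNetwork-class] together with the patient-specific parameters
#' derived from omics: hard node forcings (from mutations / extreme copy
#' number), per-node up/down transition rates and an initial ON-probability
#' per node (from expression).
#'
#' @slot network The underlying [BooleanNetwork-class].
#' @slot forcings Named integer vector over a subset of nodes, values 0/1;
#'   forced nodes never change state.
#' @slot upRates,downRates Named numeric vectors over exactly the non-forced
#'   nodes; strictly positive rates (reciprocal arbitrary time) at which a
#'   node flips 0->1 (when its rule evaluates to 1) or 1->0 (rule 0).
#' @slot initialP Named numeric vector over all nodes: probability the node
#'   starts ON; equals the forced value for forced nodes.
#'
#' @seealso [buildPersonalizedModel()], [estimateActivity()],
#'   [applyPerturbation()]
#' @exportClass PersonalizedModel
setClass("PersonalizedModel",
  representation(network = "BooleanNetwork", forcings = "integer",
                 upRates = "numeric", downRates = "numeric",
                 initialP = "numeric"))

setValidity("PersonalizedModel", function(object) {
  nn <- object@network@nodes
  f <- object@forcings
  if (length(f)) {
    if (is.null(names(f)) || !all(names(f) %in% nn))
      return("forcing targets must be network nodes")
    if (anyDuplicated(names(f))) return("duplicate forcing target")
    if (!all(f %in% c(0L, 1L))) return("forced values must be 0/1")
  }
  free <- setdiff(nn, names(f))
  for (s in c("upRates", "downRates")) {
    r <- slot(object, s)
    if (!identical(sort(names(r)), sort(free)))
      return(paste0("'", s, "' must cover exactly the non-forced nodes"))
    if (any(!is.finite(r)) || any(r <= 0))
      return(paste0("'", s, "' must be strictly positive and finite"))
  }
  p <- object@initialP
  if (!identical(sort(names(p)), sort(nn)))
    return("'initialP' must cover every node")
  if (any(p < 0 | p > 1)) return("'initialP' must lie in [0, 1]")
  if (length(f) && any(abs(p[names(f)] - f) > 0))
    return("forced nodes must have initialP equal to their forced value")
  TRUE
})

#' ActivityCurveSet: per-node activity trajectories
#'
#' Estimated (or exact) probability-of-ON for every node on a shared time
#' grid, with optional Monte Carlo standard errors.
#'
#' @slot times Strictly increasing numeric grid on \[0, tMax\].
#' @slot activity Numeric matrix, nodes x times, entries in \[0, 1\].
#' @slot stderr Numeric matrix of per-point binomial standard errors (same
#'   shape as `activity`), or a 0x0 matrix for exact solutions.
#' @slot method Character scalar, `"gillespie"` or `"exact"`.
#'
#' @seealso [estimateActivity()], [exactMasterEquation()], [computeAuc()],
#'   [detectSteadyState()]
#' @exportClass ActivityCurveSet
setClass("ActivityCurveSet",
  representation(times = "numeric", activity = "matrix",
                 stderr = "matrix", method = "character"))

setValidity("ActivityCurveSet", function(object) {
  t <- object@times
  if (length(t) < 2L || any(diff(t) <= 0))
    return("'times' must be strictly increasing with >= 2 points")
  a <- object@activity
  if (ncol(a) != length(t)) return("activity columns must match times")
  if (is.null(rownames(a))) return("activity rows must be named by node")
  if (any(a < -1e-12 | a > 1 + 1e-12)) return("activity must lie in [0, 1]")
  if (length(object@stderr) && !identical(dim(object@stderr), dim(a)))
    return("stderr must match activity dimensions")
  TRUE
})

setMethod("show", "BooleanNetwork", function(object) {
  ig <- influenceGraph(object)
  cat("BooleanNetwork with", length(object@nodes), "nodes and",
      nrow(ig), "signed edges\n")
  cat("  nodes:", paste(head(object@nodes, 8L), collapse = ", "),
      if (length(object@nodes) > 8L) "..." else "", "\n")
  if (length(object@pathways))
    cat("  pathways:", length(unique(object@pathways)), "groups over",
        length(object@pathways), "nodes\n")
})

setMethod("show", "PatientProfile", function(object) {
  cat("PatientProfile", object@sampleId, "(group ", object@group, ")\n",
      sep = "")
  cat("  mutations:", nrow(object@mutations),
      "| ploidy genes:", length(object@ploidy),
      "| expression genes:", length(object@expression), "\n")
})

setMethod("show", "PersonalizedModel", function(object) {
  cat("PersonalizedModel over", length(object@network@nodes), "nodes;",
      length(object@forcings), "forced\n")
  if (length(object@forcings))
    cat("  forcings:", paste(names(object@forcings), object@forcings,
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ActivityCurveSet", function(object) {
  cat("ActivityCurveSet (", object@method, "): ", nrow(object@activity),
      " nodes on [", min(object@times), ", ", max(object@times), "] with ",
      length(object@times), " grid points\n", sep = "")
})
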