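# Continuous-time stochastic simulation of personalized Boolean models:
# Monte Carlo trajectory ensembles, an exact master-equation solver used as
# deterministic engine/oracle, steady-state detection and AUC integration.

#' Simulation configuration
#'
#' Defaults: the time horizon is 50 arbitrary units with a 101-point grid,
#' 5000 Monte Carlo trajectories, and steady state declared when the activity
#' range over the final 20% of the grid is at most 0.01 (tied to Monte Carlo
#' error at the default ensemble size).
#'
#' @param tMax Simulation horizon (arbitrary time units, > 0).
#' @param nGrid Number of evenly spaced evaluation times on \[0, tMax\]
#'   (>= 2).
#' @param nTrajectories Monte Carlo ensemble size (>= 1).
#' @param seed Integer root seed; per-trajectory streams are derived from it
#'   by a counter-based scheme so trajectory i is reproducible in isolation.
#' @param steadyTol Steady-state tolerance on the activity range.
#' @param steadyWindow Fraction of the grid (from the end) used as the
#'   convergence window, in (0, 1).
#' @return A list of class `SimulationConfig`.
#' @export
simConfig <- function(tMax = 50, nGrid = 101L, nTrajectories = 5000L,
                      seed = 1L, steadyTol = 0.01, steadyWindow = 0.2) {
  stopifnot(tMax > 0, nGrid >= 2, nTrajectories >= 1, steadyTol > 0,
            steadyWindow > 0, steadyWindow < 1)
  structure(list(tMax = tMax, nGrid = as.integer(nGrid),
                 nTrajectories = as.integer(nTrajectories),
                 seed = as.integer(seed), steadyTol = steadyTol,
                 steadyWindow = steadyWindow),
            class = "SimulationConfig")
}

.timeGrid <- function(config) seq(0, config$tMax, length.out = config$nGrid)

# Flatten a PersonalizedModel into the regulator/truth-table arrays the C++
# kernels consume.
.compileModel <- function(model) {
  stopifnot(is(model, "PersonalizedModel"))
  net <- model@network
  nn <- net@nodes
  n <- length(nn)
  forced <- rep(-1L, n)
  if (length(model@forcings))
    forced[match(names(model@forcings), nn)] <- model@forcings
  up <- down <- rep(0, n)
  free <- names(model@upRates)
  up[match(free, nn)] <- model@upRates[free]
  down[match(free, nn)] <- model@downRates[free]
  regs <- vector("list", n)
  tt <- vector("list", n)
  for (i in seq_len(n)) {
    r <- .ruleTruthTable(net, nn[i])
    regs[[i]] <- match(r$regulators, nn)
    tt[[i]] <- r$table
  }
  list(nodes = nn, regs = regs, tt = tt, up = up, down = down,
       forced = forced, init = unname(model@initialP[nn]))
}

.newCurveSet <- function(nodes, times, activity, stderr, method) {
  rownames(activity) <- nodes
  colnames(activity) <- NULL
  if (length(stderr)) { rownames(stderr) <- nodes; colnames(stderr) <- NULL }
  new("ActivityCurveSet", times = times, activity = activity,
      stderr = stderr, method = method)
}

#' Single Gillespie trajectory of a personalized model
#'
#' One realization of the asynchronous continuous-time jump process: at each
#' jump exactly one non-forced node whose value disagrees with its rule flips,
#' after an exponential waiting time at the node's up (0 to 1) or down (1 to
#' 0) rate. Forced nodes never flip. A state with no eligible flips is
#' absorbing and the path is constant to `tMax`. Identical
#' `(seed, trajectoryIndex)` yields a bit-identical path.
#'
#' @param model A [PersonalizedModel-class].
#' @param config A [simConfig()] object.
#' @param trajectoryIndex Non-negative integer selecting the trajectory's
#'   random stream.
#' @return List with `times` (jump times, starting at 0) and `states`
#'   (matrix, one row per segment, columns named by node).
#' @export
gillespieTrajectory <- function(model, config, trajectoryIndex = 0L) {
  stopifnot(trajectoryIndex >= 0)
  cm <- .compileModel(model)
  res <- cpp_gillespie_path(cm$regs, cm$tt, cm$up, cm$down, cm$forced,
                            cm$init, config$tMax, as.double(config$seed),
                            as.integer(trajectoryIndex))
  colnames(res$states) <- cm$nodes
  res
}

#' Monte Carlo estimate of per-node activity curves
#'
#' Simulates an ensemble of `nTrajectories` Gillespie trajectories and
#' returns, for every node, the fraction of the ensemble that is ON at each
#' grid time, with binomial standard errors.
#'
#' @param model A [PersonalizedModel-class].
#' @param config A [simConfig()] object.
#' @return An [ActivityCurveSet-class] with `method = "gillespie"`.
#' @seealso [exactMasterEquation()] for the deterministic solution on small
#'   state spaces.
#' @export
estimateActivity <- function(model, config = simConfig()) {
  cm <- .compileModel(model)
  grid <- .timeGrid(config)
  act <- cpp_gillespie_activity(cm$regs, cm$tt, cm$up, cm$down, cm$forced,
                                cm$init, grid, config$nTrajectories,
                                as.double(config$seed))
  se <- sqrt(act * (1 - act) / config$nTrajectories)
  .newCurveSet(cm$nodes, grid, act, se, "gillespie")
}

#' Exact activity curves from the master equation
#'
#' Builds the full rate matrix of the jump process over the `2^m` states of
#' the `m` non-forced nodes and propagates the transient distribution on the
#' time grid by uniformization. Deterministic; probability mass is conserved
#' to the truncation tolerance.
#'
#' @param model A [PersonalizedModel-class].
#' @param config A [simConfig()] object.
#' @param cap Maximum number of non-forced nodes (default 12); beyond it an
#'   error advises the Monte Carlo engine.
#' @param tol Per-step truncation tolerance of the uniformization series.
#' @return An [ActivityCurveSet-class] with `method = "exact"` and an
#'   attribute `massErr` giving the worst probability-mass defect seen.
#' @export
exactMasterEquation <- function(model, config = simConfig(), cap = 12L,
                                tol = 1e-12) {
  cm <- .compileModel(model)
  grid <- .timeGrid(config)
  res <- cpp_exact_activity(cm$regs, cm$tt, cm$up, cm$down, cm$forced,
                            cm$init, grid, as.integer(cap), tol)
  cs <- .newCurveSet(cm$nodes, grid, res$activity,
                     matrix(numeric(0), 0, 0), "exact")
  attr(cs, "massErr") <- res$mass_err
  cs
}

#' Detect steady state of activity curves
#'
#' A curve has reached steady state when the max-min range of its activity
#' over the final `steadyWindow` fraction of the grid is at most `steadyTol`;
#' the attained level is the mean over that window.
#'
#' @param curves An [ActivityCurveSet-class].
#' @param config A [simConfig()] object supplying `steadyTol` and
#'   `steadyWindow`.
#' @return data.frame with columns `node`, `reached` (logical), `level`.
#' @export
detectSteadyState <- function(curves, config = simConfig()) {
  stopifnot(is(curves, "ActivityCurveSet"))
  G <- length(curves@times)
  nWin <- max(2L, ceiling(config$steadyWindow * G))
  idx <- (G - nWin + 1L):G
  win <- curves@activity[, idx, drop = FALSE]
  rng <- apply(win, 1L, function(z) max(z) - min(z))
  data.frame(node = rownames(curves@activity),
             reached = rng <= config$steadyTol,
             level = rowMeans(win),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Area under the activity curve
#'
#' Trapezoidal integral of each node's activity over the simulation window;
#' bounded by `0 <= AUC <= tMax`.
#'
#' @param curves An [ActivityCurveSet-class], or a numeric activity vector
#'   (then `times` must be supplied).
#' @param times Time grid when `curves` is a plain vector.
#' @return Named numeric vector of AUCs (or a single number for a vector
#'   input).
#' @export
computeAuc <- function(curves, times = NULL) {
  if (is(curves, "ActivityCurveSet")) {
    t <- curves@times
    a <- curves@activity
    return(setNames(apply(a, 1L, function(z) pracma::trapz(t, z)),
                    rownames(a)))
  }
  if (is.null(times) || length(times) < 2L)
    stop("AUC needs a time grid with at least 2 points")
  if (length(curves) != length(times))
    stop("activity and time grid lengths differ")
  pracma::trapz(times, curves)
}

#' Export activity curves and AUCs as long-format tables
#'
#' @param curves An [ActivityCurveSet-class].
#' @param sample Sample identifier recorded in the output.
#' @return `activityTable()`: data.frame (sample, node, time, activity);
#'   `aucTable()`: data.frame (sample, node, auc).
#' @export
activityTable <- function(curves, sample = NA_character_) {
  a <- curves@activity
  data.frame(sample = sample,
             node = rep(rownames(a), times = ncol(a)),
             time = rep(curves@times, each = nrow(a)),
             activity = as.vector(a),
             stringsAsFactors = FALSE)
}

#' @rdname activityTable
#' @export
aucTable <- function(curves, sample = NA_character_) {
  auc <- computeAuc(curves)
  data.frame(sample = sample, node = names(auc), auc = unname(auc),
             stringsAsFactors = FALSE)
}
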