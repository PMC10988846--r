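test_that("exact solver reproduces the two-state closed form", {
  net <- parseRules("A, 1")
  for (r in c(0.4, 1, 2.5)) {
    m <- makeModel(net, up = c(A = r), down = c(A = 1),
                   init = c(A = 0))
    cfg <- simConfig(tMax = 5, nGrid = 51)
    ex <- exactMasterEquation(m, cfg)
    expect_lt(max(abs(activityMatrix(ex)["A", ] -
                        (1 - exp(-r * curveTimes(ex))))), 1e-9)
  }
})

test_that("forcing dominates logic and freezes curves", {
  net <- parseRules("A, 1")
  m <- makeModel(net, forced = c(A = 0L))
  cfg <- simConfig(tMax = 10, nGrid = 21, nTrajectories = 200)
  expect_true(all(activityMatrix(estimateActivity(m, cfg)) == 0))
  expect_true(all(activityMatrix(exactMasterEquation(m, cfg)) == 0))
  # a forced-ON node has zero Monte Carlo standard error
  m1 <- makeModel(net, forced = c(A = 1L))
  mc <- estimateActivity(m1, cfg)
  expect_true(all(activityMatrix(mc) == 1))
  expect_true(all(mcStderr(mc) == 0))
  # all nodes forced: constant at the forced values
  tog <- parseRules("A, !B\nB, !A")
  mAll <- makeModel(tog, forced = c(A = 1L, B = 0L))
  exAll <- exactMasterEquation(mAll, simConfig(tMax = 3, nGrid = 7))
  expect_true(all(activityMatrix(exAll)["A", ] == 1))
  expect_true(all(activityMatrix(exAll)["B", ] == 0))
})

test_that("symmetric toggle and self-negating nodes sit at their closed-form levels", {
  tog <- parseRules("A, !B\nB, !A")
  m <- makeModel(tog)  # symmetric rates, uniform initial distribution
  ex <- exactMasterEquation(m, simConfig(tMax = 20, nGrid = 41))
  expect_lt(max(abs(activityMatrix(ex) - 0.5)), 1e-9)

  # self-negating input: stationary P(ON) = up/(up+down)
  osc <- parseRules("A, !A")
  x <- 0.73
  mo <- makeModel(osc, up = c(A = x), down = c(A = 1 - x), init = c(A = x))
  exo <- exactMasterEquation(mo, simConfig(tMax = 20, nGrid = 41))
  expect_lt(max(abs(activityMatrix(exo)["A", ] - x)), 1e-9)

  # frozen self-sustaining input: activity identically its initial p
  frz <- parseRules("A, A")
  mf <- makeModel(frz, init = c(A = 0.3))
  exf <- exactMasterEquation(mf, simConfig(tMax = 20, nGrid = 41))
  expect_lt(max(abs(activityMatrix(exf)["A", ] - 0.3)), 1e-9)
})

test_that("single-jump waiting times are exponential with the up rate", {
  net <- parseRules("A, 1")
  r <- 1.7
  m <- makeModel(net, up = c(A = r), down = c(A = 1), init = c(A = 0))
  cfg <- simConfig(tMax = 100, nGrid = 11, seed = 11)
  n <- 5000
  jumps <- vapply(seq_len(n) - 1L, function(i) {
    p <- gillespieTrajectory(m, cfg, trajectoryIndex = i)
    p$times[2L]
  }, numeric(1))
  se <- (1 / r) / sqrt(n)
  expect_lt(abs(mean(jumps) - 1 / r), 3 * se)
})

test_that("trajectories are bit-identical for identical (seed, index)", {
  m <- buildPersonalizedModel(neutralProfile(), toyARNetwork())
  cfg <- simConfig(seed = 7)
  p1 <- gillespieTrajectory(m, cfg, trajectoryIndex = 3L)
  p2 <- gillespieTrajectory(m, cfg, trajectoryIndex = 3L)
  expect_identical(p1, p2)
  p3 <- gillespieTrajectory(m, cfg, trajectoryIndex = 4L)
  expect_false(identical(p1, p3))
  # full ensemble output is reproducible too
  cfgS <- simConfig(nTrajectories = 300, seed = 7)
  expect_identical(activityMatrix(estimateActivity(m, cfgS)),
                   activityMatrix(estimateActivity(m, cfgS)))
})

test_that("a state with no eligible flips is absorbing, not an error", {
  net <- parseRules("A, A")
  m <- makeModel(net, init = c(A = 1))
  p <- gillespieTrajectory(m, simConfig(tMax = 10), trajectoryIndex = 0L)
  expect_length(p$times, 1L)
  expect_equal(unname(p$states[1L, "A"]), 1L)
})

test_that("Monte Carlo activity agrees with the master equation", {
  cfg <- simConfig(nTrajectories = 5000, seed = 3)
  models <- list(
    buildPersonalizedModel(neutralProfile(), toyARNetwork()),
    makeModel(generateRandomNetwork(6, maxRegulators = 2, seed = 21),
              up = setNames(runif(6, 0.3, 1.5), paste0("N", 1:6)),
              down = setNames(runif(6, 0.3, 1.5), paste0("N", 1:6))))
  for (m in models) {
    ex <- exactMasterEquation(m, cfg)
    mc <- estimateActivity(m, cfg)
    p <- activityMatrix(ex)
    # 5 binomial SEs plus a 3/n discreteness floor: near p = 0 or 1 the
    # Gaussian band is narrower than one achievable count
    tol <- 5 * sqrt(p * (1 - p) / cfg$nTrajectories) +
      3 / cfg$nTrajectories
    expect_true(all(abs(activityMatrix(mc) - p) <= tol))
  }
})

test_that("the exact solver conserves probability and respects its cap", {
  m <- buildPersonalizedModel(neutralProfile(), toyARNetwork())
  ex <- exactMasterEquation(m, simConfig())
  expect_lt(attr(ex, "massErr"), 1e-9)
  expect_error(exactMasterEquation(m, simConfig(), cap = 4L),
               "Monte Carlo")
})

test_that("steady-state detection follows the windowed range criterion", {
  cfg <- simConfig(tMax = 10, nGrid = 101, steadyTol = 0.01,
                   steadyWindow = 0.2)
  t <- seq(0, 10, length.out = 101)
  mk <- function(a) new("ActivityCurveSet", times = t,
                        activity = matrix(a, 1, dimnames = list("A", NULL)),
                        stderr = matrix(numeric(0), 0, 0), method = "exact")
  const <- detectSteadyState(mk(rep(0.4, 101)), cfg)
  expect_true(const$reached)
  expect_equal(const$level, 0.4)

  expCurve <- detectSteadyState(mk(1 - exp(-1.5 * t)), cfg)  # r*tMax = 15
  expect_true(expCurve$reached)
  expect_equal(expCurve$level, 1, tolerance = 1e-3)

  ramp <- detectSteadyState(mk(t / 10), cfg)
  expect_false(ramp$reached)
})

test_that("AUC is the trapezoidal integral, bounded by the horizon", {
  t10 <- seq(0, 10, length.out = 21)
  expect_equal(computeAuc(rep(1, 21), t10), 10)
  expect_equal(computeAuc(rep(0, 21), t10), 0)
  t1 <- seq(0, 1, length.out = 11)
  expect_equal(computeAuc(t1, t1), 0.5)
  expect_error(computeAuc(1, 1), "at least 2")

  cfg <- simConfig(tMax = 12, nGrid = 25, nTrajectories = 400)
  m <- buildPersonalizedModel(neutralProfile(), toyARNetwork())
  auc <- computeAuc(estimateActivity(m, cfg))
  expect_true(all(auc >= 0 & auc <= 12))
})

test_that("activity and AUC export tables carry the long-format schema", {
  m <- buildPersonalizedModel(neutralProfile(), toyARNetwork())
  cfg <- simConfig(tMax = 5, nGrid = 6, nTrajectories = 50)
  cs <- estimateActivity(m, cfg)
  at <- activityTable(cs, sample = "s1")
  expect_identical(names(at), c("sample", "node", "time", "activity"))
  expect_equal(nrow(at), 10 * 6)
  au <- aucTable(cs, sample = "s1")
  expect_identical(names(au), c("sample", "node", "auc"))
  expect_equal(nrow(au), 10)
})
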