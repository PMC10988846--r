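test_that("lRR discretization matches the printed thresholds exactly", {
  expect_identical(discretizeLrr(c(-1.2, -1.1, -1.0, -0.2, -0.1, 0, 0.2,
                                   0.3, 0.7, 0.71, 2)),
                   c(-2L, -2L, -1L, -1L, 0L, 0L, 0L, 1L, 1L, 2L, 2L))
  expect_error(discretizeLrr(c(0, NA)), "finite")
  expect_error(discretizeLrr(Inf), "finite")
  # total, monotone non-decreasing step function
  x <- sort(runif(200, -3, 3))
  expect_true(all(diff(discretizeLrr(x)) >= 0))
})

test_that("cohort expression normalization is min-max with the 0.5 convention", {
  m <- matrix(c(10, 20, 30, 7, 7, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  norm <- normalizeExpression(m)
  expect_equal(unname(norm["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(norm["g2", ]), c(0.5, 0.5, 0.5))
  expect_error(normalizeExpression(m[, 1, drop = FALSE]), "2 samples")
  expect_error(normalizeExpression(-m), "non-negative")

  # invariant to positive affine rescaling; ranks preserved
  raw <- matrix(rexp(50, 0.1), 5, 10,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expect_equal(normalizeExpression(raw), normalizeExpression(3 * raw + 2))
  nm <- normalizeExpression(raw)
  for (g in rownames(raw))
    expect_identical(rank(nm[g, ]), rank(raw[g, ]))
  # rank method gives percentiles
  nr <- normalizeExpression(raw, method = "rank")
  expect_true(all(nr >= 0 & nr <= 1))
})

test_that("discrete forcings follow the mutation/CNV policy table", {
  net <- parseRules("TP53, TP53\nMYC, MYC\nA, TP53 & MYC")
  pIn <- patientProfile("s", "g",
    mutations = data.frame(gene = "TP53", effect = "inactivating"))
  expect_identical(applyDiscreteForcings(pIn, net), c(TP53 = 0L))

  pAmp <- patientProfile("s", "g", ploidy = c(MYC = 2L))
  expect_identical(applyDiscreteForcings(pAmp, net), c(MYC = 1L))

  # unknown effect and |ploidy| <= 1 force nothing
  pNull <- patientProfile("s", "g",
    mutations = data.frame(gene = "TP53", effect = "unknown"),
    ploidy = c(MYC = 1L, TP53 = -1L))
  expect_length(applyDiscreteForcings(pNull, net), 0L)

  # contradiction: mutation wins with a warning, or errors under strict
  pCon <- patientProfile("s", "g",
    mutations = data.frame(gene = "MYC", effect = "activating"),
    ploidy = c(MYC = -2L))
  expect_warning(f <- applyDiscreteForcings(pCon, net), "disagree")
  expect_identical(f, c(MYC = 1L))
  expect_error(applyDiscreteForcings(pCon, net, policy = "strict"),
               "disagree")

  # genes outside the network are reported and skipped
  pOff <- patientProfile("s", "g",
    mutations = data.frame(gene = "GSTP1", effect = "inactivating"))
  expect_message(f2 <- applyDiscreteForcings(pOff, net), "ignored")
  expect_length(f2, 0L)

  # alias table routes omics genes onto network nodes
  ali <- data.frame(omics_gene = "MYC_V2", network_node = "MYC")
  pAli <- patientProfile("s", "g",
    mutations = data.frame(gene = "MYC_V2", effect = "activating"))
  expect_identical(applyDiscreteForcings(pAli, net, alias = ali),
                   c(MYC = 1L))
})

test_that("the expression transfer yields symmetric defaults and clamped rates", {
  net <- parseRules("A, 1\nB, A")
  pr <- patientProfile("s", "g", expression = c(A = 0.5, B = 1))
  ri <- deriveRatesAndInitial(pr, net, scale = 2)
  expect_equal(unname(ri$up["A"]), 1)     # scale * 0.5
  expect_equal(unname(ri$down["A"]), 1)
  expect_equal(unname(ri$initialP["A"]), 0.5)
  expect_equal(unname(ri$up["B"]), 2 * 0.99)  # clamped at 0.99
  expect_error(deriveRatesAndInitial(pr, net, scale = 0), "positive")

  # missing gene falls back to neutral defaults
  pm <- patientProfile("s", "g", expression = c(A = 0.2))
  rm_ <- deriveRatesAndInitial(pm, net, scale = 1)
  expect_equal(unname(rm_$up["B"]), 0.5)
  expect_equal(unname(rm_$initialP["B"]), 0.5)
})

test_that("personalized models compose forcings and rates correctly", {
  net <- toyARNetwork()
  m0 <- buildPersonalizedModel(neutralProfile(), net)
  expect_length(forcings(m0), 0L)
  expect_true(all(transitionRates(m0)$up == 0.5))
  expect_true(all(initialProbabilities(m0) == 0.5))

  # forcing AR to 1 makes its simulated activity identically 1
  p1 <- patientProfile("s", "g",
    mutations = data.frame(gene = "AR", effect = "activating"))
  m1 <- buildPersonalizedModel(p1, net)
  ex <- exactMasterEquation(m1, simConfig(tMax = 5, nGrid = 11))
  expect_true(all(activityMatrix(ex)["AR", ] == 1))

  # determinism: identical profiles give identical models
  expect_identical(buildPersonalizedModel(p1, net),
                   buildPersonalizedModel(p1, net))
})

test_that("a sample's model is independent of other samples' discrete omics", {
  spec <- cohortSpec(nPerGroup = 4, seed = 11)
  coh <- simulateCohort(spec)
  profs1 <- suppressMessages(cohortProfiles(coh))
  # scramble every other sample's mutations and CNVs
  coh2 <- coh
  keep <- coh2$metadata$sample[1L]
  others <- setdiff(coh2$metadata$sample, keep)
  coh2$mutations <- coh2$mutations[coh2$mutations$sample == keep, ,
                                   drop = FALSE]
  coh2$lrr[, others] <- 0
  profs2 <- suppressMessages(cohortProfiles(coh2))
  m1 <- buildPersonalizedModel(profs1[[keep]], coh$network)
  m2 <- buildPersonalizedModel(profs2[[keep]], coh$network)
  expect_identical(m1, m2)
})

test_that("input-free nodes reach their expression-derived stationary level", {
  # self-negating node: stationary P(ON) = x under the linear transfer
  net <- parseRules("A, !A")
  x <- 0.8
  pr <- patientProfile("s", "g", expression = c(A = x))
  m <- buildPersonalizedModel(pr, net)
  cfg <- simConfig(tMax = 40, nGrid = 81, nTrajectories = 4000, seed = 2)
  mc <- estimateActivity(m, cfg)
  lastQ <- activityMatrix(mc)[1L, 61:81]
  expect_lt(abs(mean(lastQ) - x), 5 * sqrt(x * (1 - x) / 4000))
})
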