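test_that("the toy AR fixture is frozen and well-formed", {
  net <- toyARNetwork()
  expect_equal(length(nodes(net)), 10L)
  expect_equal(nrow(influenceGraph(net)), nrow(influenceGraph(toyARNetwork())))
  expect_identical(writeRules(net), writeRules(toyARNetwork()))
  expect_true(all(c("AR", "AR_ERG", "IDH1", "SMAD", "ZBTB17") %in%
                    nodes(net)))
  # every node is reachable from an input node
  inputs <- names(pathwayGroups(net))[pathwayGroups(net) == "Input"]
  expect_setequal(reachableNodes(net, inputs), nodes(net))
  # AR upregulates AR_ERG/ZBTB17 and represses the SMAD/IDH1 branches
  ig <- influenceGraph(net)
  edge <- function(f, t) ig$sign[ig$from == f & ig$to == t]
  expect_identical(edge("AR", "AR_ERG"), "+")
  expect_identical(edge("AR", "ZBTB17"), "+")
  expect_identical(edge("AR", "TGFB"), "-")
  expect_identical(edge("AR", "IDH1"), "-")
})

test_that("random networks are reproducible with no vacuous literals", {
  n1 <- generateRandomNetwork(6, maxRegulators = 3, seed = 42)
  n2 <- generateRandomNetwork(6, maxRegulators = 3, seed = 42)
  expect_identical(writeRules(n1), writeRules(n2))
  expect_false(identical(writeRules(n1),
                         writeRules(generateRandomNetwork(6, 3, seed = 43))))

  single <- generateRandomNetwork(1, maxRegulators = 1, seed = 1)
  expect_identical(influenceGraph(single)$from, "N1")
  expect_error(generateRandomNetwork(0, 1), ">= 1")
  expect_error(generateRandomNetwork(3, 5), "maxRegulators")

  # every listed regulator matters semantically
  for (seed in 1:4) {
    net <- generateRandomNetwork(7, maxRegulators = 3, seed = seed)
    syn <- unique(influenceGraph(net)[, c("from", "to")])
    sem <- semanticDependencies(net)
    expect_setequal(paste(syn$from, syn$to), paste(sem$from, sem$to))
  }
})

test_that("cohort generation is seed-deterministic with stable schemas", {
  spec <- cohortSpec(nPerGroup = 4, seed = 10)
  c1 <- simulateCohort(spec)
  c2 <- simulateCohort(spec)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$lrr, c2$lrr)
  expect_identical(c1$expressionRaw, c2$expressionRaw)

  c3 <- simulateCohort(cohortSpec(nPerGroup = 4, seed = 11))
  expect_false(identical(c1$expressionRaw, c3$expressionRaw))
  expect_identical(dimnames(c1$lrr), dimnames(c3$lrr))
  expect_identical(names(c1$mutations), names(c3$mutations))

  expect_identical(c1$metadata$group,
                   rep(c("AA", "EA"), each = 4))
  expect_error(cohortSpec(nPerGroup = 2), "nPerGroup")
  expect_error(
    cohortSpec(plantedEffects = list(list(target = "NOPE",
                                          channel = "cnv",
                                          magnitude = 1))),
    "gene universe")
  expect_error(
    cohortSpec(plantedEffects = list(list(target = "AR",
                                          channel = "bogus",
                                          magnitude = 1))),
    "channel")
})

test_that("cohort TSVs round-trip through the personalization schemas", {
  dir <- tempfile("cohort")
  spec <- cohortSpec(nPerGroup = 3, seed = 6, plantedEffects = list(
    list(target = "AR", channel = "cnv", magnitude = -1.5)))
  coh <- simulateCohort(spec)
  writeCohort(coh, dir)
  expect_setequal(list.files(dir),
                  c("rules.bnet", "pathway_map.tsv", "mutations.tsv",
                    "cnv_lrr.tsv", "expression.tsv", "metadata.tsv"))
  back <- readCohort(dir)
  expect_identical(writeRules(back$network), writeRules(coh$network))
  expect_identical(back$mutations, coh$mutations)
  expect_equal(back$lrr, coh$lrr, tolerance = 1e-6)
  expect_identical(back$metadata, coh$metadata)

  # the re-read cohort feeds the personalization pipeline unchanged
  p1 <- suppressMessages(cohortProfiles(coh))
  p2 <- suppressMessages(cohortProfiles(back))
  expect_equal(length(p1), length(p2))
  expect_identical(forcings(buildPersonalizedModel(p1[[1]], coh$network)),
                   forcings(buildPersonalizedModel(p2[[1]], back$network)))

  # a planted deep deletion shows up as ploidy -2 for group A samples
  pl <- discretizeLrr(coh$lrr["AR", ])
  expect_true(any(pl[coh$metadata$group == "AA"] == -2L))
})

test_that("planted expression shifts separate the groups; none leaves them exchangeable", {
  spec <- cohortSpec(nPerGroup = 8, seed = 2, plantedEffects = list(
    list(target = "AR", channel = "expression_shift", magnitude = 2)))
  coh <- simulateCohort(spec)
  isA <- coh$metadata$group == "AA"
  expect_gt(mean(log(coh$expressionRaw["AR", isA])) -
              mean(log(coh$expressionRaw["AR", !isA])), 1)

  # without planted effects the pooled group expression distributions agree
  pooledA <- c(); pooledB <- c()
  for (r in 1:20) {
    c0 <- simulateCohort(cohortSpec(nPerGroup = 5, seed = 100 + r))
    isA0 <- c0$metadata$group == "AA"
    pooledA <- c(pooledA, log(c0$expressionRaw["AR", isA0]))
    pooledB <- c(pooledB, log(c0$expressionRaw["AR", !isA0]))
  }
  expect_gt(suppressWarnings(ks.test(pooledA, pooledB)$p.value), 0.01)
})

test_that("methylation coupling hits its target Spearman structure", {
  mk <- function(mag, seed) {
    simulateMethylationCoupling(cohortSpec(nPerGroup = 8, seed = seed,
      plantedEffects = list(list(target = "AR",
                                 channel = "methylation_coupling",
                                 magnitude = mag))))
  }
  expect_error(mk(1.7, 1), "rho")
  expect_error(
    simulateMethylationCoupling(cohortSpec(nPerGroup = 8, seed = 1)),
    "methylation_coupling")

  meth <- mk(1, 4)
  expect_true(all(meth$beta > 0 & meth$beta < 1))
  expect_equal(nrow(meth$metadata), 8 * 2 * 2)  # group x tissue strata
  probes <- strsplit(meth$dmrs$probes[meth$dmrs$leading_gene == "AR"],
                     ",")[[1]]
  expect_true(length(probes) >= 3 && length(probes) <= 10)
  rep <- selectRepresentativeProbe(probes, meth$beta, meth$positions)
  ids <- meth$metadata$sample[meth$metadata$tissue == "tumor" &
                                meth$metadata$group == "AA"]
  # magnitude 1: noise-free strictly decreasing link
  expect_equal(cor(meth$beta[rep, ids], meth$expression["AR", ids],
                   method = "spearman"), -1)

  # magnitude 0: independent, rho centered at zero over replicates
  rhos <- vapply(1:12, function(s) {
    m0 <- mk(0, 50 + s)
    p0 <- strsplit(m0$dmrs$probes[m0$dmrs$leading_gene == "AR"], ",")[[1]]
    r0 <- selectRepresentativeProbe(p0, m0$beta, m0$positions)
    i0 <- m0$metadata$sample[m0$metadata$tissue == "tumor" &
                               m0$metadata$group == "AA"]
    cor(m0$beta[r0, i0], m0$expression["AR", i0], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)

  # DMR table invariants
  expect_true(all(meth$dmrs$start <= meth$dmrs$end))
  expect_true(all(nchar(meth$dmrs$probes) > 0))
})
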