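test_that("the PPI generator realizes the configured structure exactly", {
  cfg <- simConfig(seed = 1)
  sim <- genPpiNetwork(cfg)
  subs <- allSubinteractomes(sim$network, connectedOnly = TRUE)
  expect_equal(unname(sizeHistogram(subs)), c(63, 30, 40, 27, 6, 11))
  cen <- partnerCensus(sim$network)
  expect_equal(nrow(cen$orfOrfEdges), 8L)
  expect_equal(length(cen$sharedByTwo), 517L)
  expect_setequal(cen$sharedByTwo, sim$ledger$sharedByTwo)
  expect_setequal(cen$sharedByThreePlus, sim$ledger$sharedByThreePlus)
  expect_equal(length(cen$orphanOrfs), 42L)
  expect_setequal(cen$orphanOrfs, sim$ledger$orphans)
  # per-ORF degrees equal the planted sizes
  got <- vapply(subs, subSize, 0L)
  expect_equal(got[names(sim$ledger$sizes)], sim$ledger$sizes)
})

test_that("a sharing-free configuration leaves the shared censuses empty", {
  cfg <- simConfig(seed = 2, nRoster = 30,
                   sizeDistribution = data.frame(min = 1, max = 6,
                                                 count = 25),
                   nOrfOrfEdges = 0, nSharedByTwo = 0,
                   sharedThreePlusPpis = 0)
  sim <- genPpiNetwork(cfg)
  cen <- partnerCensus(sim$network)
  expect_length(cen$sharedByTwo, 0)
  expect_length(cen$sharedByThreePlus, 0)
  expect_equal(nrow(cen$orfOrfEdges), 0L)
})

test_that("infeasible shared-partner demands are rejected", {
  cfg <- simConfig(seed = 3, nRoster = 5,
                   sizeDistribution = data.frame(min = 1, max = 1,
                                                 count = 3),
                   nOrfOrfEdges = 0, nSharedByTwo = 50,
                   sharedThreePlusPpis = 0)
  expect_error(genPpiNetwork(cfg), "infeasible")
})

test_that("hallmark targets are planted exactly", {
  cfg <- simConfig(seed = 4, nRoster = 6,
                   sizeDistribution = data.frame(min = 15, max = 15,
                                                 count = 5),
                   nOrfOrfEdges = 0, nSharedByTwo = 2,
                   sharedThreePlusPpis = 0)
  sim <- genPpiNetwork(cfg)
  orfs <- names(sim$ledger$sizes)
  targets <- setNames(c(2, 0, 4, 2, 0), orfs)
  ann <- genHallmarkAnnotation(sim$network, targets, cfg)
  for (o in orfs) {
    got <- chScore(subinteractome(sim$network, o), ann$annotation)
    expect_equal(got$score, unname(targets[o]))
  }
  # 15 partners at target 2 means exactly 3 flagged partners
  first <- subinteractome(sim$network, orfs[1])
  expect_length(intersect(subPartners(first), ann$annotation), 3L)
  expect_error(
    genHallmarkAnnotation(sim$network, setNames(2.34, orfs[1]), cfg),
    orfs[1])
})

test_that("prevalence-driven annotation scores have the expected median", {
  cfg <- simConfig(seed = 5)
  sim <- genPpiNetwork(cfg)
  ann <- genHallmarkAnnotation(sim$network, cfg = cfg)
  subs <- selectBySize(allSubinteractomes(sim$network, connectedOnly = TRUE))
  pr <- prioritize(chScoreTable(subs, ann$annotation))
  expect_lt(abs(pr$summary$median - 2.8), 0.5)
  expect_equal(pr$summary$n, 103L)
  # the ledger's realized scores match recomputation
  some <- names(ann$ledger$scores)[1:10]
  for (o in some)
    expect_equal(chScore(subinteractome(sim$network, o), ann$annotation,
                         countSelf = FALSE)$score,
                 unname(ann$ledger$scores[o]))
})

test_that("copula expression hits its Spearman targets at n = 2000", {
  cfg <- simConfig(seed = 6, rhoNormal = 0.7, rhoTumor = 0,
                   nSamplesNormal = 2000, nSamplesTumor = 2000)
  ex <- genExpressionPair(cfg)
  vn <- exprValues(ex$normal); vt <- exprValues(ex$tumor)
  rn <- spearmanTest(vn["ORF001", ], vn["PRT00001", ])$rho
  rt <- spearmanTest(vt["ORF001", ], vt["PRT00001", ])$rho
  expect_lt(abs(rn - 0.7), 0.05)
  expect_lt(abs(rt - 0), 0.05)
})

test_that("survival cohorts honor censoring and effect settings", {
  none <- genSurvivalCohort(simConfig(seed = 7, censorFraction = 0))
  expect_true(all(survEvent(none$cohort) == 1))
  some <- genSurvivalCohort(simConfig(seed = 8, censorFraction = 0.3))
  expect_lt(abs(mean(survEvent(some$cohort) == 0) - 0.3), 0.07)
  # the planted high group is recovered by the signature median split
  grp <- splitGroups(signatureScore(some$cohort, c("SIG1", "SIG2", "SIG3")))
  expect_gte(mean((grp == "high") == (some$ledger$trueGroup == 1)), 0.98)
})

test_that("the DE generator plants recoverable blocks", {
  cfg <- simConfig(seed = 9, deMissingFraction = 0)
  sim <- genDeMatrix(cfg)
  # the 100-gene exclusive down block is returned exactly
  expect_setequal(cancerSpecificGenes(sim$dcm, "TGCT", "down"),
                  sprintf("ORF%03d", 69:168))
  # with hidden cells the exclusive set can only shrink within the block
  noisy <- genDeMatrix(simConfig(seed = 10))
  got <- cancerSpecificGenes(noisy$dcm, "TGCT", "down")
  expect_true(all(got %in% sprintf("ORF%03d", 69:178)))
  # a blockless cluster plan yields no pan-cancer group
  fc0 <- genDeMatrix(simConfig(seed = 11), blocks = list())
  expect_equal(nrow(panCancerGroup(fc0$dcm)), 0L)
})

test_that("every generator is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 77)
  expect_identical(genPpiNetwork(cfg), genPpiNetwork(cfg))
  net <- genPpiNetwork(cfg)$network
  expect_identical(genHallmarkAnnotation(net, cfg = cfg),
                   genHallmarkAnnotation(net, cfg = cfg))
  expect_identical(genExpressionPair(cfg), genExpressionPair(cfg))
  expect_identical(genSurvivalCohort(cfg), genSurvivalCohort(cfg))
  expect_identical(genDeMatrix(cfg), genDeMatrix(cfg))
})

test_that("generator calls draw from independent sub-streams", {
  cfg <- simConfig(seed = 78)
  alone <- genSurvivalCohort(cfg)
  withr::local_seed(999)          # unrelated ambient RNG state
  genPpiNetwork(cfg)              # an interleaved call
  after <- genSurvivalCohort(cfg)
  expect_identical(alone, after)
})
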