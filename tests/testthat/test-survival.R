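makeCohort <- function(expr, time, event) {
  SurvivalCohort(expr, time, event)
}

test_that("signature scores aggregate genes as documented", {
  expr <- rbind(G1 = c(1, 2, 3, 4), G2 = c(4, 3, 2, 1),
                G3 = c(0, 5, 10, 15))
  coh <- makeCohort(expr, time = c(5, 6, 7, 8), event = c(1, 1, 0, 1))
  expect_equal(unname(signatureScore(coh, "G1", "mean_raw")),
               c(1, 2, 3, 4))
  # G2 mirrors G1 so their z-scores cancel exactly
  expect_equal(unname(signatureScore(coh, c("G1", "G2"), "mean_z")),
               rep(0, 4))
  # hand-computed z-score means for the 3-gene panel
  z <- apply(expr, 1, function(r) (r - mean(r)) / sd(r))
  expect_equal(unname(signatureScore(coh, c("G1", "G2", "G3"), "mean_z")),
               unname(rowMeans(z)))
  expect_error(signatureScore(coh, "G9"), "G9")
})

test_that("median split sends ties to the low group", {
  expect_equal(as.character(splitGroups(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(table(splitGroups(c(1, 1, 1, 2)))[["low"]], 3L)
  expect_error(splitGroups(rep(2, 6)), "constant")
  expect_error(splitGroups(c(1, 2)), "at least 4")
})

test_that("the product-limit curve matches hand calculation", {
  km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$nRisk, c(3L, 2L, 1L))
  expect_warning(flat <- kmCurve(c(1, 2), c(0, 0)), "no events")
  expect_equal(nrow(flat), 0L)
  expect_equal(kmCurve(5, 1)$survival, 0)
})

test_that("without censoring the KM curve is the empirical survival", {
  withr::local_seed(14)
  time <- rexp(40, 0.1)
  km <- kmCurve(time, rep(1, 40))
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(time > km$time[i]))
})

test_that("KM curve agrees with survival::survfit under censoring", {
  withr::local_seed(3)
  time <- round(rexp(60, 0.1), 1)
  event <- rbinom(60, 1, 0.7)
  km <- kmCurve(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  ref <- summary(sf, times = km$time)
  expect_equal(km$survival, ref$surv, tolerance = 1e-12)
  expect_equal(km$nRisk, ref$n.risk)
})

test_that("survival quantiles are boundary-inclusive first crossings", {
  curve <- data.frame(time = c(10, 20), nRisk = c(5, 3), nEvent = c(2, 1),
                      survival = c(0.6, 0.4))
  expect_equal(quantileSurvival(curve, 0.5), 20)
  expect_equal(quantileSurvival(curve, 0.25), 10)
  high <- data.frame(time = 10, nRisk = 10, nEvent = 1, survival = 0.9)
  expect_true(is.na(quantileSurvival(high, 0.25)))
  exact <- data.frame(time = 12, nRisk = 2, nEvent = 1, survival = 0.5)
  expect_equal(quantileSurvival(exact, 0.5), 12)
  # monotone in q: the 0.75-crossing never comes after the 0.5-crossing
  withr::local_seed(9)
  for (rep in 1:5) {
    km <- kmCurve(rexp(50, 0.1), rbinom(50, 1, 0.8))
    tq <- quantileSurvival(km, 0.25); tm <- quantileSurvival(km, 0.5)
    if (!is.na(tq) && !is.na(tm)) expect_lte(tq, tm)
  }
})

test_that("log-rank ledger matches a hand-computed 6-subject table", {
  # groups: A events at 1, 3; A censored at 4; B events at 2, 5; B censored 6
  time <- c(1, 3, 4, 2, 5, 6)
  event <- c(1, 1, 0, 1, 1, 0)
  group <- factor(c("A", "A", "A", "B", "B", "B"), levels = c("A", "B"))
  # hand ledger over event times 1, 2, 3, 5:
  # t=1: n=6 nA=3 d=1 dA=1 -> E_A += 0.5,  V += 1*(3/6)(3/6)(5/5) = 0.25
  # t=2: n=5 nA=2 d=1 dA=0 -> E_A += 0.4,  V += (2/5)(3/5)(4/4) = 0.24
  # t=3: n=4 nA=2 d=1 dA=1 -> E_A += 0.5,  V += (2/4)(2/4)(3/3) = 0.25
  # t=5: n=2 nA=0 d=1 dA=0 -> E_A += 0,    V += 0
  lr <- logrankTest(time, event, group)
  expect_equal(lr$oLow, 2)
  expect_equal(lr$eLow, 0.5 + 0.4 + 0.5)
  expect_equal(lr$varOE, 0.25 + 0.24 + 0.25)
  expect_equal(lr$chi2, (2 - 1.4)^2 / 0.74)
  expect_equal(lr$p, pchisq((2 - 1.4)^2 / 0.74, 1, lower.tail = FALSE))
  ref <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chi2, ref$chisq, tolerance = 1e-12)
})

test_that("log-rank is null on exchangeable groups and label-symmetric", {
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c("low", "high"), each = 4)
  lr <- logrankTest(time, event, group)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  withr::local_seed(21)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.8)
  g2 <- rep(c("a", "b"), 15)
  swapped <- factor(g2, levels = c("b", "a"))
  expect_equal(logrankTest(t2, e2, g2)$chi2,
               logrankTest(t2, e2, swapped)$chi2)
  expect_error(logrankTest(t2, e2, rep("a", 30)), "two non-empty")
  # invariance under a common monotone transform of time
  expect_equal(logrankTest(t2^2 + 3 * t2, e2, g2)$chi2,
               logrankTest(t2, e2, g2)$chi2)
})

test_that("hazard ratio behaves as an O/E ratio with CI", {
  null <- hazardRatio(5, 5, 7, 7)
  expect_equal(null$hr, 1)
  expect_lt(null$ciLo, 1); expect_gt(null$ciHi, 1)
  hr <- hazardRatio(4, 8, 9, 5)
  inv <- hazardRatio(9, 5, 4, 8)
  expect_equal(inv$hr, 1 / hr$hr)
  expect_true(hr$ciLo <= hr$hr && hr$hr <= hr$ciHi)
  expect_error(hazardRatio(2, 0, 3, 4), "zero expected")
})

test_that("hazard-ratio recovery is within 10% at moderate effect sizes", {
  for (trueHr in c(1, 2)) {
    est <- vapply(1:60, function(s) {
      sim <- genSurvivalCohort(simConfig(seed = 4000 + s, trueHr = trueHr))
      g <- factor(ifelse(sim$ledger$trueGroup == 1, "high", "low"),
                  levels = c("low", "high"))
      lr <- logrankTest(survTime(sim$cohort), survEvent(sim$cohort), g)
      hazardRatio(lr$oLow, lr$eLow, lr$oHigh, lr$eHigh)$hr
    }, 0)
    expect_lt(abs(median(est) - trueHr), 0.1 * trueHr)
  }
})

test_that("the O/E estimate tracks Cox but is attenuated at strong effects", {
  est <- vapply(1:40, function(s) {
    sim <- genSurvivalCohort(simConfig(seed = 7000 + s, trueHr = 3))
    g <- sim$ledger$trueGroup
    tm <- survTime(sim$cohort); ev <- survEvent(sim$cohort)
    gl <- factor(ifelse(g == 1, "high", "low"), levels = c("low", "high"))
    lr <- logrankTest(tm, ev, gl)
    oe <- hazardRatio(lr$oLow, lr$eLow, lr$oHigh, lr$eHigh)$hr
    cox <- exp(survival::coxph(survival::Surv(tm, ev) ~ g)$coef)
    c(oe, cox)
  }, c(0, 0))
  expect_lt(abs(median(est[2, ]) - 3), 0.3)      # Cox is calibrated
  expect_lt(median(est[1, ]), median(est[2, ]))  # O/E shrinks toward 1
  expect_gt(median(est[1, ]), 2.3)               # but stays in its vicinity
})

test_that("signature evaluation composes its parts consistently", {
  sim <- genSurvivalCohort(simConfig(seed = 31))
  res <- evaluateSignature(sim$cohort, c("SIG1", "SIG2", "SIG3"))
  expect_s3_class(res, "SignatureResult")
  expect_true(res$hrCi[1] <= res$hr && res$hr <= res$hrCi[2])
  expect_equal(res$nLow + res$nHigh, 500L)
  # a single-gene signature equals gene-level evaluation
  one <- evaluateSignature(sim$cohort, "SIG1")
  oneRaw <- evaluateSignature(sim$cohort, "SIG1", scoreMethod = "mean_raw")
  expect_equal(one$p, oneRaw$p)   # z-scoring cannot change a median split
})

test_that("a doubled hazard is detected in most replicates at n = 300", {
  sig <- vapply(1:40, function(s) {
    sim <- genSurvivalCohort(simConfig(seed = 5000 + s, trueHr = 2,
                                       nPatients = 300))
    res <- evaluateSignature(sim$cohort, c("SIG1", "SIG2", "SIG3"))
    res$p < 0.05 && res$hr > 1
  }, NA)
  expect_gte(mean(sig), 0.8)
})

test_that("ablation isolates a planted decisive gene", {
  sim <- genSurvivalCohort(simConfig(seed = 61, trueHr = 2.5),
                           signatureGenes = "SIG1")
  panel <- c("SIG1", "NOISE001", "NOISE002")
  for (strat in c("greedy", "exhaustive_k")) {
    ab <- ablation(sim$cohort, panel, strategy = strat)
    expect_true(ab$found)
    expect_equal(ab$decisive, "SIG1")
    expect_gt(ab$pRemaining, 0.05)
    expect_lt(ab$pFull, 0.05)
  }
  # a null cohort has nothing to ablate
  null <- genSurvivalCohort(simConfig(seed = 62, trueHr = 1,
                                      signatureDelta = 0))
  expect_error(ablation(null$cohort, c("SIG1", "SIG2", "SIG3")),
               "not significant")
})
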