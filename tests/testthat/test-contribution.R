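test_that("per-sample contribution follows x beta / y with a zero guard", {
  expect_equal(perSampleContribution(2, 0.5, 4), 0.25)
  expect_equal(perSampleContribution(5, 0, 3), 0)
  expect_equal(perSampleContribution(1, -1, 2), -0.5)
  expect_warning(out <- perSampleContribution(c(1, 1), 1, c(2, 0)),
                 "near-zero")
  expect_equal(out, c(0.5, 0))
})

test_that("aggregation operators match their definitions", {
  expect_equal(meanContribution(c(0.2, 0.4)), 0.3)
  expect_equal(meanContribution(0.7), 0.7)
  expect_error(meanContribution(numeric(0)), "empty")
  expect_equal(regionTotal(c(0.3, -0.2)), 0.5)
  expect_equal(regionTotal(numeric(0)), 0)
  expect_equal(regionTotal(-1.2), 1.2)
  expect_equal(regionFrequencies(c(a = 2, b = 2)), c(a = 0.5, b = 0.5))
  expect_equal(unname(regionFrequencies(c(3, 0, 0))), c(1, 0, 0))
  expect_null(regionFrequencies(c(0, 0)))
})

test_that("contribution entropy has the closed-form values and bounds", {
  expect_equal(contributionEntropy(rep(0.2, 5)), log(5))
  expect_equal(contributionEntropy(c(1, 0, 0, 0)), 0)
  expect_equal(contributionEntropy(c(0.5, 0.5)), log(2))
  set.seed(4)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    p <- runif(k); p <- p / sum(p)
    e <- contributionEntropy(p)
    expect_gte(e, 0)
    expect_lte(e, log(k) + 1e-12)
  }
})

test_that("dense ranking shares ranks on ties and brain-wide set needs all regions", {
  tot <- data.frame(region = rep(c("R1", "R2"), each = 3),
                    tf = rep(c("a", "b", "c"), 2),
                    s = c(5, 3, 3, 1, 2, 3))
  rk <- rankTfs(tot)
  r1 <- rk[rk$region == "R1", ]
  expect_equal(r1$rank[match(c("a", "b", "c"), r1$tf)], c(1L, 2L, 2L))
  # a TF ranked below the cutoff in any region is excluded
  expect_setequal(brainWideTfs(rk, maxRank = 2), c("b", "c"))
  expect_setequal(brainWideTfs(rk, maxRank = 1), character(0))
  tot2 <- tot
  tot2$s[4] <- 10                         # make a rank 1 everywhere
  expect_true("a" %in% brainWideTfs(rankTfs(tot2), maxRank = 1))
})

test_that("fitted models reconstruct expression from stored coefficients", {
  cf <- simulationConfig(nRegions = 2L, nSamplesPerRegion = 15L,
                         nTfs = 8L, nGenes = 30L, tfsPerGene = 2L,
                         noiseSd = 0.2, nLocalizedTfs = 0L)
  ex <- simulateExpression(cf, seed = 13)
  pk <- simulatePeaks(ex$truth, cf, seed = 13)
  cand <- candidateInteractions(pk$peaks, pk$tss)
  st <- collapseReplicates(ex$study)
  fit <- fitRegionModels(st, "GM", cand, seed = 5)
  em <- exprsValues(st)
  for (g in fit$fits$gene[fit$fits$passed]) {
    cfg <- fit$coefs[fit$coefs$gene == g, ]
    a0 <- fit$fits$intercept[fit$fits$gene == g]
    pred <- a0 + colSums(em[cfg$tf, , drop = FALSE] * cfg$beta)
    expect_equal(unname(pred), unname(fit$fitted[[g]]), tolerance = 1e-8)
  }
})

test_that("planted localized TFs concentrate contribution in their region", {
  tot <- expand.grid(region = paste0("R", 1:5), tf = paste0("t", 1:9),
                     stringsAsFactors = FALSE)
  set.seed(6)
  tot$s <- runif(nrow(tot), 9, 11)
  tot$s[tot$tf == "t1" & tot$region == "R3"] <- 30   # concentrated TF
  loc <- localizedTfs(tot)
  expect_true("t1" %in% loc$tf)
  expect_equal(loc$region[loc$tf == "t1"], "R3")
  # a perfectly uniform TF is never selected
  tot$s[tot$tf == "t2"] <- 10
  expect_false("t2" %in% localizedTfs(tot)$tf)
})
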