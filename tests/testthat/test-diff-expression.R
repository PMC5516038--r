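test_that("present filter requires half the samples of some sub-region", {
  st <- tinyStudy(nGenes = 3, nPerSub = 10)
  pm <- presentCalls(st)
  aa <- samplesForRegion(st, "Aa")
  ab <- samplesForRegion(st, "Ab")
  pm["g1", ] <- FALSE; pm["g1", aa[1:6]] <- TRUE        # 60% in Aa
  pm["g2", ] <- FALSE
  pm["g2", aa[1:4]] <- TRUE; pm["g2", ab[1:4]] <- TRUE  # 40% both
  pm["g3", ] <- TRUE
  SummarizedExperiment::assay(st, "present") <- pm
  keep <- dePresentFilter(st, c("Aa", "Ab"))
  expect_true("g1" %in% keep)
  expect_false("g2" %in% keep)
  expect_true("g3" %in% keep)
  expect_error(dePresentFilter(st, "Aa"), "two sub-regions")
})

test_that("EB variance shrinkage recovers planted hyperparameters", {
  set.seed(10)
  d0 <- 8; s02 <- 0.04; df <- 18
  s2 <- s02 * d0 / rchisq(3000, d0) * rchisq(3000, df) / df
  sh <- ebShrinkVar(s2, df)
  expect_equal(sh$d0, d0, tolerance = 0.25)
  expect_equal(sh$s02, s02, tolerance = 0.1)
  # agreement with the reference moderated-statistics implementation
  skip_if_not_installed("limma")
  ref <- limma::squeezeVar(s2[1:500], df)
  sh2 <- ebShrinkVar(s2[1:500], df)
  expect_equal(sh2$d0, ref$df.prior, tolerance = 0.05)
  expect_equal(sh2$s02, ref$var.prior, tolerance = 0.05)
})

test_that("threshold test matches the reference TREAT implementation", {
  skip_if_not_installed("limma")
  set.seed(21)
  nG <- 300; nA <- 8; nB <- 8
  lfc <- c(rnorm(nG / 2, 0, 0.3), rnorm(nG / 2, 1.5, 0.3))
  A <- matrix(rnorm(nG * nA, 8, 0.5), nG, nA) + lfc
  B <- matrix(rnorm(nG * nB, 8, 0.5), nG, nB)
  df <- nA + nB - 2
  s2 <- (rowSums((A - rowMeans(A))^2) + rowSums((B - rowMeans(B))^2)) / df
  sh <- ebShrinkVar(s2, df)
  mine <- treatTest(A, B, tau = log2(1.5), shrink = sh)

  design <- cbind(A = rep(c(1, 0), c(nA, nB)),
                  B = rep(c(0, 1), c(nA, nB)))
  fit <- limma::lmFit(cbind(A, B), design)
  fit <- limma::contrasts.fit(fit, c(1, -1))
  tr <- limma::treat(fit, lfc = log2(1.5))
  expect_equal(mine$log_fc, unname(tr$coefficients[, 1]),
               tolerance = 1e-10)
  expect_equal(mine$p_raw, unname(tr$p.value[, 1]), tolerance = 0.02)
})

test_that("with zero threshold and no moderation the test is an ordinary t-test", {
  set.seed(3)
  A <- matrix(rnorm(50 * 6, 5), 50, 6)
  B <- matrix(rnorm(50 * 6, 5.4), 50, 6)
  mine <- treatTest(A, B, tau = 0, shrink = list(d0 = 0))
  ref <- vapply(1:50, function(i)
    t.test(A[i, ], B[i, ], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(mine$p_raw, ref, tolerance = 1e-10)
})

test_that("at the threshold boundary with vanishing variance p tends to 0.5", {
  tau <- log2(1.5)
  A <- matrix(8 + tau + c(-1, 1) * 1e-7, 1, 4)
  B <- matrix(8 + c(-1, 1) * 1e-7, 1, 4)
  out <- treatTest(A, B, tau = tau)
  expect_equal(out$p_raw, 0.5, tolerance = 1e-3)
})

test_that("pairwise DE runs all contrasts and unions significant genes", {
  cf <- simulationConfig(nRegions = 3L, nSubregions = 3L,
                         nSamplesPerRegion = 30L, nTfs = 5L,
                         nGenes = 60L, fracNullGenes = 0.5,
                         fracDeGenes = 0.5, nLocalizedTfs = 0L)
  ex <- simulateExpression(cf, seed = 17)
  pw <- pairwiseDe(ex$study, "R1")
  expect_equal(length(unique(pw$results$contrast)), choose(3, 2))
  sig <- unique(pw$results$gene[pw$results$significant])
  expect_setequal(pw$union, sig)
  # planted shifted genes are recovered
  expect_gt(mean(ex$truth$de_genes %in% pw$union), 0.8)
  # union monotonicity: the 3-subregion union contains each
  # single-contrast significant set
  for (ct in unique(pw$results$contrast)) {
    sub <- pw$results[pw$results$contrast == ct, ]
    expect_true(all(sub$gene[sub$significant] %in% pw$union))
  }
  # a region with a single sub-region is skipped with a note
  expect_warning(out <- pairwiseDe(ex$study, "R1a"), "sub-regions")
  expect_length(out$union, 0)
})

test_that("localized expression needs significance against every sibling", {
  pw <- list(
    subregions = c("a", "b", "c"),
    union = c("g1", "g2"),
    results = data.frame(
      contrast = rep(c("a-b", "a-c", "b-c"), each = 2),
      gene = rep(c("g1", "g2"), 3),
      log_fc = c(2, 2, 2, 2, 0, 0.1),
      p_raw = 0, p_adj = c(0, 0, 0, 0.5, 0.9, 0.9),
      significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      direction = c("up", "up", "up", "up", "up", "up")))
  le <- localizedExpression(pw)
  expect_true(any(le$gene == "g1" & le$subregion == "a" &
                    le$direction == "up"))
  expect_false("g2" %in% le$gene)        # up vs one, ns vs the other
})
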