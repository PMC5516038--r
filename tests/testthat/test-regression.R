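test_that("TF selection keeps non-zero coefficients up to n_d - 1", {
  expect_equal(selectTfs(c(a = 0.4, b = 0, c = -0.2), nd = 10),
               c("a", "c"))
  beta <- setNames(seq(0.1, 1.2, by = 0.1), paste0("t", sprintf("%02d", 1:12)))
  kept <- selectTfs(beta, nd = 10)
  expect_length(kept, 9)
  expect_false("t01" %in% kept)          # three smallest dropped
  expect_false("t02" %in% kept)
  expect_false("t03" %in% kept)
  expect_equal(selectTfs(c(a = 0, b = 0), nd = 5), character(0))
})

test_that("cross-validated OLS returns per-fold held-out SSEs", {
  set.seed(2)
  n <- 40
  X <- matrix(rnorm(2 * n), n, 2)
  y <- 1 + X %*% c(2, -1)
  sse <- crossValidateOls(X, drop(y), k = 10, seed = 1)
  expect_length(sse, 10)
  expect_true(all(sse < 1e-16))          # exactly linear response

  # zero-column design: intercept-only model, checked by formula
  y2 <- rnorm(n)
  set.seed(5)
  foldid <- sample(rep(1:10, length.out = n))
  sse2 <- crossValidateOls(matrix(0, n, 0), y2, k = 10, seed = 5)
  man <- vapply(1:10, function(f)
    sum((y2[foldid == f] - mean(y2[foldid != f]))^2), numeric(1))
  expect_equal(sse2, man)

  expect_error(crossValidateOls(X, drop(y), k = 50, seed = 1),
               "cannot run")
  expect_identical(crossValidateOls(X, drop(y2), k = 10, seed = 3),
                   crossValidateOls(X, drop(y2), k = 10, seed = 3))
})

test_that("gate test is one-sided with sensible degenerate behavior", {
  expect_lt(gateTest(rep(0, 10), rexp(100) + 1), 1e-6)
  expect_gt(gateTest(rexp(10) + 5, rexp(100)), 0.5)
  expect_equal(gateTest(rep(1, 10), rep(1, 100)), 1)
  expect_equal(gateTest(rep(0, 10), rep(1, 100)), 0)
  # identical distributions: p is uniform-ish, mean near 0.5
  set.seed(11)
  ps <- replicate(200, gateTest(rnorm(10, 5), rnorm(100, 5)))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("BH adjustment matches the step-up arithmetic", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.03), 0.03)
  expect_equal(adjustBH(c(0.001, 1.0)), c(0.002, 1.0))
})

test_that("random models draw the requested SSE count deterministically", {
  set.seed(3)
  n <- 30
  pool <- matrix(rnorm(n * 20), n, 20,
                 dimnames = list(NULL, paste0("g", 1:20)))
  y <- rnorm(n)
  sse <- randomModels(y, pool, nTf = 3, nModels = 10, k = 10, seed = 4)
  expect_length(sse, 100)
  expect_identical(sse, randomModels(y, pool, nTf = 3, nModels = 10,
                                     k = 10, seed = 4))
  expect_error(randomModels(y, pool[, 1:2], nTf = 3), "pool smaller")
})

test_that("robust interactions require presence in every run", {
  mk <- function(pairs, passed) {
    list(fits = data.frame(gene = unique(pairs$gene),
                           passed = unique(pairs$gene) %in% passed),
         coefs = pairs)
  }
  p1 <- data.frame(tf = c("A", "B"), gene = c("g1", "g2"),
                   beta = c(1, 2))
  p2 <- data.frame(tf = "A", gene = "g1", beta = 1.2)
  runs <- c(replicate(4, mk(p1, c("g1", "g2")), simplify = FALSE),
            list(mk(p2, "g1")))
  out <- robustInteractions(runs)
  expect_equal(out$tf, "A")              # B-g2 only in 4/5 runs
  expect_equal(out$gene, "g1")
  expect_equal(out$runs_observed, 5L)
  expect_equal(out$beta_mean, mean(c(1, 1, 1, 1, 1.2)))
  expect_error(robustInteractions(runs[1:3]), "five runs")
  # gate-failing genes contribute nothing
  runs0 <- replicate(5, mk(p1, character(0)), simplify = FALSE)
  expect_equal(nrow(robustInteractions(runs0)), 0)
})

test_that("genes with a single candidate TF skip LASSO but are still gated", {
  ont <- RegionOntology(id = c("GM", "A"), parent = c(NA, "GM"))
  set.seed(8)
  n <- 30
  genes <- c("tf1", paste0("g", 1:10))
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n),
                        donor_id = "d1", region_id = "A",
                        hemisphere = "L",
                        structure_id = sprintf("s%02d", 1:n))
  em <- matrix(rnorm(length(genes) * n, 8, 1), length(genes), n,
               dimnames = list(genes, samples$sample_id))
  em["g1", ] <- 2 + 0.9 * em["tf1", ] + rnorm(n, 0, 0.1)
  pm <- matrix(TRUE, nrow(em), n, dimnames = dimnames(em))
  st <- BrainExpressionStudy(em, pm, samples, ont)
  cand <- data.frame(tf = "tf1", gene = "g1", peak_z = 2.5,
                     tss_distance = 0L)
  fit <- fitRegionModels(st, "A", cand, seed = 2)
  expect_equal(fit$fits$gene, "g1")
  expect_true(is.na(fit$fits$lambda))    # no LASSO with one candidate
  expect_true(fit$fits$passed)
  expect_equal(fit$coefs$tf, "tf1")
  expect_equal(fit$coefs$beta, 0.9, tolerance = 0.1)
})
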