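mkAln <- function(seqs, ss, id = "crs1") {
  methods::new("CRSAlignment", crsId = id, pairs = dotBracketPairs(ss),
               sequences = seqs, human = "human")
}

test_that("dot-bracket parsing and Stockholm round-trip", {
  p <- dotBracketPairs("((..))")
  expect_equal(unname(p), cbind(c(2, 1), c(5, 6))[order(c(2, 1)), ])
  expect_error(dotBracketPairs("(()"), "unbalanced")

  aln <- mkAln(c(human = "GGAAACC", sp01 = "GGAAACC"), "((...))")
  path <- withr::local_tempfile(fileext = ".sto")
  writeStockholm(aln, path)
  back <- readStockholm(path, crsId = "crs1")
  expect_equal(back@sequences, aln@sequences)
  expect_equal(back@pairs, aln@pairs)
})

test_that("fingerprint projection follows the canonical-pair rule", {
  aln <- mkAln(c(human = "AGGCU", spA = "CGGCA", spB = "-GGCU"),
               "(...)")
  expect_equal(projectFingerprint(aln, "human"), 1L)   # A-U canonical
  expect_equal(projectFingerprint(aln, "spA"), 0L)     # C-A mismatch
  expect_equal(projectFingerprint(aln, "spB"), 0L)     # gap
  expect_error(projectFingerprint(aln, "nope"), "absent")
})

test_that("wobble pairs count as canonical, gaps and mismatches do not", {
  # stem of 3: cols 1-3 pair with 8-6
  seqs <- c(human = "GCGAAUGC",  # pairs: (1,8)=G-C, (2,7)=C-G, (3,6)=G-U
            gapsp = "-CGAAUGC",  # (1,8) has a gap
            badsp = "ACGAAUGC")  # (1,8)=A-C non-canonical
  aln <- mkAln(seqs, "(((..)))")
  expect_equal(projectFingerprint(aln, "human"), c(1L, 1L, 1L))
  expect_equal(projectFingerprint(aln, "gapsp"), c(0L, 1L, 1L))
  expect_equal(projectFingerprint(aln, "badsp"), c(0L, 1L, 1L))
})

test_that("fingerprint distance is the normalized Hamming distance", {
  expect_equal(fpDistance(c(1, 1, 1, 1), c(1, 0, 1, 1)), 0.25)
  expect_equal(fpDistance(c(1, 0), c(1, 0)), 0)
  expect_equal(fpDistance(c(1, 0, 1), c(0, 1, 0)), 1)
  expect_error(fpDistance(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("pairwise identity and GC content match their worked examples", {
  expect_equal(pairwiseIdentity(c("AC-GU", "ACCGU")), 1.0)
  expect_equal(pairwiseIdentity(c("ACGU", "ACGU")), 1.0)
  expect_equal(pairwiseIdentity(c("AAAA", "CCCC")), 0.0)
  expect_warning(pairwiseIdentity(c("----", "ACGU")), "all-gap")
  expect_equal(gcContent("AUGC"), 0.5)
  expect_equal(gcContent("AUAU"), 0.0)
  expect_equal(gcContent("GCGC"), 1.0)
  expect_equal(gcContent(c("AU--", "GC")), 0.5)
})

test_that("Fitch parsimony handles base cases and missing species", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  fps <- rbind(a = c(1L, 1L), b = c(1L, 1L), c = c(1L, 1L),
               d = c(1L, 1L))
  expect_equal(fitchParsimony(tree, fps)$raw, 0)
  fps2 <- rbind(a = 1L, b = 1L, c = 0L, d = 0L)
  out <- fitchParsimony(tree, fps2)
  expect_equal(out$raw, 1)
  expect_equal(out$normalized, 1 / (1 * 4))
  # a missing species is pruned without penalty
  out2 <- fitchParsimony(tree, fps2[c("a", "b", "c"), , drop = FALSE],
                         minCoverage = 0.7)
  expect_equal(out2$raw, 1)
  # insufficient fingerprint coverage leaves the score undefined
  out3 <- fitchParsimony(tree, fps2[c("a", "b"), , drop = FALSE])
  expect_true(is.na(out3$raw))
})

test_that("Fitch scores equal brute-force minimum changes on random trees", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    fps <- randomFingerprints(tree, nbp = 3)
    mine <- fitchParsimony(tree, fps, minCoverage = 0)$raw
    oracle <- sum(vapply(1:3, function(b) {
      st <- fps[, b]; names(st) <- rownames(fps)
      bruteForceFitch(tree, st)
    }, numeric(1)))
    expect_equal(mine, oracle)
  }
})

test_that("largest conserved subtree matches the exhaustive clade scan", {
  set.seed(321)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    tree <- ape::rtree(n, tip.label = c("human",
                                        sprintf("s%02d", 1:(n - 1))))
    fps <- randomFingerprints(tree, nbp = 5)
    fps["human", ] <- 1L
    mine <- largestConservedSubtree(tree, fps, theta = 0.45,
                                    coverage = 0.7)
    oracle <- bruteForceSubtree(tree, fps, theta = 0.45, coverage = 0.7)
    expect_equal(mine$size, oracle$size)
    expect_equal(sort(mine$species), sort(oracle$species))
  }
})

test_that("subtree walk returns the root when everything is conserved", {
  tree <- ape::rtree(8, tip.label = c("human", paste0("s", 1:7)))
  fps <- matrix(1L, 8, 4, dimnames = list(tree$tip.label, NULL))
  out <- largestConservedSubtree(tree, fps)
  expect_equal(out$size, 8)
  # and just the human leaf when nothing else is
  fps2 <- fps; fps2[-1, ] <- 0L
  rownames(fps2) <- tree$tip.label
  fps2["human", ] <- 1L
  out2 <- largestConservedSubtree(tree, fps2)
  expect_equal(out2$species, "human")
})

test_that("median parsimony filter is strict and two-subtree", {
  rep <- data.frame(crs_id = c("a", "b", "c", "d"),
                    parsimony_T11 = c(0.1, 0.2, 0.3, 0.4),
                    parsimony_T26 = c(0.1, 0.2, 0.3, 0.4))
  expect_setequal(parsimonyFilter(rep), c("a", "b"))
  repTie <- rep
  repTie$parsimony_T11 <- 0.25            # all equal: strict < fails
  repTie$parsimony_T26 <- 0.25
  expect_length(parsimonyFilter(repTie), 0)
  repMix <- rep
  repMix$parsimony_T26 <- c(0.4, 0.3, 0.2, 0.1)  # discordant subtrees
  expect_length(parsimonyFilter(repMix), 0)
})

test_that("hit validation enforces the projection fraction boundary", {
  ss <- paste0(paste(rep("(", 10), collapse = ""), "....",
               paste(rep(")", 10), collapse = ""))
  stem <- .canonicalPairsFixture(10)
  human <- paste0(stem$left, "AAAA", stem$right)
  aln <- mkAln(c(human = human), ss)
  expect_true(validateHit(aln, human)$kept)
  # break exactly 2 of 10 pairs: fraction 0.8, kept (inclusive)
  broken2 <- human
  substr(broken2, 1, 2) <- "--"
  v <- validateHit(aln, broken2)
  expect_equal(v$fraction, 0.8)
  expect_true(v$kept)
  # 3 of 10 broken: rejected
  broken3 <- human
  substr(broken3, 1, 3) <- "---"
  expect_false(validateHit(aln, broken3)$kept)
  # repeat overlap rejects regardless of projection
  expect_false(validateHit(aln, human, repeatOverlap = TRUE)$kept)
})

test_that("recurrence needs three distinct genes within one stratum", {
  inst <- data.frame(crs_id = "m1", gene = c("g1", "g2", "g3"),
                     category = "ARE")
  expect_equal(recurrenceFilter(inst), "m1")
  inst2 <- data.frame(crs_id = "m2", gene = c("g1", "g1", "g2"),
                      category = "ARE")
  expect_length(recurrenceFilter(inst2), 0)
  inst3 <- data.frame(crs_id = "m3", gene = c("g1", "g2", "g3", "g4"),
                      category = c("ARE", "ARE", "HCE", "HCE"))
  expect_length(recurrenceFilter(inst3), 0)   # 2 + 2 split
  expect_length(recurrenceFilter(inst[0, ]), 0)
})

test_that("motif overlap score and clustering behave as defined", {
  A <- c("s1", "s2", "s3"); B <- c("s2", "s3", "s4", "s5")
  expect_equal(motifOverlap(A, B), 0.5)
  expect_equal(motifOverlap(A, A), 1)
  expect_equal(motifOverlap(A, c("x", "y")), 0)
  expect_equal(motifOverlap(character(0), character(0)), 0)
  sets <- list(m1 = A, m2 = A, m3 = c("q1", "q2"))
  om <- overlapMatrix(sets)
  expect_true(isSymmetric(om))
  expect_true(all(om >= 0 & om <= 1))
  cl <- clusterMotifs(om, cut = 0.5)
  expect_equal(cl$clusters[["m1"]], cl$clusters[["m2"]])
  expect_false(cl$clusters[["m1"]] == cl$clusters[["m3"]])
  # all-zero overlaps: no merges below distance 1
  om0 <- diag(3); dimnames(om0) <- list(letters[1:3], letters[1:3])
  cl0 <- clusterMotifs(om0, cut = 0.99)
  expect_length(unique(cl0$clusters), 3)
})
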