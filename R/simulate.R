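#' Simulation configuration
#'
#' Default study conditions for the synthetic-data generator.  The
#' expression arm emulates a region-ontology-structured microarray
#' study with planted sparse linear TF effects; the structure arm
#' emulates a species phylogeny with conserved and degraded RNA
#' structure alignments.
#'
#' @param nRegions Number of depth-2 brain regions.
#' @param nSubregions Sub-regions (depth 3) per region.
#' @param nDonors Number of donors.
#' @param nSamplesPerRegion Collapsed samples per depth-2 region.
#' @param nReplicates Replicate measurements per collapsed sample.
#' @param nTfs,nGenes Numbers of transcription factors and target genes.
#' @param tfsPerGene Planted regulators per non-null gene.
#' @param effectRange Absolute range of planted coefficients.
#' @param noiseSd Residual standard deviation of gene expression.
#' @param fracNullGenes Fraction of genes with no planted TF effect.
#' @param nLocalizedTfs TFs given region-specific activity.
#' @param regionShift Expression offset of a localized TF inside its
#'   region (log-scale units).
#' @param fracDeGenes Fraction of null genes given planted
#'   between-sub-region shifts.
#' @param deShift Planted sub-region expression shift (log2 units).
#' @param dropout Fraction of absent (present = FALSE) calls.
#' @param jitterSd Replicate jitter standard deviation.
#' @param nDecoyTfs Decoy candidate TFs per gene (survive the peak
#'   filters; the sparse regression must prune them).
#' @param tssWindow,zMin Peak-filter settings mirrored by the decoys.
#' @param enrichedCategory RE category enriched in DE genes.
#' @param enrichmentOddsRatio Planted odds ratio of that enrichment.
#' @param reBackgroundRate RE frequency among non-DE genes.
#' @param fracStructured Fraction of REs overlapped by a CRS interval.
#' @param nSpecies Species count of the synthetic phylogeny.
#' @param nConservedCrs,nDegradedCrs CRS counts by construction.
#' @param nStemPairs Consensus base pairs per CRS.
#' @param loopLength,flankLength Unpaired columns per CRS.
#' @param subRate Per-unit-distance substitution intensity.
#' @param compensatoryRate Probability that a stem substitution is
#'   compensatory (pair-preserving) in a conserved CRS.
#' @param compensatoryRateDegraded Same, for degraded CRSs.
#' @param fracMissingSpecies Fraction of species without a sequence.
#' @return A named list of settings.
#' @export
simulationConfig <- function(nRegions = 5L, nSubregions = 2L, nDonors = 6L,
                             nSamplesPerRegion = 40L, nReplicates = 1L,
                             nTfs = 30L, nGenes = 300L, tfsPerGene = 3L,
                             effectRange = c(0.3, 1), noiseSd = 0.3,
                             fracNullGenes = 0.2, nLocalizedTfs = 3L,
                             regionShift = 4.5, fracDeGenes = 0.5,
                             deShift = 1.2, dropout = 0.02,
                             jitterSd = 0.05, nDecoyTfs = 3L,
                             tssWindow = 10000L, zMin = 1.96,
                             enrichedCategory = "ARE",
                             enrichmentOddsRatio = 6,
                             reBackgroundRate = 0.15,
                             fracStructured = 0.6,
                             nSpecies = 26L, nConservedCrs = 10L,
                             nDegradedCrs = 10L, nStemPairs = 12L,
                             loopLength = 6L, flankLength = 5L,
                             subRate = 0.35, compensatoryRate = 0.95,
                             compensatoryRateDegraded = 0.15,
                             fracMissingSpecies = 0.08) {
  as.list(environment())
}

#' Simulate a regional expression study with planted TF effects
#'
#' TF expression is Gaussian on the log scale with per-region offsets
#' for localized TFs.  Each non-null gene is an intercept plus a sparse
#' linear combination of its planted TFs' (centered) expression plus
#' Gaussian noise; null genes are intercept plus noise.  DE genes (a
#' subset of the null genes, so differential shifts do not confound the
#' planted linear effects) get a fixed shift in one sub-region of every
#' depth-2 region.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed; identical seeds give identical studies.
#' @return A list with elements \code{study}
#'   (\linkS4class{BrainExpressionStudy}) and \code{truth} (planted
#'   interactions, localized TFs, DE genes).
#' @export
simulateExpression <- function(config = simulationConfig(), seed = 1L) {
  set.seed(stageSeed(seed, "expression"))
  cf <- config
  regions <- paste0("R", seq_len(cf$nRegions))
  sub <- unlist(lapply(regions, function(r)
    paste0(r, letters[seq_len(cf$nSubregions)])))
  ont <- RegionOntology(
    id = c("GM", regions, sub),
    parent = c(NA, rep("GM", cf$nRegions),
               rep(regions, each = cf$nSubregions)))

  tfs <- sprintf("TF%02d", seq_len(cf$nTfs))
  genes <- sprintf("G%04d", seq_len(cf$nGenes))

  # collapsed sample layout: per region, samples rotate over
  # sub-regions and donors; structure_id is the replicate key
  samp <- do.call(rbind, lapply(regions, function(r) {
    kids <- paste0(r, letters[seq_len(cf$nSubregions)])
    n <- cf$nSamplesPerRegion
    data.frame(region_id = rep(kids, length.out = n),
               donor_id = paste0("D", rep(seq_len(cf$nDonors),
                                          length.out = n)),
               stringsAsFactors = FALSE)
  }))
  samp$structure_id <- paste0("S", seq_len(nrow(samp)))
  if (cf$nReplicates > 1)
    samp <- samp[rep(seq_len(nrow(samp)), each = cf$nReplicates), ]
  samp$sample_id <- sprintf("SMP%04d", seq_len(nrow(samp)))
  samp$hemisphere <- "L"
  samp <- samp[, c("sample_id", "donor_id", "region_id", "hemisphere",
                   "structure_id")]
  nS <- nrow(samp)
  region2 <- substr(samp$region_id, 1, nchar(samp$region_id) - 1)

  # localized TFs and their regions
  nLoc <- min(cf$nLocalizedTfs, cf$nTfs, cf$nRegions)
  locTfs <- if (nLoc > 0) sample(tfs, nLoc) else character(0)
  locRegions <- if (nLoc > 0) sample(regions, nLoc) else character(0)

  muTf <- stats::rnorm(cf$nTfs, 6, 0.5)
  names(muTf) <- tfs
  X <- matrix(stats::rnorm(cf$nTfs * nS, 0, 1), cf$nTfs, nS,
              dimnames = list(tfs, samp$sample_id))
  X <- X + muTf
  for (i in seq_along(locTfs))
    X[locTfs[i], region2 == locRegions[i]] <-
      X[locTfs[i], region2 == locRegions[i]] + cf$regionShift

  nNull <- round(cf$fracNullGenes * cf$nGenes)
  nullGenes <- if (nNull > 0) sort(sample(genes, nNull)) else character(0)
  modGenes <- setdiff(genes, nullGenes)

  planted <- NULL
  Y <- matrix(0, cf$nGenes, nS, dimnames = list(genes, samp$sample_id))
  intercepts <- stats::rnorm(cf$nGenes, 8, 0.7)
  names(intercepts) <- genes
  for (g in genes) Y[g, ] <- intercepts[g]
  if (length(modGenes)) {
    # balanced regulator assignment: every TF gets a comparable regulon
    pool <- sample(rep(tfs, length.out = length(modGenes) *
                         cf$tfsPerGene))
    plist <- vector("list", length(modGenes))
    for (k in seq_along(modGenes)) {
      g <- modGenes[k]
      gtf <- pool[((k - 1) * cf$tfsPerGene + 1):(k * cf$tfsPerGene)]
      while (anyDuplicated(gtf) > 0)
        gtf[duplicated(gtf)] <- sample(setdiff(tfs, gtf),
                                       sum(duplicated(gtf)))
      beta <- stats::runif(cf$tfsPerGene, cf$effectRange[1],
                           cf$effectRange[2]) *
        sample(c(-1, 1), cf$tfsPerGene, replace = TRUE)
      Y[g, ] <- Y[g, ] + colSums((X[gtf, , drop = FALSE] - muTf[gtf]) * beta)
      plist[[k]] <- data.frame(tf = gtf, gene = g, beta = beta,
                               stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, plist)
  }
  Y <- Y + matrix(stats::rnorm(cf$nGenes * nS, 0, cf$noiseSd),
                  cf$nGenes, nS)

  # planted sub-region shifts in null genes, mirrored in every region
  nDe <- round(cf$fracDeGenes * length(nullGenes))
  deGenes <- if (nDe > 0) sort(sample(nullGenes, nDe)) else character(0)
  deDetail <- NULL
  if (length(deGenes)) {
    dlist <- vector("list", length(deGenes))
    for (k in seq_along(deGenes)) {
      g <- deGenes[k]
      sgn <- sample(c(-1, 1), 1)
      pick <- paste0(regions,
                     sample(letters[seq_len(cf$nSubregions)],
                            cf$nRegions, replace = TRUE))
      Y[g, samp$region_id %in% pick] <-
        Y[g, samp$region_id %in% pick] + sgn * cf$deShift
      dlist[[k]] <- data.frame(gene = g, subregion = paste(pick,
                                                           collapse = ","),
                               shift = sgn * cf$deShift,
                               stringsAsFactors = FALSE)
    }
    deDetail <- do.call(rbind, dlist)
  }

  if (cf$nReplicates > 1) {
    jit <- matrix(stats::rnorm(length(Y), 0, cf$jitterSd), nrow(Y))
    Y <- Y + jit
    X <- X + matrix(stats::rnorm(length(X), 0, cf$jitterSd), nrow(X))
  }

  em <- rbind(X, Y)
  pm <- matrix(stats::runif(length(em)) >= cf$dropout, nrow(em),
               dimnames = dimnames(em))
  pm[tfs, ] <- TRUE

  study <- BrainExpressionStudy(em, pm, samp, ont)
  truth <- list(
    planted = planted,
    tfs = tfs, genes = genes,
    null_genes = nullGenes,
    localized = data.frame(tf = locTfs, region = locRegions,
                           stringsAsFactors = FALSE),
    de_genes = deGenes, de_detail = deDetail)
  list(study = study, truth = truth)
}

#' Simulate scored TF binding-site peaks
#'
#' The synthetic genome has one chromosome per gene with the TSS at a
#' fixed offset.  Every planted interaction gets a high-scoring peak
#' inside the TSS window; every gene additionally gets high-scoring
#' peaks for decoy TFs (candidates the regression must prune), one
#' low-scoring in-window peak (removed by the Z-score filter) and one
#' high-scoring peak just outside the window (removed by the distance
#' filter).  Each TF carries a large background peak set on a decoy
#' chromosome that anchors its score distribution.
#'
#' @param truth Ground truth from \code{\link{simulateExpression}}.
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return A list with \code{peaks} (data.frame: \code{tf},
#'   \code{chrom}, \code{start}, \code{end}, \code{score}) and
#'   \code{tss} (data.frame: \code{gene}, \code{chrom}, \code{pos},
#'   \code{strand}).  Coordinates are 0-based half-open.
#' @export
simulatePeaks <- function(truth, config = simulationConfig(), seed = 1L) {
  set.seed(stageSeed(seed, "peaks"))
  cf <- config
  tssPos <- 100000L
  genes <- truth$genes
  tfs <- truth$tfs
  tss <- data.frame(gene = genes, chrom = paste0("chr_", genes),
                    pos = tssPos, strand = "+", stringsAsFactors = FALSE)

  nBg <- 2000L
  bg <- do.call(rbind, lapply(tfs, function(tf) {
    st <- as.integer(seq(1e6, by = 1000, length.out = nBg))
    data.frame(tf = tf, chrom = "chr_decoy", start = st, end = st + 200L,
               score = stats::rnorm(nBg, 100, 10), stringsAsFactors = FALSE)
  }))

  peakNear <- function(tf, gene, z) {
    offs <- as.integer(round(stats::runif(1, -cf$tssWindow + 300,
                                          cf$tssWindow - 300)))
    st <- tssPos + offs - 100L
    data.frame(tf = tf, chrom = paste0("chr_", gene), start = st,
               end = st + 200L, score = 100 + z * 10,
               stringsAsFactors = FALSE)
  }

  keep <- NULL
  if (!is.null(truth$planted))
    keep <- do.call(rbind, lapply(seq_len(nrow(truth$planted)), function(i)
      peakNear(truth$planted$tf[i], truth$planted$gene[i],
               stats::runif(1, 3.5, 5))))

  decoys <- do.call(rbind, lapply(genes, function(g) {
    pt <- if (is.null(truth$planted)) character(0) else
      truth$planted$tf[truth$planted$gene == g]
    pool <- setdiff(tfs, pt)
    dtf <- sample(pool, min(cf$nDecoyTfs, length(pool)))
    qual <- do.call(rbind, lapply(dtf, function(tf)
      peakNear(tf, g, stats::runif(1, 3.5, 5))))
    low <- peakNear(sample(pool, 1), g, stats::rnorm(1, 0, 0.5))
    farTf <- sample(pool, 1)
    far <- data.frame(tf = farTf, chrom = paste0("chr_", g),
                      start = tssPos + cf$tssWindow + 500L,
                      end = tssPos + cf$tssWindow + 700L,
                      score = 145, stringsAsFactors = FALSE)
    rbind(qual, low, far)
  }))

  list(peaks = rbind(bg, keep, decoys), tss = tss)
}

#' Simulate UTR regulatory-element annotations and CRS intervals
#'
#' Places REs of several categories in gene UTRs.  The configured
#' category is enriched among DE genes at the configured odds ratio; a
#' configurable fraction of REs is overlapped (by at least one
#' nucleotide) by a conserved-RNA-structure interval.
#'
#' @param truth Ground truth from \code{\link{simulateExpression}}.
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return A list with \code{re} (data.frame: \code{gene}, \code{utr},
#'   \code{category}, \code{element}, \code{chrom}, \code{start},
#'   \code{end}) and \code{crs_intervals} (data.frame: \code{crs_id},
#'   \code{chrom}, \code{start}, \code{end}).
#' @export
simulateReAnnotations <- function(truth, config = simulationConfig(),
                                  seed = 1L) {
  set.seed(stageSeed(seed, "re"))
  cf <- config
  genes <- truth$genes
  deGenes <- truth$de_genes
  tssPos <- 100000L
  utr3 <- c(105000L, 106000L)
  utr5 <- c(99500L, 100000L)

  p0 <- cf$reBackgroundRate
  odds1 <- cf$enrichmentOddsRatio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)

  cats <- data.frame(
    category = c("ARE", "RBP", "RBP", "miRNA", "APA", "HCE"),
    element = c("ARE", "RBP:ELAVL1", "RBP:RBM47", "miRNA:miR-96",
                "APA", "HCE"), stringsAsFactors = FALSE)

  rows <- list()
  for (ci in seq_len(nrow(cats))) {
    el <- cats$element[ci]
    enriched <- el == cf$enrichedCategory |
      cats$category[ci] == cf$enrichedCategory
    pDe <- if (enriched) p1 else p0
    pBg <- p0
    for (g in genes) {
      pr <- if (g %in% deGenes) pDe else pBg
      if (stats::runif(1) < pr) {
        u <- if (stats::runif(1) < 0.8) "3p" else "5p"
        lim <- if (u == "3p") utr3 else utr5
        st <- as.integer(round(stats::runif(1, lim[1], lim[2] - 30)))
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, utr = u, category = cats$category[ci], element = el,
          chrom = paste0("chr_", g), start = st, end = st + 25L,
          stringsAsFactors = FALSE)
      }
    }
  }
  # guarantee enough enriched-category DE genes for recurrence search
  guaranteed <- utils::head(deGenes, 5)
  for (g in guaranteed) {
    have <- any(vapply(rows, function(r)
      r$gene == g & r$element == cf$enrichedCategory, logical(1)))
    if (!have)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, utr = "3p", category = cf$enrichedCategory,
        element = cf$enrichedCategory, chrom = paste0("chr_", g),
        start = utr3[1] + 100L, end = utr3[1] + 125L,
        stringsAsFactors = FALSE)
  }
  re <- do.call(rbind, rows)
  rownames(re) <- NULL

  crsIds <- c(sprintf("CRS_C%02d", seq_len(cf$nConservedCrs)),
              sprintf("CRS_D%02d", seq_len(cf$nDegradedCrs)))
  crs <- NULL
  structured <- stats::runif(nrow(re)) < cf$fracStructured
  if (any(structured)) {
    idx <- which(structured)
    crs <- data.frame(
      crs_id = sample(crsIds, length(idx), replace = TRUE),
      chrom = re$chrom[idx],
      # overlap the last nucleotide of the RE at minimum
      start = re$end[idx] - sample(1:20, length(idx), replace = TRUE),
      end = re$end[idx] + 30L, stringsAsFactors = FALSE)
  }
  list(re = re, crs_intervals = crs)
}

# canonical RNA base pairs, wobble included
.canonicalPairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

.randomCanonical <- function(n) {
  sample(.canonicalPairs, n, replace = TRUE)
}

#' Simulate a species phylogeny with conserved and degraded CRSs
#'
#' Builds a random rooted species tree with a designated human leaf and
#' evolves each CRS alignment along it.  In conserved CRSs stem
#' substitutions are mostly compensatory, so base-pair fingerprints stay
#' close to the human fingerprint across the tree; in degraded CRSs
#' stem substitutions mostly break pairs, scattering fingerprint losses
#' over the species.  A fraction of species is omitted entirely
#' (missing sequences).
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return A list with \code{tree} (ape \code{phylo}),
#'   \code{alignments} (list of \linkS4class{CRSAlignment}),
#'   \code{subtrees} (named list of species sets, nested),
#'   \code{conserved} and \code{degraded} (CRS id vectors).
#' @export
simulateStructuralPhylogeny <- function(config = simulationConfig(),
                                        seed = 1L) {
  set.seed(stageSeed(seed, "phylo"))
  cf <- config
  n <- cf$nSpecies
  species <- c("human", sprintf("sp%02d", seq_len(n - 1)))
  tree <- ape::rtree(n, tip.label = sample(species))
  tree$edge.length <- tree$edge.length * 0.6

  d <- ape::cophenetic.phylo(tree)["human", ]
  ord <- names(sort(d))
  subtrees <- list(T11 = sort(ord[seq_len(min(11, n))]),
                   T26 = sort(ord[seq_len(min(26, n))]))

  width <- 2L * cf$nStemPairs + cf$loopLength + 2L * cf$flankLength
  stem5 <- cf$flankLength + seq_len(cf$nStemPairs)
  pairs <- cbind(i = stem5, j = cf$flankLength + cf$nStemPairs +
                   cf$loopLength + (cf$nStemPairs:1))
  unpaired <- setdiff(seq_len(width), c(pairs[, 1], pairs[, 2]))

  makeCrs <- function(id, compRate) {
    human <- character(width)
    bp <- .randomCanonical(cf$nStemPairs)
    human[pairs[, 1]] <- substr(bp, 1, 1)
    human[pairs[, 2]] <- substr(bp, 2, 2)
    human[unpaired] <- sample(c("A", "C", "G", "U"), length(unpaired),
                              replace = TRUE)
    nMiss <- round(cf$fracMissingSpecies * n)
    missing <- if (nMiss > 0)
      sample(setdiff(species, "human"), nMiss) else character(0)
    seqs <- list(human = paste(human, collapse = ""))
    for (sp in setdiff(species, c("human", missing))) {
      p <- 1 - exp(-cf$subRate * d[sp])
      p <- min(p, 0.35)
      s <- human
      # stem evolution: per pair, substitute with prob p
      for (b in seq_len(cf$nStemPairs)) {
        if (stats::runif(1) < p) {
          if (stats::runif(1) < compRate) {
            np <- .randomCanonical(1)
            s[pairs[b, 1]] <- substr(np, 1, 1)
            s[pairs[b, 2]] <- substr(np, 2, 2)
          } else if (stats::runif(1) < 0.5) {
            s[pairs[b, 1]] <- "-"  # gap breaks the pair
          } else {
            q <- s[pairs[b, 2]]
            bad <- c("A", "C", "G", "U")
            bad <- bad[!paste0(bad, q) %in% .canonicalPairs]
            s[pairs[b, 1]] <- sample(bad, 1)  # non-canonical pair
          }
        }
      }
      mut <- stats::runif(length(unpaired)) < p
      s[unpaired[mut]] <- sample(c("A", "C", "G", "U"), sum(mut),
                                 replace = TRUE)
      seqs[[sp]] <- paste(s, collapse = "")
    }
    methods::new("CRSAlignment", crsId = id, pairs = pairs,
                 sequences = unlist(seqs), human = "human")
  }

  conserved <- sprintf("CRS_C%02d", seq_len(cf$nConservedCrs))
  degraded <- sprintf("CRS_D%02d", seq_len(cf$nDegradedCrs))
  alns <- c(lapply(conserved, makeCrs, compRate = cf$compensatoryRate),
            lapply(degraded, makeCrs,
                   compRate = cf$compensatoryRateDegraded))
  names(alns) <- c(conserved, degraded)
  list(tree = tree, alignments = alns, subtrees = subtrees,
       conserved = conserved, degraded = degraded)
}

#' Simulate structure-motif search hits
#'
#' Stands in for a covariance-model search over the UTR sequences of
#' structured REs.  Every conserved CRS receives well-projecting hits in
#' the REs of at least three distinct genes of one category, plus one
#' sub-threshold hit (fewer than 80\% of consensus pairs projectable)
#' and one repeat-overlapping hit that downstream validation must
#' reject.  Degraded CRSs receive hits in only two genes.
#'
#' @param phylo Result of \code{\link{simulateStructuralPhylogeny}}.
#' @param reSim Result of \code{\link{simulateReAnnotations}}.
#' @param truth Ground truth from \code{\link{simulateExpression}}.
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return Data frame with columns \code{crs_id}, \code{gene},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{matched_seq}, \code{repeat_overlap}.
#' @export
simulateSearchHits <- function(phylo, reSim, truth,
                               config = simulationConfig(), seed = 1L) {
  set.seed(stageSeed(seed, "hits"))
  cf <- config
  re <- reSim$re
  cand <- re[re$element == cf$enrichedCategory &
               re$gene %in% truth$de_genes, , drop = FALSE]
  cand <- cand[!duplicated(cand$gene), , drop = FALSE]
  if (nrow(cand) < 3)
    stop("synthetic RE table lacks enough enriched DE genes")

  hitFor <- function(crs, reRow, breakFrac = 0, repeatOverlap = FALSE) {
    aln <- phylo$alignments[[crs]]
    s <- strsplit(unname(aln@sequences[aln@human]), "")[[1]]
    if (breakFrac > 0) {
      nb <- ceiling(breakFrac * nrow(aln@pairs))
      bb <- sample(nrow(aln@pairs), nb)
      s[aln@pairs[bb, 1]] <- "-"
    }
    data.frame(crs_id = crs, gene = reRow$gene, chrom = reRow$chrom,
               start = reRow$start, end = reRow$start +
                 sum(s != "-"), strand = "+",
               matched_seq = paste(s, collapse = ""),
               repeat_overlap = repeatOverlap, stringsAsFactors = FALSE)
  }

  out <- list()
  for (crs in phylo$conserved) {
    ng <- min(nrow(cand), 3 + sample(0:2, 1))
    pick <- cand[sample(nrow(cand), ng), , drop = FALSE]
    for (i in seq_len(nrow(pick)))
      out[[length(out) + 1]] <- hitFor(crs, pick[i, ])
    out[[length(out) + 1]] <- hitFor(crs, cand[sample(nrow(cand), 1), ],
                                     breakFrac = 0.3)
    out[[length(out) + 1]] <- hitFor(crs, cand[sample(nrow(cand), 1), ],
                                     repeatOverlap = TRUE)
  }
  for (crs in phylo$degraded) {
    pick <- cand[sample(nrow(cand), 2), , drop = FALSE]
    for (i in seq_len(nrow(pick)))
      out[[length(out) + 1]] <- hitFor(crs, pick[i, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate every pipeline input and write it to disk
#'
#' Runs all generator arms under one seed and writes the plain-file
#' formats the pipeline reads: study TSV/JSON, peak and TSS tables, RE
#' and CRS-interval tables, Newick tree, Stockholm alignments, subtree
#' species lists, the search-hit table and \code{ground_truth.json}.
#'
#' @param dir Output directory.
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return Invisibly, a list with all in-memory simulation objects.
#' @export
simulateAll <- function(dir, config = simulationConfig(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- simulateExpression(config, seed)
  writeStudy(ex$study, dir)
  pk <- simulatePeaks(ex$truth, config, seed)
  writeTsv(pk$peaks, file.path(dir, "peaks.tsv"))
  writeTsv(pk$tss, file.path(dir, "tss.tsv"))
  reSim <- simulateReAnnotations(ex$truth, config, seed)
  writeTsv(reSim$re, file.path(dir, "re.tsv"))
  if (!is.null(reSim$crs_intervals))
    writeTsv(reSim$crs_intervals, file.path(dir, "crs_intervals.tsv"))
  phylo <- simulateStructuralPhylogeny(config, seed)
  ape::write.tree(phylo$tree, file.path(dir, "species.nwk"))
  alnDir <- file.path(dir, "alignments")
  dir.create(alnDir, showWarnings = FALSE)
  for (aln in phylo$alignments)
    writeStockholm(aln, file.path(alnDir, paste0(aln@crsId, ".sto")))
  jsonlite::write_json(phylo$subtrees, file.path(dir, "subtrees.json"))
  hits <- simulateSearchHits(phylo, reSim, ex$truth, config, seed)
  writeTsv(hits, file.path(dir, "hits.tsv"))
  gt <- list(planted = ex$truth$planted, localized = ex$truth$localized,
             de_genes = ex$truth$de_genes,
             null_genes = ex$truth$null_genes,
             conserved_crs = phylo$conserved,
             degraded_crs = phylo$degraded)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", na = "null")
  invisible(list(study = ex$study, truth = ex$truth, peaks = pk,
                 re = reSim, phylo = phylo, hits = hits))
}
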