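#' Pipeline configuration
#'
#' All thresholds of the analysis in one place, with the defaults used
#' throughout: peak Z cutoff 1.96, TSS window 10 kb, 10 CV folds, 10
#' random models, gate/DE/enrichment alpha 0.05, fold-change threshold
#' log2(1.5), 20-sample region eligibility, fingerprint theta 0.2,
#' subtree coverage 0.8, projection fraction 0.8, 3-gene recurrence,
#' GC bounds 0.2-0.8, identity < 0.95.
#'
#' @param simulation A \code{\link{simulationConfig}}.
#' @param runs Number of independent analysis runs (default 5).
#' @param regressionRegions Regions to fit models in; NULL = ontology
#'   root (one brain-wide fit whose contributions are then evaluated
#'   per region).
#' @param contributionDepth Ontology depth for contribution, entropy
#'   and localization summaries (default 2).
#' @param minRegionSamples Region eligibility threshold.
#' @param folds,nRandom,zMin,tssWindow,alpha,tau,nMc,minGenes,theta,
#'   subtreeCoverage,projectionFraction,minRecurrenceGenes,gcBounds,
#'   maxIdentity,clusterCut,maxRank Stage thresholds (see Details).
#' @return Named list of settings.
#' @export
pipelineConfig <- function(simulation = simulationConfig(), runs = 5L,
                           regressionRegions = NULL,
                           contributionDepth = 2L,
                           minRegionSamples = 20L, folds = 10L,
                           nRandom = 10L, zMin = 1.96,
                           tssWindow = 10000L, alpha = 0.05,
                           tau = log2(1.5), nMc = 1e4, minGenes = 10L,
                           theta = 0.2, subtreeCoverage = 0.8,
                           projectionFraction = 0.8,
                           minRecurrenceGenes = 3L,
                           gcBounds = c(0.2, 0.8), maxIdentity = 0.95,
                           clusterCut = 0.5, maxRank = 20L) {
  as.list(environment())
}

# deterministic number formatting for report files
.reportTsv <- function(df, path, digits = 12) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmtNum, digits = digits)
  writeTsv(df, path)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Generates all inputs under \code{outDir/input}, then executes the
#' stages in order: candidate derivation, gated regression over the
#' run-seed list, robust-interaction intersection, contribution /
#' entropy / localization summaries, pairwise differential expression,
#' RE enrichment, and the structure-motif conservation pipeline.
#' Report TSVs are written under \code{outDir}; identical configuration
#' and seed give byte-identical reports.
#'
#' @param outDir Output directory.
#' @param config A \code{\link{pipelineConfig}}.
#' @param seed Integer base seed.
#' @return Invisibly, a list with all stage results.
#' @export
runAll <- function(outDir, config = pipelineConfig(), seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inDir <- file.path(outDir, "input")
  simulateAll(inDir, config$simulation, seed)

  manifest <- list(seed = seed, runs = config$runs,
                   seeds = runSeeds(seed, config$runs))
  inputs <- list.files(inDir, recursive = TRUE, full.names = TRUE)
  manifest$input_digests <- as.list(tools::md5sum(inputs))
  names(manifest$input_digests) <- list.files(inDir, recursive = TRUE)

  study <- collapseReplicates(loadStudy(
    file.path(inDir, "expression.tsv"), file.path(inDir, "present.tsv"),
    file.path(inDir, "samples.tsv"), file.path(inDir, "ontology.json")))
  ont <- studyOntology(study)

  peaks <- readTsv(file.path(inDir, "peaks.tsv"))
  tss <- readTsv(file.path(inDir, "tss.tsv"))
  cand <- candidateInteractions(peaks, tss, config$zMin,
                                config$tssWindow)
  .reportTsv(cand, file.path(outDir, "candidates.tsv"))

  regions <- config$regressionRegions
  if (is.null(regions)) regions <- rootRegion(ont)
  eligible <- eligibleRegions(study, config$minRegionSamples)
  regions <- intersect(regions, eligible)
  seeds <- manifest$seeds

  runsByRegion <- lapply(regions, function(r) {
    lapply(seeds, function(s)
      fitRegionModels(study, r, cand, seed = s, k = config$folds,
                      nRandom = config$nRandom, alpha = config$alpha))
  })
  names(runsByRegion) <- regions

  fitRows <- do.call(rbind, unlist(lapply(regions, function(r)
    lapply(runsByRegion[[r]], function(run)
      cbind(region = r, run_seed = run$seed, run$fits))),
    recursive = FALSE))
  .reportTsv(fitRows, file.path(outDir, "gene_fits.tsv"))

  robust <- do.call(rbind, lapply(regions, function(r) {
    ri <- robustInteractions(runsByRegion[[r]],
                             allowFewer = config$runs < 5)
    if (nrow(ri)) cbind(region = r, ri) else NULL
  }))
  if (is.null(robust))
    robust <- data.frame(region = character(0), tf = character(0),
                         gene = character(0), beta_mean = numeric(0),
                         runs_observed = integer(0))
  .reportTsv(robust, file.path(outDir, "interactions.tsv"))

  # contributions: evaluate every fitted model over the regions at the
  # summary depth, per run, then average totals over runs
  depthRegions <- regionsAtDepth(ont, config$contributionDepth)
  contribRuns <- lapply(seq_along(seeds), function(i) {
    tot <- do.call(rbind, lapply(regions, function(r)
      contributionTable(study, runsByRegion[[r]][[i]],
                        regions = depthRegions)$totals))
    if (is.null(tot)) return(NULL)
    stats::aggregate(s ~ region + tf, data = tot, FUN = sum)
  })
  contribRuns <- contribRuns[!vapply(contribRuns, is.null, logical(1))]
  if (length(contribRuns)) {
    allTot <- do.call(rbind, contribRuns)
    meanTot <- stats::aggregate(s ~ region + tf, data = allTot,
                                FUN = function(v) sum(v) /
                                  length(contribRuns))
    ranked <- rankTfs(meanTot)
    .reportTsv(ranked[order(ranked$region, ranked$rank, ranked$tf), ],
               file.path(outDir, "region_totals.tsv"))
    et <- entropyTable(meanTot)
    loc <- localizedTfs(meanTot)
    et$localized <- et$tf %in% loc$tf
    .reportTsv(et[order(et$e), ], file.path(outDir, "entropy.tsv"))
    bw <- brainWideTfs(ranked, config$maxRank)
    writeLines(bw, file.path(outDir, "brain_wide_tfs.txt"))
  } else {
    meanTot <- NULL
    loc <- NULL
  }

  # differential expression between sibling sub-regions
  deParents <- ont@nodes$id[vapply(ont@nodes$id, function(r) {
    k <- length(regionChildren(ont, r))
    k >= 2 && k <= 5
  }, logical(1))]
  deRes <- lapply(deParents, function(r)
    pairwiseDe(study, r, tau = config$tau, alpha = config$alpha))
  names(deRes) <- deParents
  deTab <- do.call(rbind, lapply(deParents, function(r) {
    x <- deRes[[r]]$results
    if (is.null(x)) return(NULL)
    cbind(region = r, x)
  }))
  if (!is.null(deTab))
    .reportTsv(deTab[deTab$significant, , drop = FALSE],
               file.path(outDir, "de_results.tsv"))
  deUnion <- do.call(rbind, lapply(deParents, function(r) {
    u <- deRes[[r]]$union
    if (length(u)) data.frame(region = r, gene = u) else NULL
  }))
  if (is.null(deUnion))
    deUnion <- data.frame(region = character(0), gene = character(0))
  .reportTsv(deUnion, file.path(outDir, "de_union.tsv"))
  locExpr <- do.call(rbind, lapply(deParents, function(r) {
    le <- localizedExpression(deRes[[r]])
    if (nrow(le)) cbind(region = r, le) else NULL
  }))
  if (!is.null(locExpr))
    .reportTsv(locExpr, file.path(outDir, "localized_expression.tsv"))

  # RE enrichment per region
  re <- readTsv(file.path(inDir, "re.tsv"))
  crsIv <- tryCatch(readTsv(file.path(inDir, "crs_intervals.tsv")),
                    error = function(e) NULL)
  re <- flagStructured(re, crsIv)
  background <- sort(setdiff(rownames(study), unique(cand$tf)))
  enr <- do.call(rbind, lapply(deParents, function(r) {
    u <- deRes[[r]]$union
    runRegionEnrichment(u, background, re, region = r,
                        nMc = config$nMc, alpha = config$alpha,
                        minGenes = config$minGenes,
                        seed = stageSeed(seed, "enrichment"))
  }))
  .reportTsv(enr, file.path(outDir, "enrichment.tsv"))

  motifs <- runMotifAnalysis(inDir, deUnion = deUnion, re = re,
                             enrichment = enr, config = config)
  .reportTsv(motifs$reports, file.path(outDir, "motif_reports.tsv"))
  writeLines(motifs$selected, file.path(outDir, "motif_selected.txt"))
  if (!is.null(motifs$overlap)) {
    om <- data.frame(crs_id = rownames(motifs$overlap),
                     motifs$overlap, check.names = FALSE)
    .reportTsv(om, file.path(outDir, "overlap_matrix.tsv"))
    writeLines(paste(names(motifs$clusters), motifs$clusters,
                     sep = "\t"),
               file.path(outDir, "motif_clusters.tsv"))
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, candidates = cand,
                 runsByRegion = runsByRegion, robust = robust,
                 totals = meanTot, localized = loc, de = deRes,
                 enrichment = enr, motifs = motifs))
}

#' Structure-motif conservation analysis over a simulated input set
#'
#' Reads the species tree, subtree definitions, CRS alignments and the
#' search-hit table from \code{inDir}; computes conservation reports,
#' applies the GC / identity / parsimony filters, validates hits,
#' annotates instances with RE categories and DE regions, applies the
#' recurrence rule and clusters the selected motifs by instance
#' overlap.
#'
#' @param inDir Input directory (as written by \code{\link{simulateAll}}).
#' @param deUnion Data frame \code{region}, \code{gene} of DE calls.
#' @param re Structured-flagged RE table.
#' @param enrichment Enrichment result table (may be empty).
#' @param config A \code{\link{pipelineConfig}}.
#' @return List with \code{reports}, \code{passSequence},
#'   \code{passParsimony}, \code{recurring}, \code{selected},
#'   \code{instances}, \code{overlap}, \code{clusters}.
#' @export
runMotifAnalysis <- function(inDir, deUnion, re, enrichment = NULL,
                             config = pipelineConfig()) {
  tree <- ape::read.tree(file.path(inDir, "species.nwk"))
  subtrees <- jsonlite::fromJSON(file.path(inDir, "subtrees.json"))
  alnFiles <- list.files(file.path(inDir, "alignments"),
                         pattern = "\\.sto$", full.names = TRUE)
  alns <- lapply(alnFiles, readStockholm)
  names(alns) <- vapply(alns, function(a) a@crsId, character(1))

  reports <- do.call(rbind, lapply(alns, function(a)
    subtreeReport(a, tree, subtrees, theta = config$theta,
                  coverage = config$subtreeCoverage)))
  rownames(reports) <- NULL
  passSeq <- reports$crs_id[sequenceFilters(reports, config$gcBounds,
                                            config$maxIdentity)]
  passPars <- parsimonyFilter(reports)

  hits <- readTsv(file.path(inDir, "hits.tsv"))
  inst <- NULL
  if (nrow(hits)) {
    kept <- vapply(seq_len(nrow(hits)), function(i) {
      a <- alns[[hits$crs_id[i]]]
      if (is.null(a)) return(FALSE)
      validateHit(a, hits$matched_seq[i],
                  repeatOverlap = isTRUE(hits$repeat_overlap[i]) |
                    hits$repeat_overlap[i] == "TRUE",
                  minFraction = config$projectionFraction)$kept
    }, logical(1))
    hv <- hits[kept, , drop = FALSE]
    if (nrow(hv)) {
      # category: RE(s) of the same gene overlapping the hit interval
      inst <- do.call(rbind, lapply(seq_len(nrow(hv)), function(i) {
        rr <- re[re$gene == hv$gene[i] & re$chrom == hv$chrom[i] &
                   re$start < hv$end[i] & re$end > hv$start[i], ,
                 drop = FALSE]
        if (nrow(rr) == 0) return(NULL)
        data.frame(crs_id = hv$crs_id[i], gene = hv$gene[i],
                   category = unique(rr$element),
                   key = paste0(hv$chrom[i], ":", hv$start[i], "-",
                                hv$end[i], ":", hv$strand[i]),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  recurring <- character(0)
  if (!is.null(inst) && nrow(inst)) {
    # stratify by DE region: an instance counts where its gene is DE
    instR <- merge(inst, deUnion, by = "gene")
    recurring <- recurrenceFilter(instR, config$minRecurrenceGenes)
  }
  selected <- sort(Reduce(intersect,
                          list(passSeq, passPars, recurring)))

  overlap <- NULL
  clusters <- NULL
  if (!is.null(inst) && length(selected) >= 1) {
    sets <- lapply(selected, function(id)
      unique(inst$key[inst$crs_id == id]))
    names(sets) <- selected
    overlap <- overlapMatrix(sets)
    clusters <- clusterMotifs(overlap, config$clusterCut)$clusters
  }
  list(reports = reports, passSequence = passSeq,
       passParsimony = passPars, recurring = recurring,
       selected = selected, instances = inst, overlap = overlap,
       clusters = clusters)
}
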