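#' Construct a BrainExpressionStudy
#'
#' @param exprs Numeric matrix, genes x samples, log-scale expression.
#' @param present Logical matrix of present calls, same dimensions.
#' @param samples \code{data.frame} with columns \code{sample_id},
#'   \code{donor_id}, \code{region_id}, \code{hemisphere} and optionally
#'   \code{structure_id} (the replicate grouping key; defaults to
#'   \code{region_id}).
#' @param ontology A \linkS4class{RegionOntology}.
#' @return A \linkS4class{BrainExpressionStudy}.
#' @export
BrainExpressionStudy <- function(exprs, present, samples, ontology) {
  if (is.null(samples$structure_id)) samples$structure_id <- samples$region_id
  cd <- S4Vectors::DataFrame(samples)
  rownames(cd) <- samples$sample_id
  colnames(exprs) <- samples$sample_id
  colnames(present) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs, present = present), colData = cd)
  methods::new("BrainExpressionStudy", se, ontology = ontology)
}

#' Study accessors
#'
#' @param study A \linkS4class{BrainExpressionStudy}.
#' @return \code{exprsValues}: genes x samples numeric matrix;
#'   \code{presentCalls}: logical matrix; \code{sampleData}: plain
#'   \code{data.frame} of sample annotation; \code{studyOntology}: the
#'   \linkS4class{RegionOntology}.
#' @name study-accessors
NULL

#' @rdname study-accessors
#' @export
exprsValues <- function(study) {
  SummarizedExperiment::assay(study, "exprs")
}

#' @rdname study-accessors
#' @export
presentCalls <- function(study) {
  SummarizedExperiment::assay(study, "present")
}

#' @rdname study-accessors
#' @export
sampleData <- function(study) {
  as.data.frame(SummarizedExperiment::colData(study))
}

#' @rdname study-accessors
#' @export
studyOntology <- function(study) {
  study@ontology
}

#' Load an expression study from plain files
#'
#' Expression and present-call matrices are TSV with samples as rows and
#' genes as columns (first column = sample id); the sample sheet is a
#' TSV with columns \code{sample_id}, \code{donor_id}, \code{region_id},
#' \code{hemisphere} and optionally \code{structure_id}; the ontology is
#' JSON.  Only left-hemisphere samples are retained (hemisphere
#' \code{"L"}), mirroring the donor-bias control of the source atlas.
#'
#' @param exprsPath,presentPath,samplesPath,ontologyPath File paths.
#' @return A \linkS4class{BrainExpressionStudy} restricted to
#'   left-hemisphere samples.
#' @export
loadStudy <- function(exprsPath, presentPath, samplesPath, ontologyPath) {
  ont <- readOntology(ontologyPath)
  sheet <- readTsv(samplesPath)
  ev <- readTsv(exprsPath)
  pv <- readTsv(presentPath)
  em <- as.matrix(ev[, -1, drop = FALSE])
  rownames(em) <- ev[[1]]
  pm <- as.matrix(pv[, -1, drop = FALSE]) > 0
  rownames(pm) <- pv[[1]]
  if (!identical(dim(em), dim(pm)) ||
      !identical(rownames(em), rownames(pm)) ||
      !identical(colnames(em), colnames(pm)))
    stop("expression and present-call matrices are inconsistent")
  if (!setequal(rownames(em), sheet$sample_id))
    stop("sample sheet does not match expression matrix rows")
  sheet <- sheet[match(rownames(em), sheet$sample_id), ]
  bad <- setdiff(unique(sheet$region_id), ont@nodes$id)
  if (length(bad))
    stop("sample region not in ontology: ", paste(bad, collapse = ", "))
  keep <- sheet$hemisphere == "L"
  sheet <- sheet[keep, , drop = FALSE]
  BrainExpressionStudy(exprs = t(em[keep, , drop = FALSE]),
                       present = t(pm[keep, , drop = FALSE]),
                       samples = sheet, ontology = ont)
}

#' Write an expression study to plain files
#'
#' Inverse of \code{\link{loadStudy}}; TSV round-trips reproduce values
#' exactly via full-precision formatting.
#'
#' @param study A \linkS4class{BrainExpressionStudy}.
#' @param dir Output directory; files \code{expression.tsv},
#'   \code{present.tsv}, \code{samples.tsv} and \code{ontology.json} are
#'   created.
#' @return The directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  em <- t(exprsValues(study))
  pm <- t(presentCalls(study))
  writeTsv(data.frame(sample_id = rownames(em),
                      as.data.frame(em, check.names = FALSE),
                      check.names = FALSE),
           file.path(dir, "expression.tsv"))
  writeTsv(data.frame(sample_id = rownames(pm),
                      as.data.frame(pm + 0L, check.names = FALSE),
                      check.names = FALSE),
           file.path(dir, "present.tsv"))
  writeTsv(sampleData(study), file.path(dir, "samples.tsv"))
  writeOntology(study@ontology, file.path(dir, "ontology.json"))
  invisible(dir)
}

#' Samples belonging to a region
#'
#' A sample belongs to a region if its annotated region is that region
#' or any of its descendants in the ontology, so coarse regions pool all
#' their sub-region samples.
#'
#' @param study A \linkS4class{BrainExpressionStudy}.
#' @param region A region identifier.
#' @return Character vector of sample ids.
#' @export
samplesForRegion <- function(study, region) {
  ids <- regionDescendants(study@ontology, region)
  cd <- sampleData(study)
  cd$sample_id[cd$region_id %in% ids]
}

#' Subset a study to the samples of one region
#'
#' @param study A \linkS4class{BrainExpressionStudy}.
#' @param region A region identifier.
#' @return The study restricted to the region's samples.
#' @export
regionStudy <- function(study, region) {
  study[, samplesForRegion(study, region)]
}

#' Regions with enough collapsed samples
#'
#' Returns the regions whose replicate-collapsed sample count (summed
#' over all donors and descendant sub-regions) reaches
#' \code{minSamples}.  The default of 20 guarantees held-out test sets
#' of two or more samples under 10-fold cross-validation.
#'
#' @param study A \linkS4class{BrainExpressionStudy} (uncollapsed is
#'   fine; counts are computed after collapsing).
#' @param minSamples Minimum collapsed sample count (default 20).
#' @return Character vector of region ids.
#' @export
eligibleRegions <- function(study, minSamples = 20L) {
  cd <- sampleData(study)
  groups <- unique(cd[, c("donor_id", "structure_id", "region_id")])
  nd <- study@ontology@nodes
  keep <- vapply(nd$id, function(r) {
    ids <- regionDescendants(study@ontology, r)
    sum(groups$region_id %in% ids) >= minSamples
  }, logical(1))
  nd$id[keep]
}

#' Collapse replicated samples by their median
#'
#' Samples sharing the same (donor, anatomical structure) key are
#' collapsed to one sample per group using the per-gene median; a
#' collapsed present call is TRUE when at least half of the members were
#' present (majority rule).  Idempotent: collapsing a collapsed study is
#' a no-op.
#'
#' @param study A \linkS4class{BrainExpressionStudy}.
#' @return A collapsed \linkS4class{BrainExpressionStudy}.
#' @export
collapseReplicates <- function(study) {
  cd <- sampleData(study)
  key <- paste(cd$donor_id, cd$structure_id, sep = "\r")
  first <- !duplicated(key)
  if (all(table(key) == 1)) return(study)
  em <- exprsValues(study)
  pm <- presentCalls(study)
  ukey <- key[first]
  newE <- matrix(NA_real_, nrow(em), length(ukey),
                 dimnames = list(rownames(em), cd$sample_id[first]))
  newP <- matrix(FALSE, nrow(em), length(ukey),
                 dimnames = dimnames(newE))
  for (i in seq_along(ukey)) {
    idx <- which(key == ukey[i])
    if (length(idx) == 1) {
      newE[, i] <- em[, idx]
      newP[, i] <- pm[, idx]
    } else {
      newE[, i] <- matrixStats_rowMedians(em[, idx, drop = FALSE])
      newP[, i] <- rowMeans(pm[, idx, drop = FALSE]) >= 0.5
    }
  }
  BrainExpressionStudy(newE, newP, cd[first, , drop = FALSE],
                       study@ontology)
}

# Row medians without extra dependencies; median of an even-sized set is
# the mean of the two central values.
matrixStats_rowMedians <- function(m) {
  apply(m, 1, stats::median)
}

#' Collapse probes mapping to the same gene
#'
#' Probes that refer to the same gene are collapsed by the per-sample
#' median of their expression; present calls by majority.
#'
#' @param study A \linkS4class{BrainExpressionStudy} whose rows are
#'   probes.
#' @param probeToGene Named character vector mapping probe id to gene
#'   id; probes without a mapping are dropped.
#' @return A \linkS4class{BrainExpressionStudy} whose rows are genes.
#' @export
collapseProbes <- function(study, probeToGene) {
  em <- exprsValues(study)
  pm <- presentCalls(study)
  gene <- probeToGene[rownames(em)]
  keep <- !is.na(gene)
  em <- em[keep, , drop = FALSE]
  pm <- pm[keep, , drop = FALSE]
  gene <- gene[keep]
  ug <- unique(gene)
  newE <- matrix(NA_real_, length(ug), ncol(em),
                 dimnames = list(ug, colnames(em)))
  newP <- matrix(FALSE, length(ug), ncol(em), dimnames = dimnames(newE))
  for (i in seq_along(ug)) {
    idx <- which(gene == ug[i])
    if (length(idx) == 1) {
      newE[i, ] <- em[idx, ]
      newP[i, ] <- pm[idx, ]
    } else {
      newE[i, ] <- apply(em[idx, , drop = FALSE], 2, stats::median)
      newP[i, ] <- colMeans(pm[idx, , drop = FALSE]) >= 0.5
    }
  }
  BrainExpressionStudy(newE, newP, sampleData(study), study@ontology)
}
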