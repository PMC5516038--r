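#' Filter binding-site peaks by per-TF Z-score
#'
#' Peak cluster scores are standardized separately for each TF
#' ((score - mean) / sd) and only peaks reaching \code{zMin} are kept.
#' A TF with fewer than two peaks (or zero score spread) has no defined
#' standard deviation and is skipped with a warning.
#'
#' @param peaks Data frame with columns \code{tf}, \code{chrom},
#'   \code{start}, \code{end}, \code{score}.
#' @param zMin Z-score cutoff (default 1.96).
#' @return The filtered peak table with an added \code{z} column.
#' @export
zscoreFilter <- function(peaks, zMin = 1.96) {
  out <- lapply(split(peaks, peaks$tf), function(p) {
    if (nrow(p) < 2) {
      warning("TF ", p$tf[1], " has a single peak; skipped", call. = FALSE)
      return(NULL)
    }
    s <- stats::sd(p$score)
    if (s == 0) {
      warning("TF ", p$tf[1], " has zero score spread; skipped",
              call. = FALSE)
      return(NULL)
    }
    p$z <- (p$score - mean(p$score)) / s
    p[p$z >= zMin, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- cbind(peaks[0, , drop = FALSE], z = numeric(0))
  rownames(res) <- NULL
  res
}

#' Assign filtered peaks to genes by TSS distance
#'
#' A (TF, gene) candidate pair is emitted when any nucleotide of a peak
#' lies within \code{window} nucleotides of the gene's transcription
#' start site (inclusive on both sides).  Duplicate pairs are collapsed
#' keeping the maximum peak Z-score.
#'
#' @param peaks Z-filtered peak table from \code{\link{zscoreFilter}}
#'   (0-based half-open coordinates).
#' @param tss Data frame with columns \code{gene}, \code{chrom},
#'   \code{pos} (0-based TSS position), \code{strand}.
#' @param window Window half-width in nucleotides (default 10000).
#' @return Data frame of candidate interactions: \code{tf}, \code{gene},
#'   \code{peak_z}, \code{tss_distance} (signed, peak edge nearest the
#'   TSS).
#' @export
assignToGenes <- function(peaks, tss, window = 10000L) {
  if (is.null(peaks) || nrow(peaks) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      peak_z = numeric(0), tss_distance = integer(0)))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L,
                                                peaks$end))
  # TSS position pos covers nucleotides [pos - window, pos + window]
  win <- GenomicRanges::GRanges(tss$chrom,
                                IRanges::IRanges(tss$pos - window + 1L,
                                                 tss$pos + window + 1L))
  ov <- GenomicRanges::findOverlaps(pk, win)
  if (length(ov) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      peak_z = numeric(0), tss_distance = integer(0)))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  dist <- vapply(seq_along(qi), function(k) {
    p0 <- peaks$start[qi[k]]
    p1 <- peaks$end[qi[k]] - 1L  # last covered nucleotide
    t0 <- tss$pos[si[k]]
    if (p1 < t0) p1 - t0 else if (p0 > t0) p0 - t0 else 0L
  }, integer(1))
  cand <- data.frame(tf = peaks$tf[qi], gene = tss$gene[si],
                     peak_z = peaks$z[qi], tss_distance = dist,
                     stringsAsFactors = FALSE)
  ord <- order(cand$tf, cand$gene, -cand$peak_z)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand[, c("tf", "gene")]), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Derive candidate TF-gene interactions from peak and TSS tables
#'
#' Composition of \code{\link{zscoreFilter}} and
#' \code{\link{assignToGenes}}, restricted to genes present in the
#' study.
#'
#' @param peaks Raw peak table.
#' @param tss TSS table.
#' @param zMin Z-score cutoff.
#' @param window TSS window half-width.
#' @return Candidate interaction data frame.
#' @export
candidateInteractions <- function(peaks, tss, zMin = 1.96,
                                  window = 10000L) {
  assignToGenes(zscoreFilter(peaks, zMin), tss, window)
}
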