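#' Flag structured regulatory elements
#'
#' An RE is structured when it shares at least one nucleotide with a
#' conserved-RNA-structure interval (half-open genomic coordinates).
#'
#' @param re RE table: \code{gene}, \code{utr}, \code{category},
#'   \code{element}, \code{chrom}, \code{start}, \code{end}.
#' @param crsIntervals CRS interval table: \code{chrom}, \code{start},
#'   \code{end} (may be NULL/empty: all flags FALSE).
#' @return The RE table with a logical \code{structured} column.
#' @export
flagStructured <- function(re, crsIntervals) {
  re$structured <- logical(nrow(re))
  if (is.null(crsIntervals) || nrow(crsIntervals) == 0 ||
      nrow(re) == 0) return(re)
  gr <- GenomicRanges::GRanges(re$chrom,
                               IRanges::IRanges(re$start + 1L, re$end))
  gc <- GenomicRanges::GRanges(crsIntervals$chrom,
                               IRanges::IRanges(crsIntervals$start + 1L,
                                                crsIntervals$end))
  re$structured <- IRanges::overlapsAny(gr, gc, minoverlap = 1L)
  re
}

#' Monte-Carlo chi-square association test
#'
#' Association between DE membership and RE membership over a gene
#' background, as a 2x2 chi-square test with a Monte-Carlo p-value
#' (see \code{\link{mcChisqTest}}).  The
#' test is skipped (NA) unless the RE is present in at least
#' \code{minGenes} DE genes and \code{minGenes} non-DE genes.
#'
#' @param deGenes Differentially expressed gene ids.
#' @param background All background gene ids.
#' @param memberGenes Genes carrying the RE.
#' @param nMc Monte-Carlo replicates (default 1e5).
#' @param minGenes Minimum count on both DE margins (default 10).
#' @param seed Integer seed for the resampling.
#' @return List with \code{p}, \code{table} (2x2 counts), \code{skipped}.
#' @export
enrichmentTest <- function(deGenes, background, memberGenes, nMc = 1e5,
                           minGenes = 10L, seed = 1L) {
  de <- background %in% deGenes
  mem <- background %in% memberGenes
  tab <- table(factor(de, c(TRUE, FALSE)), factor(mem, c(TRUE, FALSE)))
  dimnames(tab) <- list(de = c("de", "not_de"), re = c("re", "no_re"))
  if (tab["de", "re"] < minGenes || tab["not_de", "re"] < minGenes)
    return(list(p = NA_real_, table = tab, skipped = TRUE))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = NA_real_, table = tab, skipped = TRUE))
  list(p = mcChisqTest(tab, nMc = nMc, seed = seed), table = tab,
       skipped = FALSE)
}

#' Monte-Carlo chi-square p-value for a 2x2 table
#'
#' Tables are resampled as multinomial draws with fixed grand total
#' under the independence model estimated from the observed margins;
#' each simulated table's statistic uses its own margins' expected
#' counts.  The estimator is
#' \eqn{(1 + \#\{\chi^2_* \ge \chi^2_{obs}\}) / (1 + n_{mc})}, which
#' converges to the asymptotic chi-square p-value on large-count
#' tables.
#'
#' @param tab 2x2 integer matrix.
#' @param nMc Number of replicates.
#' @param seed Integer seed.
#' @return The Monte-Carlo p-value.
#' @export
mcChisqTest <- function(tab, nMc = 1e5, seed = 1L) {
  stopifnot(identical(dim(tab), c(2L, 2L)))
  set.seed(seed)
  n <- sum(tab)
  pr <- as.vector(outer(rowSums(tab) / n, colSums(tab) / n))
  E <- pr * n
  obs <- sum((as.vector(tab) - E)^2 / E)
  sim <- stats::rmultinom(nMc, n, pr)
  r1 <- sim[1, ] + sim[3, ]; r2 <- sim[2, ] + sim[4, ]
  c1 <- sim[1, ] + sim[2, ]; c2 <- sim[3, ] + sim[4, ]
  st <- (sim[1, ] - r1 * c1 / n)^2 / (r1 * c1 / n) +
    (sim[2, ] - r2 * c1 / n)^2 / (r2 * c1 / n) +
    (sim[3, ] - r1 * c2 / n)^2 / (r1 * c2 / n) +
    (sim[4, ] - r2 * c2 / n)^2 / (r2 * c2 / n)
  st[!is.finite(st)] <- 0   # degenerate margin: no evidence
  (1 + sum(st >= obs - 1e-12)) / (1 + nMc)
}

#' Region-level RE enrichment scan
#'
#' Tests RE types and specific RE elements for association with a
#' region's DE genes, separately for all REs and structured-only REs,
#' and stratified by UTR (any, 5', 3').  BH correction is applied
#' within each (region, types-vs-elements) family; significance at
#' adjusted 0.05.
#'
#' @param deUnion DE gene ids of the region.
#' @param background Background gene ids (all protein-coding genes on
#'   the array).
#' @param re Structured-flagged RE table (\code{\link{flagStructured}}).
#' @param region Region id used for labeling.
#' @param nMc Monte-Carlo replicates per test.
#' @param alpha Significance level.
#' @param minGenes Minimum genes on both DE margins.
#' @param seed Integer seed.
#' @return Data frame: \code{region}, \code{family} (type/element),
#'   \code{scope} (all/structured), \code{utr}, \code{item}, the 2x2
#'   counts, \code{p_raw}, \code{p_adj}, \code{significant}.
#' @export
runRegionEnrichment <- function(deUnion, background, re, region = "region",
                                nMc = 1e5, alpha = 0.05, minGenes = 10L,
                                seed = 1L) {
  empty <- data.frame(region = character(0), family = character(0),
                      scope = character(0), utr = character(0),
                      item = character(0), n_de_re = integer(0),
                      n_de_nore = integer(0), n_bg_re = integer(0),
                      n_bg_nore = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0))
  if (length(deUnion) == 0 || is.null(re) || nrow(re) == 0) return(empty)
  rows <- list()
  k <- 0L
  for (family in c("type", "element")) {
    col <- if (family == "type") "category" else "element"
    for (scope in c("all", "structured")) {
      sub <- if (scope == "all") re else re[re$structured, , drop = FALSE]
      for (utr in c("any", "5p", "3p")) {
        sub2 <- if (utr == "any") sub else sub[sub$utr == utr, ,
                                               drop = FALSE]
        for (item in sort(unique(sub2[[col]]))) {
          member <- unique(sub2$gene[sub2[[col]] == item])
          k <- k + 1L
          tst <- enrichmentTest(deUnion, background, member, nMc,
                                minGenes,
                                seed = stageSeed(seed, "enrich", k))
          if (tst$skipped) next
          tb <- tst$table
          rows[[length(rows) + 1]] <- data.frame(
            region = region, family = family, scope = scope, utr = utr,
            item = item, n_de_re = tb["de", "re"],
            n_de_nore = tb["de", "no_re"], n_bg_re = tb["not_de", "re"],
            n_bg_nore = tb["not_de", "no_re"], p_raw = tst$p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (family in unique(out$family)) {
    i <- out$family == family
    out$p_adj[i] <- adjustBH(out$p_raw[i])
  }
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
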