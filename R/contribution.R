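#' Per-sample TF contribution
#'
#' The coefficient-weighted share of a TF in one sample's expression of
#' a target gene: \eqn{c = x \beta / y}.  Log-scale expression keeps
#' the denominator away from zero; values below \code{epsY} in
#' magnitude yield a 0 contribution (guarded division).
#'
#' @param x TF expression in the sample.
#' @param beta Fitted coefficient of the TF.
#' @param y Target-gene expression in the sample.
#' @param epsY Denominator guard (default 1e-8).
#' @return The contribution ratio (vectorized).
#' @export
perSampleContribution <- function(x, beta, y, epsY = 1e-8) {
  out <- x * beta / y
  bad <- abs(y) < epsY
  if (any(bad)) {
    warning(sum(bad), " near-zero denominators guarded to 0",
            call. = FALSE)
    out[bad] <- 0
  }
  out
}

#' Mean contribution over a region's samples
#'
#' @param c Per-sample contributions of one (TF, gene) pair.
#' @return Their arithmetic mean.
#' @export
meanContribution <- function(c) {
  if (length(c) == 0) stop("empty sample set")
  mean(c)
}

#' Total regional contribution of a TF
#'
#' Sum of absolute mean contributions over all regulated genes.
#'
#' @param c Mean contributions of the TF over its gate-passing genes.
#' @return \eqn{s = \sum_g |c_g|}.
#' @export
regionTotal <- function(c) {
  sum(abs(c))
}

#' Regional contribution frequencies of a TF
#'
#' Normalizes the regional totals of a TF over the regions of one
#' ontology depth to relative frequencies.
#'
#' @param s Named vector of regional totals (one depth).
#' @return Frequency vector summing to 1, or NULL when all totals are
#'   zero (the TF is excluded from entropy ranking).
#' @export
regionFrequencies <- function(s) {
  tot <- sum(s)
  if (tot <= 0) return(NULL)
  s / tot
}

#' Shannon entropy of a TF's regional contribution profile
#'
#' Natural-log entropy with the 0 log 0 = 0 convention.  Low entropy
#' marks a TF whose contribution concentrates in few regions.
#'
#' @param p Frequency vector from \code{\link{regionFrequencies}}.
#' @return The entropy in nats.
#' @export
contributionEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Contribution table of one fitted run
#'
#' Computes, for every gate-passing gene and its fitted TFs, the mean
#' per-sample contribution in each requested region, and aggregates to
#' regional TF totals.
#'
#' @param study Collapsed \linkS4class{BrainExpressionStudy}.
#' @param fit Result of \code{\link{fitRegionModels}} for one region
#'   and run.
#' @param regions Regions to evaluate (default: the fitted region).
#' @param epsY Denominator guard for near-zero expression.
#' @return List with \code{contributions} (data frame \code{region},
#'   \code{tf}, \code{gene}, \code{c}) and \code{totals} (data frame
#'   \code{region}, \code{tf}, \code{s}).
#' @export
contributionTable <- function(study, fit, regions = fit$region,
                              epsY = 1e-8) {
  passed <- fit$fits$gene[fit$fits$passed]
  cf <- fit$coefs[fit$coefs$gene %in% passed, , drop = FALSE]
  em <- exprsValues(study)
  rows <- list()
  for (r in regions) {
    ids <- samplesForRegion(study, r)
    if (length(ids) == 0) stop("region ", r, " has no samples")
    e <- em[, ids, drop = FALSE]
    if (nrow(cf) > 0) {
      cc <- vapply(seq_len(nrow(cf)), function(i) {
        mean(perSampleContribution(e[cf$tf[i], ], cf$beta[i],
                                   e[cf$gene[i], ], epsY))
      }, numeric(1))
      rows[[r]] <- data.frame(region = r, tf = cf$tf, gene = cf$gene,
                              c = cc, stringsAsFactors = FALSE)
    }
  }
  contributions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(0), tf = character(0),
               gene = character(0), c = numeric(0))
  totals <- if (nrow(contributions)) {
    agg <- stats::aggregate(c ~ region + tf, data = contributions,
                            FUN = function(v) sum(abs(v)))
    names(agg)[3] <- "s"
    agg
  } else data.frame(region = character(0), tf = character(0),
                    s = numeric(0))
  rownames(contributions) <- rownames(totals) <- NULL
  list(contributions = contributions, totals = totals)
}

#' Rank TFs by regional contribution
#'
#' Dense ranking (ties share a rank) of the regional totals, largest
#' contribution first, separately per region.
#'
#' @param totals Data frame \code{region}, \code{tf}, \code{s} (means
#'   over runs or a single run).
#' @return The table with an added \code{rank} column.
#' @export
rankTfs <- function(totals) {
  out <- do.call(rbind, lapply(split(totals, totals$region), function(d) {
    u <- sort(unique(d$s), decreasing = TRUE)
    d$rank <- match(d$s, u)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Brain-wide most active TFs
#'
#' TFs ranked at or above \code{maxRank} in every evaluated region.
#'
#' @param ranked Output of \code{\link{rankTfs}}.
#' @param maxRank Worst admissible rank (default 20).
#' @return Character vector of TF ids.
#' @export
brainWideTfs <- function(ranked, maxRank = 20L) {
  worst <- stats::aggregate(rank ~ tf, data = ranked, FUN = max)
  nreg <- length(unique(ranked$region))
  cnt <- stats::aggregate(rank ~ tf, data = ranked, FUN = length)
  ok <- worst$rank <= maxRank & cnt$rank[match(worst$tf, cnt$tf)] == nreg
  sort(worst$tf[ok])
}

#' Entropy table over the regions of one depth
#'
#' @param totals Data frame \code{region}, \code{tf}, \code{s} covering
#'   the regions of one ontology depth; missing (region, TF) totals
#'   count as 0.
#' @return Data frame \code{tf}, \code{e} (entropy), \code{argmax}
#'   (region of largest contribution), \code{s_max}; all-zero TFs are
#'   dropped.
#' @export
entropyTable <- function(totals) {
  regions <- sort(unique(totals$region))
  tfs <- sort(unique(totals$tf))
  m <- matrix(0, length(tfs), length(regions),
              dimnames = list(tfs, regions))
  m[cbind(match(totals$tf, tfs), match(totals$region, regions))] <-
    totals$s
  out <- lapply(tfs, function(tf) {
    p <- regionFrequencies(m[tf, ])
    if (is.null(p)) return(NULL)
    data.frame(tf = tf, e = contributionEntropy(p),
               argmax = regions[which.max(m[tf, ])],
               s_max = max(m[tf, ]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Localized TFs at one ontology depth
#'
#' A TF is called localized when its contribution in some region is in
#' the top third of that region's contributions (at or above the 2/3
#' quantile) and its contribution entropy over the depth's regions is
#' in the bottom third (at or below the 1/3 quantile).  The region of
#' largest contribution is reported per selected TF.
#'
#' @param totals Data frame \code{region}, \code{tf}, \code{s} for the
#'   regions of one depth.
#' @return Data frame \code{tf}, \code{region} (argmax), \code{e}.
#' @export
localizedTfs <- function(totals) {
  et <- entropyTable(totals)
  if (is.null(et) || nrow(et) < 3)
    return(data.frame(tf = character(0), region = character(0),
                      e = numeric(0)))
  eCut <- stats::quantile(et$e, 1 / 3, names = FALSE)
  hi <- unlist(lapply(split(totals, totals$region), function(d) {
    cut <- stats::quantile(d$s, 2 / 3, names = FALSE)
    d$tf[d$s >= cut]
  }))
  sel <- et$e <= eCut & et$tf %in% hi
  out <- data.frame(tf = et$tf[sel], region = et$argmax[sel],
                    e = et$e[sel], stringsAsFactors = FALSE)
  out[order(out$e), ]
}
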