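#' Present-call filter for differential expression
#'
#' Keeps the genes for which at least \code{minFrac} of the samples of
#' at least one sub-region have a present call.
#'
#' @param study A \linkS4class{BrainExpressionStudy}.
#' @param subregions Character vector of sub-region ids.
#' @param minFrac Minimum present fraction (default 0.5).
#' @return Character vector of gene ids.
#' @export
dePresentFilter <- function(study, subregions, minFrac = 0.5) {
  if (length(subregions) < 2) stop("need at least two sub-regions")
  pm <- presentCalls(study)
  ok <- rep(FALSE, nrow(pm))
  for (r in subregions) {
    ids <- samplesForRegion(study, r)
    if (length(ids) == 0) next
    ok <- ok | rowMeans(pm[, ids, drop = FALSE]) >= minFrac
  }
  rownames(pm)[ok]
}

# Inverse of the trigamma function by Newton iteration (monotone
# decreasing on (0, Inf)).
.trigammaInverse <- function(y) {
  vapply(y, function(v) {
    if (v > 1e7) return(1 / sqrt(v))
    if (v < 1e-6) return(1 / v)
    x <- 0.5 + 1 / v
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / v) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes variance shrinkage hyperparameters
#'
#' Method-of-moments fit of a scaled inverse chi-square prior to the
#' per-gene residual variances: the log variances are matched against
#' the moments of log chi-square variables, giving a prior degrees of
#' freedom \code{d0} and prior variance \code{s02}.  \code{d0 = Inf}
#' (no excess spread) collapses the posterior variance to \code{s02}.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with \code{d0} and \code{s02}.
#' @export
ebShrinkVar <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t-test relative to a fold-change threshold
#'
#' Tests, per gene, the null hypothesis that the true absolute log
#' fold-change is within \code{tau}, using a moderated t-statistic:
#' the posterior residual variance blends the gene's variance with an
#' empirical-Bayes prior, and the p-value sums the two shifted tails
#' \eqn{P(T > (|lfc| - \tau)/se) + P(T > (|lfc| + \tau)/se)} on
#' \code{d0 + df} degrees of freedom (capped at 1).
#'
#' @param lfc Estimated log fold-changes (one per gene).
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom of \code{s2}.
#' @param u Unscaled standard error of the fold-change estimate
#'   (e.g. \code{sqrt(1/nA + 1/nB)}).
#' @param tau Fold-change threshold on the log scale.
#' @param shrink Hyperparameters from \code{\link{ebShrinkVar}}; with
#'   \code{d0 = 0} the unmoderated per-gene variance is used.
#' @return Numeric vector of p-values.
#' @export
treatPValue <- function(lfc, s2, df, u, tau, shrink = list(d0 = 0)) {
  d0 <- shrink$d0
  if (d0 == 0) {
    s2post <- s2
    dft <- df
  } else if (is.infinite(d0)) {
    s2post <- rep(shrink$s02, length(s2))
    dft <- Inf
  } else {
    s2post <- (d0 * shrink$s02 + df * s2) / (d0 + df)
    dft <- d0 + df
  }
  se <- sqrt(s2post) * u
  tr <- (abs(lfc) - tau) / se
  tl <- (abs(lfc) + tau) / se
  p <- stats::pt(tr, df = dft, lower.tail = FALSE) +
    stats::pt(tl, df = dft, lower.tail = FALSE)
  pmin(p, 1)
}

#' Two-group fold-change-threshold test
#'
#' Convenience two-group form: the fold-change is the difference of
#' group means, the residual variance pools both groups, and the
#' p-value comes from \code{\link{treatPValue}}.  If no shrink
#' parameters are supplied the unmoderated variance is used; if the
#' pooled variance is degenerate (zero) for all genes a Welch test
#' against zero is the fallback.
#'
#' @param valuesA,valuesB Numeric matrices (genes x samples) or vectors
#'   (one gene).
#' @param tau Log fold-change threshold (default \code{log2(1.5)}).
#' @param shrink Optional hyperparameters from
#'   \code{\link{ebShrinkVar}}.
#' @return Data frame \code{log_fc}, \code{p_raw}.
#' @export
treatTest <- function(valuesA, valuesB, tau = log2(1.5), shrink = NULL) {
  if (is.null(dim(valuesA))) valuesA <- matrix(valuesA, nrow = 1)
  if (is.null(dim(valuesB))) valuesB <- matrix(valuesB, nrow = 1)
  nA <- ncol(valuesA); nB <- ncol(valuesB)
  if (nA < 2 || nB < 2) stop("need at least two samples per group")
  mA <- rowMeans(valuesA); mB <- rowMeans(valuesB)
  lfc <- mA - mB
  sse <- rowSums((valuesA - mA)^2) + rowSums((valuesB - mB)^2)
  df <- nA + nB - 2
  s2 <- sse / df
  if (all(s2 == 0)) {
    warning("all residual variances are zero; Welch fallback",
            call. = FALSE)
    p <- vapply(seq_along(lfc), function(i)
      tryCatch(stats::t.test(valuesA[i, ], valuesB[i, ])$p.value,
               error = function(e) 1), numeric(1))
    return(data.frame(log_fc = lfc, p_raw = p))
  }
  if (is.null(shrink)) shrink <- list(d0 = 0)
  u <- sqrt(1 / nA + 1 / nB)
  data.frame(log_fc = lfc,
             p_raw = treatPValue(lfc, s2, df, u, tau, shrink))
}

#' Pairwise differential expression between a region's sub-regions
#'
#' Fits one joint group-means model over all sub-region samples
#' (replicates retained), shrinks the per-gene residual variances by
#' empirical Bayes, and tests every pair of sub-regions against the
#' fold-change threshold.  BH adjustment is applied to each contrast
#' separately; the DE set of the region is the union of significant
#' genes over all contrasts.
#'
#' @param study A \linkS4class{BrainExpressionStudy} (uncollapsed).
#' @param region Region id; its direct children are the sub-regions.
#' @param tau Log fold-change threshold (default \code{log2(1.5)}).
#' @param alpha Significance level on adjusted p-values.
#' @param minFrac Present-call fraction for \code{\link{dePresentFilter}}.
#' @return List with \code{results} (per contrast x gene:
#'   \code{contrast}, \code{gene}, \code{log_fc}, \code{p_raw},
#'   \code{p_adj}, \code{significant}, \code{direction}), \code{union}
#'   (DE gene ids) and \code{subregions}.
#' @export
pairwiseDe <- function(study, region, tau = log2(1.5), alpha = 0.05,
                       minFrac = 0.5) {
  kids <- regionChildren(studyOntology(study), region)
  kids <- kids[vapply(kids, function(r)
    length(samplesForRegion(study, r)) >= 2, logical(1))]
  if (length(kids) < 2) {
    warning("region ", region, " has fewer than two eligible sub-regions",
            call. = FALSE)
    return(list(results = NULL, union = character(0), subregions = kids))
  }
  genes <- dePresentFilter(study, kids, minFrac)
  em <- exprsValues(study)[genes, , drop = FALSE]
  groupIds <- lapply(kids, function(r) samplesForRegion(study, r))
  names(groupIds) <- kids

  n <- vapply(groupIds, length, integer(1))
  means <- vapply(groupIds, function(ids)
    rowMeans(em[, ids, drop = FALSE]), numeric(nrow(em)))
  sse <- rowSums(vapply(seq_along(kids), function(i) {
    rowSums((em[, groupIds[[i]], drop = FALSE] - means[, i])^2)
  }, numeric(nrow(em))))
  df <- sum(n) - length(kids)
  s2 <- sse / df
  shrink <- ebShrinkVar(s2, df)

  combs <- utils::combn(kids, 2, simplify = FALSE)
  res <- lapply(combs, function(pr) {
    a <- pr[1]; b <- pr[2]
    lfc <- means[, a] - means[, b]
    u <- sqrt(1 / n[[a]] + 1 / n[[b]])
    p <- treatPValue(lfc, s2, df, u, tau, shrink)
    padj <- adjustBH(p)
    data.frame(contrast = paste(a, b, sep = "-"), gene = genes,
               log_fc = lfc, p_raw = p, p_adj = padj,
               significant = padj < alpha,
               direction = ifelse(lfc > 0, "up", "down"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  list(results = res,
       union = sort(unique(res$gene[res$significant])),
       subregions = kids)
}

#' Localized expression calls within a region
#'
#' A gene is localized-up (-down) in a sub-region when it is
#' significantly up (down) versus every sibling sub-region.
#'
#' @param pw Result of \code{\link{pairwiseDe}}.
#' @return Data frame \code{gene}, \code{subregion}, \code{direction}.
#' @export
localizedExpression <- function(pw) {
  out <- data.frame(gene = character(0), subregion = character(0),
                    direction = character(0))
  if (is.null(pw$results)) return(out)
  kids <- pw$subregions
  res <- pw$results
  rows <- list()
  for (r in kids) {
    others <- setdiff(kids, r)
    for (g in pw$union) {
      dirs <- vapply(others, function(o) {
        hit <- res[res$gene == g &
                     res$contrast %in% c(paste(r, o, sep = "-"),
                                         paste(o, r, sep = "-")), ,
                   drop = FALSE]
        if (nrow(hit) == 0 || !hit$significant[1]) return(NA_character_)
        # orient the sign towards sub-region r
        if (startsWith(hit$contrast[1], paste0(r, "-")))
          hit$direction[1]
        else if (hit$direction[1] == "up") "down" else "up"
      }, character(1))
      if (!anyNA(dirs) && length(unique(dirs)) == 1)
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, subregion = r, direction = dirs[[1]],
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else out
}
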