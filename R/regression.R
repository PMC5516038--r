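#' Select TFs from a fitted coefficient vector
#'
#' Keeps the TFs with non-zero coefficients; if more than
#' \code{nd - 1} survive (nd = sample count), the \code{nd - 1} largest
#' by absolute coefficient are kept (ties broken by TF id) so the
#' downstream OLS stays identifiable.
#'
#' @param beta Named coefficient vector (no intercept).
#' @param nd Number of samples.
#' @return Character vector of selected TF ids (possibly empty).
#' @export
selectTfs <- function(beta, nd) {
  nz <- beta[beta != 0]
  if (length(nz) == 0) return(character(0))
  if (length(nz) > nd - 1) {
    ord <- order(-abs(nz), names(nz))
    nz <- nz[ord][seq_len(nd - 1)]
  }
  sort(names(nz))
}

#' K-fold cross-validated OLS sum of squared errors
#'
#' Splits the samples into \code{k} folds, fits an ordinary
#' least-squares model (with intercept) on each training part and
#' returns the held-out sum of squared errors of each fold.
#'
#' @param X Predictor matrix of the selected TFs (may have zero
#'   columns: intercept-only model).
#' @param y Response vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Numeric vector of \code{k} held-out SSEs.
#' @export
crossValidateOls <- function(X, y, k = 10L, seed = 1L) {
  n <- length(y)
  if (k > n) stop("cannot run ", k, "-fold CV with ", n, " samples")
  set.seed(seed)
  foldid <- sample(rep(seq_len(k), length.out = n))
  sse <- numeric(k)
  X1 <- cbind(`(Intercept)` = 1, X)
  for (f in seq_len(k)) {
    tr <- foldid != f
    fit <- stats::lm.fit(X1[tr, , drop = FALSE], y[tr])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred <- drop(X1[!tr, , drop = FALSE] %*% cf)
    sse[f] <- sum((y[!tr] - pred)^2)
  }
  sse
}

#' One-sided gate test of a gene model against its random models
#'
#' Welch two-sample one-sided t-test of the k fold SSEs of the real
#' model against the pooled fold SSEs of the random models; the
#' alternative is that the real model's SSEs are smaller.  With zero
#' spread in both groups the p-value is 0 or 1 by mean comparison
#' (1 when the means are equal).
#'
#' @param cvSse Fold SSEs of the real model.
#' @param randomSse Pooled fold SSEs of the random models.
#' @param varEqual Assume equal variances (default FALSE: Welch).
#' @return The one-sided p-value.
#' @export
gateTest <- function(cvSse, randomSse, varEqual = FALSE) {
  if (stats::sd(cvSse) == 0 && stats::sd(randomSse) == 0) {
    if (mean(cvSse) < mean(randomSse)) return(0)
    return(1)
  }
  tryCatch(
    stats::t.test(cvSse, randomSse, alternative = "less",
                  var.equal = varEqual)$p.value,
    error = function(e) if (mean(cvSse) < mean(randomSse)) 0 else 1)
}

# Fit one gene: LASSO selection (when >= 2 candidates), coefficient
# extraction and k-fold OLS CV.  Returns NULL when nothing is selected.
.fitOneModel <- function(X, y, k, seed) {
  nTf <- ncol(X)
  if (nTf >= 2) {
    lf <- fitLassoPath(X, y, seed = seed, nfolds = k)
    sel <- selectTfs(lf$beta, length(y))
    if (length(sel) == 0)
      return(list(sel = character(0),
                  sse = crossValidateOls(X[, 0, drop = FALSE], y, k,
                                         seed = seed + 1L)))
    beta <- lf$beta[sel]
    a0 <- lf$a0
    lambda <- lf$lambda
  } else {
    # too few predictors for LASSO: plain OLS on all candidates
    fit <- stats::lm.fit(cbind(1, X), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    a0 <- cf[1]
    beta <- cf[-1]
    names(beta) <- colnames(X)
    sel <- names(beta)[beta != 0]
    beta <- beta[sel]
    lambda <- NA_real_
  }
  sse <- crossValidateOls(X[, sel, drop = FALSE], y, k, seed = seed + 1L)
  fitted <- unname(a0) + drop(X[, sel, drop = FALSE] %*% beta)
  list(sel = sel, beta = beta, a0 = unname(a0), lambda = lambda,
       sse = sse, fitted = fitted)
}

#' Per-gene random models
#'
#' Repeats the full fitting procedure (LASSO selection when applicable,
#' then cross-validated OLS) on \code{nModels} random predictor sets of
#' the same size as the gene's candidate set, drawn from the expression
#' of all other genes on the array.
#'
#' @param y Response vector of the target gene.
#' @param pool Expression matrix (samples x genes) to draw random
#'   predictors from; must exclude the target gene.
#' @param nTf Number of random predictors per model.
#' @param nModels Number of random models (default 10).
#' @param k CV folds.
#' @param seed Integer seed.
#' @return Numeric vector of \code{nModels * k} held-out SSEs.
#' @export
randomModels <- function(y, pool, nTf, nModels = 10L, k = 10L,
                         seed = 1L) {
  if (ncol(pool) < nTf)
    stop("random-model pool smaller than the candidate count")
  sse <- numeric(0)
  for (m in seq_len(nModels)) {
    set.seed(stageSeed(seed, "random-model", m))
    cols <- sample(ncol(pool), nTf)
    fit <- .fitOneModel(pool[, cols, drop = FALSE], y, k,
                        seed = stageSeed(seed, "random-fit", m))
    sse <- c(sse, fit$sse)
  }
  sse
}

#' Fit gated regression models for every candidate gene of a region
#'
#' For each gene with candidate TFs: restrict to the region's samples,
#' drop genes with under 50\% present calls, run LASSO selection and
#' 10-fold OLS cross-validation, compare against random models with a
#' one-sided t-test, and BH-adjust the gate p-values over all genes.
#'
#' @param study A collapsed \linkS4class{BrainExpressionStudy}.
#' @param region Region id to analyze.
#' @param candidates Candidate interaction table
#'   (\code{\link{candidateInteractions}}).
#' @param seed Integer run seed.
#' @param k CV folds (default 10).
#' @param nRandom Random models per gene (default 10).
#' @param presentMin Minimum present-call fraction (default 0.5).
#' @param alpha Gate significance level on adjusted p-values.
#' @return List with \code{fits} (per-gene data frame: \code{gene},
#'   \code{n_tf}, \code{lambda}, \code{intercept}, \code{p_raw},
#'   \code{p_adj}, \code{passed}), \code{coefs} (per selected (gene,
#'   TF): \code{beta}), \code{fitted} (per-gene fitted values from the
#'   stored intercept and coefficients) and \code{region}, \code{seed}.
#' @export
fitRegionModels <- function(study, region, candidates, seed = 1L,
                            k = 10L, nRandom = 10L, presentMin = 0.5,
                            alpha = 0.05) {
  sub <- regionStudy(study, region)
  em <- exprsValues(sub)
  present <- rowMeans(presentCalls(sub)) >= presentMin
  em <- em[present, , drop = FALSE]
  if (ncol(em) < k)
    stop("region ", region, " has fewer samples than CV folds")
  genesAll <- rownames(em)
  cand <- candidates[candidates$gene %in% genesAll &
                       candidates$tf %in% genesAll, , drop = FALSE]
  targets <- sort(unique(cand$gene))
  tx <- t(em)   # samples x genes

  fits <- vector("list", length(targets))
  coefs <- vector("list", length(targets))
  fitted <- list()
  for (gi in seq_along(targets)) {
    g <- targets[gi]
    tfg <- sort(cand$tf[cand$gene == g])
    y <- tx[, g]
    X <- tx[, tfg, drop = FALSE]
    gSeed <- stageSeed(seed, paste0("gene-", g))
    fit <- .fitOneModel(X, y, k, seed = gSeed)
    if (length(fit$sel) == 0) {
      fits[[gi]] <- data.frame(gene = g, n_tf = length(tfg),
                               lambda = NA_real_, intercept = NA_real_,
                               p_raw = NA_real_, stringsAsFactors = FALSE)
      next
    }
    pool <- tx[, setdiff(genesAll, g), drop = FALSE]
    rss <- randomModels(y, pool, nTf = length(tfg), nModels = nRandom,
                        k = k, seed = gSeed)
    p <- gateTest(fit$sse, rss)
    fits[[gi]] <- data.frame(gene = g, n_tf = length(tfg),
                             lambda = fit$lambda, intercept = fit$a0,
                             p_raw = p, stringsAsFactors = FALSE)
    coefs[[gi]] <- data.frame(gene = g, tf = fit$sel,
                              beta = unname(fit$beta[fit$sel]),
                              stringsAsFactors = FALSE)
    fitted[[g]] <- fit$fitted
  }
  fits <- do.call(rbind, fits)
  fits$p_adj <- NA_real_
  ok <- !is.na(fits$p_raw)
  fits$p_adj[ok] <- adjustBH(fits$p_raw[ok])
  fits$passed <- !is.na(fits$p_adj) & fits$p_adj < alpha
  coefs <- do.call(rbind, coefs)
  rownames(fits) <- rownames(coefs) <- NULL
  list(region = region, seed = seed, fits = fits, coefs = coefs,
       fitted = fitted)
}

#' Robust interactions across independent runs
#'
#' Intersection of the (TF, gene) pairs that appear with a non-zero
#' coefficient in gate-passing models of every run.
#'
#' @param runs List of results from \code{\link{fitRegionModels}}, one
#'   per run seed (normally five).
#' @param minRuns Require this many runs (default: all supplied runs
#'   must agree; fewer than 5 supplied runs is an error unless
#'   \code{allowFewer}).
#' @param allowFewer Permit fewer than five runs.
#' @return Data frame \code{tf}, \code{gene}, \code{beta_mean} (mean
#'   coefficient over runs), \code{runs_observed}.
#' @export
robustInteractions <- function(runs, minRuns = length(runs),
                               allowFewer = FALSE) {
  if (length(runs) < 5 && !allowFewer)
    stop("the robustness protocol expects five runs; got ", length(runs))
  pairs <- lapply(runs, function(r) {
    passed <- r$fits$gene[r$fits$passed]
    cf <- r$coefs[r$coefs$gene %in% passed, , drop = FALSE]
    cf$key <- paste(cf$tf, cf$gene, sep = "\r")
    cf
  })
  allKeys <- unlist(lapply(pairs, `[[`, "key"))
  tab <- table(allKeys)
  keep <- names(tab)[tab >= minRuns]
  if (length(keep) == 0)
    return(data.frame(tf = character(0), gene = character(0),
                      beta_mean = numeric(0), runs_observed = integer(0)))
  betas <- do.call(rbind, pairs)
  betas <- betas[betas$key %in% keep, , drop = FALSE]
  agg <- stats::aggregate(beta ~ key + tf + gene, data = betas, FUN = mean)
  out <- data.frame(tf = agg$tf, gene = agg$gene, beta_mean = agg$beta,
                    runs_observed = as.integer(tab[agg$key]),
                    stringsAsFactors = FALSE)
  out[order(out$tf, out$gene), c("tf", "gene", "beta_mean",
                                 "runs_observed")]
}
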