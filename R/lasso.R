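#' LASSO solution path by covariance-update coordinate descent
#'
#' Solves \eqn{\min_\beta \frac{1}{2n}\|y - a - X\beta\|_2^2 +
#' \lambda\|\beta\|_1} over a decreasing \eqn{\lambda} grid with warm
#' starts.  Predictors are standardized internally (population sd);
#' coefficients are returned on the original scale with an unpenalized
#' intercept.  The compiled inner loop works on the Gram matrix, so a
#' coordinate step costs O(p) independent of the sample count.
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Numeric response vector.
#' @param lambda Optional decreasing lambda grid; derived from the data
#'   when NULL (log-spaced from the smallest lambda that zeroes all
#'   coefficients).
#' @param nlambda Grid size when \code{lambda} is NULL.
#' @param lambdaMinRatio Smallest lambda as a fraction of the largest;
#'   defaults to 1e-4 (n > p) or 0.01 (n <= p).
#' @param tol Coordinate-descent convergence tolerance.
#' @param maxit Maximum sweeps per lambda.
#' @return List with \code{lambda}, \code{a0} (intercepts) and
#'   \code{beta} (p x nlambda matrix, original scale).
#' @export
lassoPath <- function(X, y, lambda = NULL, nlambda = 50L,
                      lambdaMinRatio = NULL, tol = 1e-8, maxit = 1000L) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  xc <- X - rep(xm, each = n)
  xs <- sqrt(colMeans(xc^2))
  keep <- xs > 0
  ym <- mean(y); yc <- y - ym
  if (!any(keep)) {
    lambda <- if (is.null(lambda)) 1 else lambda
    return(list(lambda = lambda,
                a0 = rep(ym, length(lambda)),
                beta = matrix(0, p, length(lambda),
                              dimnames = list(colnames(X), NULL))))
  }
  Xs <- xc[, keep, drop = FALSE] /
    rep(xs[keep], each = n)
  C <- crossprod(Xs) / n
  b <- drop(crossprod(Xs, yc)) / n
  if (is.null(lambda)) {
    lmax <- max(abs(b))
    if (lmax <= 0) lmax <- 1e-3
    if (is.null(lambdaMinRatio))
      lambdaMinRatio <- if (n > p) 1e-4 else 0.01
    lambda <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                      length.out = nlambda))
  }
  Bs <- .cd_lasso_path(C, b, lambda, tol, maxit)
  B <- matrix(0, p, length(lambda), dimnames = list(colnames(X), NULL))
  B[keep, ] <- Bs / xs[keep]
  a0 <- ym - drop(crossprod(xm, B))
  list(lambda = lambda, a0 = a0, beta = B)
}

#' LASSO fit with cross-validated one-standard-error lambda
#'
#' K-fold cross-validation over the full-data lambda path; the selected
#' lambda is the largest one whose mean CV error is within one standard
#' error of the minimum (the one-standard-error rule).  Fold assignment
#' is drawn from \code{seed}, so refits are reproducible.
#'
#' @param X Numeric predictor matrix (candidate-TF expression).
#' @param y Response vector (gene expression).
#' @param seed Integer seed for the fold assignment.
#' @param nfolds Number of CV folds (default 10).
#' @param nlambda Lambda grid size.
#' @return List with \code{lambda} (selected), \code{a0}, \code{beta}
#'   (named vector, original scale), \code{cvm}, \code{cvsd},
#'   \code{lambdaGrid}.
#' @export
fitLassoPath <- function(X, y, seed = 1L, nfolds = 10L, nlambda = 50L) {
  n <- nrow(X)
  if (ncol(X) < 2)
    stop("LASSO regression requires at least two predictors")
  if (nfolds > n) stop("more folds than samples")
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  full <- lassoPath(X, y, nlambda = nlambda)
  lam <- full$lambda
  mse <- matrix(NA_real_, nfolds, length(lam))
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    ft <- lassoPath(X[tr, , drop = FALSE], y[tr], lambda = lam)
    pred <- X[!tr, , drop = FALSE] %*% ft$beta
    pred <- pred + rep(ft$a0, each = nrow(pred))
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(mse)
  cvsd <- apply(mse, 2, stats::sd) / sqrt(nfolds)
  i0 <- which.min(cvm)
  i1 <- which(cvm <= cvm[i0] + cvsd[i0])[1]
  beta <- full$beta[, i1]
  names(beta) <- colnames(X)
  list(lambda = lam[i1], a0 = full$a0[i1], beta = beta,
       cvm = cvm, cvsd = cvsd, lambdaGrid = lam)
}
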