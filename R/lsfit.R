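#' Least squares with deterministic handling of collinear columns
#'
#' Solves `min ||y - X b||` by QR decomposition. Columns that are (numerically)
#' linear combinations of columns to their left are dropped, so the drop
#' order is deterministic: earlier columns always win. Dropped columns are
#' reported and given `NA` coefficients.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix with column names.
#' @param tol Relative tolerance used to declare a column collinear.
#' @return List with `coefficients` (length `ncol(X)`, `NA` for dropped),
#'   `residuals`, `fitted`, `kept` (logical per column), `dropped`
#'   (character names), `rank`, `XtX_inv` (inverse Gram matrix of the kept
#'   columns) and `n`.
#' @export
ols_fit <- function(y, X, tol = 1e-9) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) == 0L) stop("design matrix has no columns")

  # left-to-right rank screen: keep a column iff it adds to the column space
  qrX <- qr(X)  # pivoted; used only to know the rank
  r <- qrX$rank
  if (r == 0L) stop("design matrix has rank zero")
  kept <- logical(ncol(X))
  basis <- NULL
  for (j in seq_len(ncol(X))) {
    cand <- if (is.null(basis)) X[, j, drop = FALSE] else cbind(basis, X[, j])
    if (qr(cand)$rank > (if (is.null(basis)) 0L else ncol(basis))) {
      basis <- cand
      kept[j] <- TRUE
    }
    if (sum(kept) == r) break
  }
  Xk <- X[, kept, drop = FALSE]
  if (n <= ncol(Xk)) stop("more coefficients than observations")

  fit <- qr(Xk)
  bk <- qr.coef(fit, y)
  fitted <- drop(Xk %*% bk)
  res <- y - fitted

  R <- qr.R(fit)
  XtX_inv <- chol2inv(R)
  dimnames(XtX_inv) <- list(colnames(Xk), colnames(Xk))

  coefs <- rep(NA_real_, ncol(X))
  names(coefs) <- colnames(X)
  coefs[kept] <- bk
  list(coefficients = coefs, residuals = res, fitted = fitted,
       kept = kept, dropped = colnames(X)[!kept], rank = sum(kept),
       XtX_inv = XtX_inv, X = Xk, n = n)
}

#' Cluster-robust (CR1) sandwich covariance
#'
#' Computes the clustered sandwich estimator
#' `(X'X)^-1 [ sum_g X_g' u_g u_g' X_g ] (X'X)^-1` with the CR1
#' small-sample scale `G/(G-1) * (n-1)/(n-k)`, where `G` is the number of
#' clusters and `k` the model degrees of freedom (regressors plus any
#' absorbed fixed-effect coefficients, supplied via `df_absorbed`). With
#' every observation its own cluster this reduces, up to the stated scale
#' factors, to the HC1 heteroskedasticity-robust estimator. Scores are
#' summed within clusters, which permits arbitrary correlation of errors
#' inside a cluster (e.g. serial correlation within a plot).
#'
#' @param fit A fit as returned by [ols_fit()] (uses `X`, `residuals`,
#'   `XtX_inv`, `n`).
#' @param cluster Vector of cluster identifiers, length `n`.
#' @param df_absorbed Model degrees of freedom absorbed outside `X`
#'   (e.g. from [fe_degrees_of_freedom()]); added to `k`.
#' @return List with `vcov` (for the kept columns), `n_clusters`, `k`.
#' @export
cluster_robust_vcov <- function(fit, cluster, df_absorbed = 0L) {
  cluster <- as.factor(cluster)
  n <- fit$n
  if (length(cluster) != n) stop("cluster length must match observations")
  G <- nlevels(droplevels(cluster))
  if (G < 2L) stop("cluster-robust variance needs at least 2 clusters")
  k <- ncol(fit$X) + as.integer(df_absorbed)
  scores <- fit$X * fit$residuals          # n x k matrix of x_i * u_i
  Sg <- rowsum(scores, cluster)            # cluster-summed scores
  meat <- crossprod(Sg)
  scale <- (G / (G - 1)) * ((n - 1) / (n - k))
  V <- scale * (fit$XtX_inv %*% meat %*% fit$XtX_inv)
  dimnames(V) <- dimnames(fit$XtX_inv)
  list(vcov = V, n_clusters = G, k = k)
}
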