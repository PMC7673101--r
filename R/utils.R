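#' Moore-Penrose pseudo-inverse via SVD
#'
#' Computes `pinv(X)` with a relative singular-value cutoff. Used for
#' back-reconstruction, where the generalized inverse of a non-square
#' source matrix is required.
#'
#' @param x numeric matrix.
#' @param tol relative tolerance: singular values below `tol * max(d)` are
#'   treated as zero.
#' @return the pseudo-inverse, `ncol(x)` by `nrow(x)`.
#' @keywords internal
#' @noRd
pseudo_inverse <- function(x, tol = 1e-10) {
  sv <- svd(x)
  keep <- sv$d > tol * sv$d[1L]
  if (!any(keep)) stop("matrix is numerically zero; pseudo-inverse undefined")
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# numerical rank with the same relative cutoff as pseudo_inverse()
matrix_rank <- function(x, tol = 1e-10) {
  d <- svd(x, nu = 0, nv = 0)$d
  sum(d > tol * d[1L])
}

# i.i.d. Laplace(0, b) draws; super-Gaussian sources for ICA fixtures
rlaplace <- function(n, b = 1) {
  u <- stats::runif(n, -0.5, 0.5)
  -b * sign(u) * log1p(-2 * abs(u))
}

# orthonormal basis of the orthogonal complement of the columns of W
# inside R^m; W may have zero columns (returns identity basis then)
orth_complement <- function(W, m) {
  if (is.null(W) || ncol(W) == 0L) return(diag(m))
  q <- qr(cbind(W, diag(m)))
  Q <- qr.Q(q)
  Q[, (ncol(W) + 1L):m, drop = FALSE]
}

# residual maker: regress each column of y on design (with intercept
# prepended), return residuals.  Errors on rank deficiency, naming the
# aliased columns.
ols_residuals <- function(y, design = NULL, add_intercept = TRUE) {
  y <- as.matrix(y)
  n <- nrow(y)
  X <- if (add_intercept) cbind(`(intercept)` = rep(1, n), design) else design
  if (is.null(X)) return(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("design rows must match data rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qx$pivot[(qx$rank + 1L):ncol(X)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qx, y)
}

# two-sided p-value for a Pearson correlation through the t transform
cor_pvalue <- function(r, n, df = n - 2L) {
  r <- min(max(r, -1), 1)
  if (df <= 0) return(NA_real_)
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
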