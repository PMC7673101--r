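#' Back-reconstruct loadings for a new group
#'
#' Projects a new group's feature matrix through the Moore-Penrose
#' pseudo-inverse of fitted source maps, `A_new = X_new pinv(S)`. This is
#' the linear projection used to estimate, e.g., control-group loadings
#' from a patient-group decomposition; when `X_new` lies in the row space
#' of `S` the original loadings are recovered exactly.
#'
#' @param sources M x voxels source matrix (full row rank).
#' @param x_new new feature matrix ([feature_matrix()] or plain matrix)
#'   whose columns align with the source voxel order.
#' @param tol relative singular-value tolerance for the pseudo-inverse.
#' @return subjects x M matrix of back-reconstructed loadings.
#' @export
back_reconstruct <- function(sources, x_new, tol = 1e-10) {
  X <- if (inherits(x_new, "feature_matrix")) x_new$values
       else as.matrix(x_new)
  if (ncol(X) != ncol(sources))
    stop("voxel count of the new data does not match the sources")
  rk <- matrix_rank(sources, tol)
  if (rk < nrow(sources))
    stop(sprintf("source matrix is rank deficient (rank %d of %d)",
                 rk, nrow(sources)))
  X %*% pseudo_inverse(sources, tol)
}

#' Group difference on component loadings
#'
#' Two-sample t-test on one loading column, optionally after residualizing
#' covariates (e.g. full-scale IQ, age, handedness) from the loadings
#' across all subjects — the residualize-then-test analogue of "covariates
#' were regressed out".
#'
#' @param loadings numeric vector of subject loadings.
#' @param labels two-level factor or character vector (e.g. patient /
#'   control), aligned with `loadings`.
#' @param covariates optional data frame of covariates to residualize out
#'   (numeric columns and factors are both accepted).
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return list with `t`, `p`, `df`, `group_means` and the group labels.
#' @export
group_difference <- function(loadings, labels, covariates = NULL,
                             var_equal = TRUE) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) < 2L)) stop("need at least 2 subjects per group")
  if (stats::sd(loadings) == 0) stop("loadings are constant")
  y <- loadings
  if (!is.null(covariates)) {
    design <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                 drop = FALSE]
    y <- drop(ols_residuals(matrix(y), design))
  }
  tt <- stats::t.test(y ~ labels, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       group_means = stats::setNames(tapply(y, labels, mean),
                                     levels(labels)))
}

#' Correlate loadings with clinical scores
#'
#' Pearson correlation between a loading column and a symptom score, with
#' an optional partial correlation: when `partial_covariates` is given,
#' both vectors are residualized on the covariates first and the p-value
#' uses the reduced degrees of freedom `n - 2 - k`.
#'
#' @param loadings numeric vector.
#' @param scores numeric vector aligned with `loadings`.
#' @param partial_covariates optional data frame / matrix of covariates
#'   (e.g. mean framewise displacement) to partial out.
#' @return list with `r`, `p`, `n`, and `partial` (number of covariates
#'   partialled out).
#' @export
correlate_loadings <- function(loadings, scores, partial_covariates = NULL) {
  keep <- stats::complete.cases(loadings, scores)
  x <- loadings[keep]
  y <- scores[keep]
  n <- length(x)
  if (n < 4L) stop("too few complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("inputs must not be constant")
  k <- 0L
  if (!is.null(partial_covariates)) {
    cv <- as.data.frame(partial_covariates)[keep, , drop = FALSE]
    design <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    k <- ncol(design)
    x <- drop(ols_residuals(matrix(x), design))
    y <- drop(ols_residuals(matrix(y), design))
  }
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, n, df = n - 2L - k), n = n, partial = k)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control: returns the BH-adjusted p-values
#' and the rejection flags at level `q` (a hypothesis with adjusted p
#' exactly `q` is rejected, matching the classical step-up rule).
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `p_adjusted` and `rejected`.
#' @export
fdr_adjust <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}
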