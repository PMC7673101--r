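#' Subject-by-voxel feature matrix
#'
#' The basic container fed to the fusion stage: one modality's values for
#' a set of subjects over the in-mask voxels, together with the subject
#' order, an optional 3D mask (recording the flattening order, which is
#' R's column-major order over the mask grid) and a processing log.
#'
#' @param values numeric subjects x voxels matrix without missing values.
#' @param subject_ids character vector, one id per row.
#' @param modality short tag, e.g. `"falff"` or `"gmv"`.
#' @param mask optional 3D logical array whose `TRUE` count equals
#'   `ncol(values)`.
#' @param provenance character vector of processing steps applied so far.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, subject_ids, modality, mask = NULL,
                           provenance = character(0)) {
  values <- as.matrix(values)
  if (nrow(values) != length(subject_ids))
    stop("one subject id per row required")
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  if (!is.null(mask) && sum(mask) != ncol(values))
    stop("mask voxel count does not match the number of columns")
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 modality = modality, mask = mask,
                 provenance = as.character(provenance)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d subjects x %d voxels\n",
              x$modality, nrow(x$values), ncol(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Stack per-subject 3D maps into a feature matrix
#'
#' Row i of the result holds the in-mask voxels of map i, flattened in
#' column-major order over the mask grid. [unstack_features()] inverts the
#' operation.
#'
#' @param maps list of 3D arrays on a common grid.
#' @param mask 3D logical array on that grid with at least one `TRUE`.
#' @param subject_ids character vector, one per map.
#' @param modality modality tag stored in the result.
#' @return a [feature_matrix()].
#' @export
mask_and_stack <- function(maps, mask, subject_ids, modality = "map") {
  if (length(maps) != length(subject_ids))
    stop("need one subject id per map")
  if (sum(mask) == 0L) stop("mask selects no voxels")
  idx <- which(as.vector(mask))
  rows <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    if (!identical(dim(m), dim(mask)))
      stop(sprintf("map grid mismatch for subject %s", subject_ids[i]))
    as.vector(m)[idx]
  })
  feature_matrix(do.call(rbind, rows), subject_ids, modality, mask = mask,
                 provenance = "mask_and_stack")
}

#' Unstack feature-matrix rows back into 3D maps
#'
#' @param fm a [feature_matrix()] carrying a mask.
#' @param fill value for out-of-mask voxels.
#' @return list of 3D arrays, one per subject.
#' @export
unstack_features <- function(fm, fill = NA_real_) {
  if (is.null(fm$mask)) stop("feature matrix carries no mask")
  idx <- which(as.vector(fm$mask))
  lapply(seq_len(nrow(fm$values)), function(i) {
    out <- array(fill, dim = dim(fm$mask))
    out[idx] <- fm$values[i, ]
    out
  })
}

# build the nuisance design used for feature residualization:
# age, IQ, handedness indicators (L, M vs reference R) and site
# indicators (K-1 columns).  Sites with a single subject are merged into
# the largest site (with a warning) or raise an error, per `singleton`.
covariate_design <- function(covariates, singleton = c("merge", "error")) {
  singleton <- match.arg(singleton)
  design <- NULL
  add <- function(design, col, name) {
    col <- as.matrix(col)
    colnames(col) <- name
    cbind(design, col)
  }
  if (!is.null(covariates$age))
    design <- add(design, covariates$age, "age")
  if (!is.null(covariates$iq))
    design <- add(design, covariates$iq, "iq")
  if (!is.null(covariates$handedness)) {
    h <- factor(covariates$handedness, levels = c("R", "L", "M"))
    for (lev in c("L", "M"))
      if (any(h == lev))
        design <- add(design, as.numeric(h == lev),
                      paste0("handedness_", lev))
  }
  if (!is.null(covariates$site)) {
    site <- factor(covariates$site)
    tab <- table(site)
    if (any(tab == 1L)) {
      lonely <- names(tab)[tab == 1L]
      if (singleton == "error")
        stop("site(s) with a single subject: ",
             paste(lonely, collapse = ", "))
      warning("merging single-subject site(s) into the largest site: ",
              paste(lonely, collapse = ", "))
      biggest <- names(tab)[which.max(tab)]
      site <- factor(ifelse(as.character(site) %in% lonely,
                            biggest, as.character(site)))
    }
    levs <- levels(droplevels(site))
    for (lev in levs[-1])
      design <- add(design, as.numeric(site == lev), paste0("site_", lev))
  }
  design
}

#' Residualize covariates out of a feature matrix
#'
#' Per voxel, replaces the values by the residuals of an OLS fit on an
#' intercept plus the supplied covariates (age, full-scale IQ, handedness
#' indicators and acquisition-site indicators — whichever columns are
#' present in `covariates`). Residual columns have zero mean and are
#' orthogonal to every covariate; applying the operation twice equals
#' applying it once.
#'
#' @param fm a [feature_matrix()].
#' @param covariates data frame aligned with `fm$subject_ids`; recognised
#'   columns: `age`, `iq`, `handedness` (levels R/L/M), `site`. `NULL`
#'   residualizes the intercept only (column demeaning).
#' @param singleton what to do with a site containing a single subject:
#'   `"merge"` it into the largest site (with a warning) or `"error"`.
#' @return a [feature_matrix()] with residualized values.
#' @export
residualize_covariates <- function(fm, covariates = NULL,
                                   singleton = c("merge", "error")) {
  design <- if (is.null(covariates)) NULL
            else covariate_design(covariates, match.arg(singleton))
  if (!is.null(design) && nrow(design) != nrow(fm$values))
    stop("covariate rows must align with subjects")
  vals <- ols_residuals(fm$values, design)
  feature_matrix(vals, fm$subject_ids, fm$modality, fm$mask,
                 c(fm$provenance, "residualize_covariates"))
}

#' Normalize modalities to a common mean sum of squares
#'
#' Each matrix is scaled by one scalar so that the mean of its squared
#' entries (over all subjects and voxels) equals `target`; after the call
#' all modalities share the same value range scale while relative
#' structure within a modality is untouched.
#'
#' @param fms list of [feature_matrix()] objects.
#' @param target common mean-square target (default 1).
#' @return list of rescaled feature matrices.
#' @export
normalize_ssq <- function(fms, target = 1) {
  if (length(fms) == 0L) stop("need at least one feature matrix")
  lapply(fms, function(fm) {
    ms <- mean(fm$values^2)
    if (ms == 0) stop("cannot normalize an all-zero feature matrix")
    feature_matrix(fm$values * sqrt(target / ms), fm$subject_ids,
                   fm$modality, fm$mask, c(fm$provenance, "normalize_ssq"))
  })
}
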