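#' Extract the three network regressors for symptom prediction
#'
#' Summarizes each subject by the mean feature value over three voxel
#' masks derived from the selected joint component: the positive and
#' negative functional (modality-1) networks and the positive structural
#' (modality-2) network. Column order is fixed: `f_pos`, `f_neg`, `s_pos`.
#'
#' @param functional modality-1 [feature_matrix()] (or plain matrix).
#' @param structural modality-2 [feature_matrix()] (or plain matrix).
#' @param masks list with logical voxel vectors `fpos`, `fneg` (over the
#'   functional matrix's columns) and `spos` (over the structural one);
#'   all three must be non-empty.
#' @return subjects x 3 matrix with columns `f_pos`, `f_neg`, `s_pos`.
#' @export
extract_roi_features <- function(functional, structural, masks) {
  Xf <- if (inherits(functional, "feature_matrix")) functional$values
        else as.matrix(functional)
  Xs <- if (inherits(structural, "feature_matrix")) structural$values
        else as.matrix(structural)
  for (nm in c("fpos", "fneg", "spos"))
    if (sum(masks[[nm]]) == 0L) stop("empty mask: ", nm)
  cbind(
    f_pos = rowMeans(Xf[, masks$fpos, drop = FALSE]),
    f_neg = rowMeans(Xf[, masks$fneg, drop = FALSE]),
    s_pos = rowMeans(Xs[, masks$spos, drop = FALSE])
  )
}

#' Fit the three-network symptom regression
#'
#' Ordinary least squares for
#' `score = b0 + b1 f_pos + b2 f_neg + b3 s_pos`,
#' the multiple-regression model linking the extracted network features to
#' a symptom score (ADOS or SRS).
#'
#' @param features subjects x 3 matrix from [extract_roi_features()].
#' @param scores numeric symptom scores.
#' @param masks optional defining masks, stored with the model.
#' @param meta optional named list of training metadata (cohort tag,
#'   score name, ...).
#' @return a `prediction_model` list: `coef` (b0..b3), `masks`, `meta`.
#' @export
fit_symptom_model <- function(features, scores, masks = NULL, meta = list()) {
  features <- as.matrix(features)
  if (ncol(features) != 3L) stop("expected exactly 3 feature columns")
  keep <- stats::complete.cases(features, scores)
  features <- features[keep, , drop = FALSE]
  scores <- scores[keep]
  if (length(scores) <= 4L) stop("need more than 4 complete subjects")
  cc <- stats::cor(features)
  for (i in 1:2) for (j in (i + 1):3)
    if (abs(cc[i, j]) > 1 - 1e-10)
      stop(sprintf("collinear features: %s and %s",
                   colnames(features)[i], colnames(features)[j]))
  fit <- stats::lm.fit(cbind(1, features), scores)
  if (any(is.na(fit$coefficients))) stop("degenerate feature matrix")
  structure(list(coef = stats::setNames(fit$coefficients,
                                        c("b0", "b1", "b2", "b3")),
                 masks = masks, meta = meta, n = length(scores)),
            class = "prediction_model")
}

#' Predict symptom scores from network features
#'
#' @param model a [fit_symptom_model()] result.
#' @param features subjects x 3 matrix with the training column order
#'   (`f_pos`, `f_neg`, `s_pos`).
#' @return numeric vector of predicted scores.
#' @export
predict_scores <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != 3L) stop("expected exactly 3 feature columns")
  drop(cbind(1, features) %*% model$coef)
}

#' Evaluate predictions: correlation, RMSE and NRMSE
#'
#' RMSE is the square root of the mean squared deviation between
#' predicted and true scores; NRMSE divides it by the range
#' `max(y) - min(y)` of the observed true scores. Accuracy is also
#' summarized by the Pearson correlation between predictions and truth
#' with its two-sided p-value.
#'
#' @param yhat predicted scores.
#' @param y true scores (non-constant), aligned with `yhat`.
#' @return a `prediction_report` list: `r`, `p`, `rmse`, `nrmse`, `n`.
#' @export
evaluate_prediction <- function(yhat, y) {
  keep <- stats::complete.cases(yhat, y)
  yhat <- yhat[keep]
  y <- y[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete pairs")
  rng <- max(y) - min(y)
  if (rng == 0) stop("true scores are constant; NRMSE undefined")
  rmse <- sqrt(mean((yhat - y)^2))
  r <- if (stats::sd(yhat) == 0) 0 else stats::cor(yhat, y)
  structure(list(r = r, p = cor_pvalue(r, n), rmse = rmse,
                 nrmse = rmse / rng, n = n),
            class = "prediction_report")
}

#' Cross-cohort, cross-subtype prediction specificity
#'
#' Applies every subtype's trained model (and defining masks) from cohort
#' A to every subtype's data in cohort B: the diagonal cells test whether
#' a subtype's network features generalize to the matched subtype in an
#' independent cohort, the off-diagonal cells whether they (fail to)
#' predict the other subtypes. Each cell holds an
#' [evaluate_prediction()] report plus a `significant` flag
#' (`p < alpha` with `r > 0`).
#'
#' @param models named list (by training subtype) of
#'   [fit_symptom_model()] results carrying their masks.
#' @param cohort_b named list (by subtype) of
#'   `list(falff =, gmv =, scores =)`; a subtype missing from cohort B
#'   yields `NA` cells.
#' @param alpha significance level for the flags.
#' @return a `specificity_matrix` list: `reports` (train x test matrix of
#'   reports), `r`, `p`, `significant` (numeric/logical matrices).
#' @export
cross_cohort_specificity <- function(models, cohort_b, alpha = 0.05) {
  train <- names(models)
  test <- names(cohort_b)
  rmat <- pmat <- matrix(NA_real_, length(train), length(test),
                         dimnames = list(train = train, test = test))
  sig <- matrix(NA, length(train), length(test),
                dimnames = list(train = train, test = test))
  reports <- matrix(list(), length(train), length(test),
                    dimnames = list(train = train, test = test))
  for (tr in train) for (te in test) {
    dat <- cohort_b[[te]]
    if (is.null(dat)) next
    feats <- extract_roi_features(dat$falff, dat$gmv, models[[tr]]$masks)
    rep_ <- evaluate_prediction(predict_scores(models[[tr]], feats),
                                dat$scores)
    reports[[tr, te]] <- rep_
    rmat[tr, te] <- rep_$r
    pmat[tr, te] <- rep_$p
    sig[tr, te] <- is.finite(rep_$p) && rep_$p < alpha && rep_$r > 0
  }
  structure(list(reports = reports, r = rmat, p = pmat, significant = sig,
                 alpha = alpha),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("<specificity_matrix> r (train x test):\n")
  print(round(x$r, 3))
  cat("significant (p <", x$alpha, ", r > 0):\n")
  print(x$significant)
  invisible(x)
}
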