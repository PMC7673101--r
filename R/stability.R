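#' Leave-one-site-out reproducibility runs
#'
#' For every acquisition site in turn, drops that site's subjects,
#' re-runs covariate residualization, sum-of-squares normalization,
#' reference-guided fusion and reference-component selection on the
#' remainder, and records the selected component's z-thresholded positive
#' and negative masks per modality. Component sign is aligned to an
#' optional all-sites reference map (maximal spatial correlation,
#' modality 1), so tallies across runs are not scrambled by the sign
#' ambiguity of ICA.
#'
#' @param fms list of subject-aligned raw [feature_matrix()] objects.
#' @param ref reference score vector.
#' @param covariates data frame with at least a `site` column (plus any
#'   of `age`, `iq`, `handedness`), aligned with the subjects.
#' @param M,lam,seed fusion settings; the same seed is reused for every
#'   run so each is individually reproducible.
#' @param z threshold on |Z| for the network masks.
#' @param q FDR level for component selection.
#' @param match_map optional modality-1 voxel map used to sign-align the
#'   selected component across runs.
#' @param min_remaining minimal subjects that must remain after dropping
#'   a site (default `2 * M`); smaller runs are skipped with a warning.
#' @return list of per-run records: `site`, `n`, `selection`,
#'   `significant`, `source` (per-modality selected rows), `sign_mask`
#'   (per-modality integer vectors in \{-1, 0, 1\}).
#' @export
leave_one_site_out <- function(fms, ref, covariates, M = 8, lam = 0.5,
                               seed = 1, z = 2, q = 0.05,
                               match_map = NULL, min_remaining = 2 * M) {
  site <- factor(covariates$site)
  if (nlevels(site) < 3L) stop("need at least 3 sites")
  runs <- list()
  for (s in levels(site)) {
    keep <- site != s
    if (sum(keep) < min_remaining) {
      warning(sprintf("site %s: only %d subjects would remain; skipped",
                      s, sum(keep)))
      next
    }
    sub_cov <- droplevels(covariates[keep, , drop = FALSE])
    sub <- lapply(fms, function(fm)
      feature_matrix(fm$values[keep, , drop = FALSE],
                     fm$subject_ids[keep], fm$modality, fm$mask,
                     fm$provenance))
    sub <- lapply(sub, residualize_covariates, covariates = sub_cov)
    sub <- normalize_ssq(sub)
    model <- fuse(sub, ref[keep], M = M, lam = lam, seed = seed)
    sel <- select_reference_component(model, q = q)

    comp <- sel$component
    flip <- 1
    if (!is.null(match_map)) {
      # re-match against the all-sites map: the run's own selection can
      # drift, but the planted pattern is identified by spatial similarity
      rs <- apply(model$sources[[1]], 1, stats::cor, y = match_map)
      comp <- which.max(abs(rs))
      flip <- sign(rs[comp])
    }
    src <- lapply(model$sources, function(S) flip * S[comp, ])
    sgn <- lapply(src, function(v) {
      if (!sel$significant) return(integer(length(v)))
      th <- zscore_threshold(v, z)
      as.integer(th$positive) - as.integer(th$negative)
    })
    runs[[s]] <- list(site = s, n = sum(keep), selection = sel,
                      significant = sel$significant, component = comp,
                      source = src, sign_mask = sgn)
  }
  runs
}

#' Occurrence mask across reproducibility runs
#'
#' Counts, per voxel, in how many runs it survived thresholding with a
#' positive sign and with a negative sign, and keeps voxels that survive
#' with the same sign in at least `ceiling(fraction * n_runs)` runs — or
#' at least `count` runs when an absolute-count rule is requested
#' instead.
#'
#' @param masks list of integer sign vectors in \{-1, 0, 1\} (e.g. the
#'   `sign_mask` entries of [leave_one_site_out()] runs).
#' @param fraction fraction of runs a voxel must survive in (default
#'   0.70).
#' @param count optional absolute run count overriding the fraction rule.
#' @return list with `mask` (integer sign vector of the stable voxels),
#'   `positive_count`, `negative_count`, `threshold`, `n_runs`.
#' @export
occurrence_mask <- function(masks, fraction = 0.70, count = NULL) {
  if (length(masks) == 0L) stop("need at least one run mask")
  v <- length(masks[[1]])
  for (m in masks)
    if (length(m) != v) stop("masks must share the voxel grid")
  n_runs <- length(masks)
  pos <- Reduce(`+`, lapply(masks, function(m) as.integer(m > 0)))
  neg <- Reduce(`+`, lapply(masks, function(m) as.integer(m < 0)))
  thr <- if (!is.null(count)) count else ceiling(fraction * n_runs)
  out <- integer(v)
  out[pos >= thr] <- 1L
  out[neg >= thr] <- -1L
  list(mask = out, positive_count = pos, negative_count = neg,
       threshold = thr, n_runs = n_runs)
}

#' Project fitted components onto an independent cohort
#'
#' Back-reconstructs the loadings of a fitted decomposition on a new
#' cohort's feature matrices and correlates every component's projected
#' loadings with that cohort's symptom scores — the cross-cohort
#' replication check for a reference-associated component.
#'
#' @param model a [fuse()] result (or a list of per-modality source
#'   matrices).
#' @param fms_new list of per-modality [feature_matrix()] objects for the
#'   new cohort, voxel-aligned with the sources.
#' @param scores symptom scores for the new cohort.
#' @return list with `table` (data frame: modality, component, r, p) and
#'   `loadings` (per-modality back-reconstructed matrices).
#' @export
project_components <- function(model, fms_new, scores) {
  sources <- if (inherits(model, "fusion_model")) model$sources else model
  modalities <- if (inherits(model, "fusion_model")) model$modalities
                else paste0("modality", seq_along(sources))
  loadings <- Map(back_reconstruct, sources, fms_new)
  tabs <- lapply(seq_along(loadings), function(k) {
    A <- loadings[[k]]
    res <- lapply(seq_len(ncol(A)), function(m)
      correlate_loadings(A[, m], scores))
    data.frame(modality = modalities[k], component = seq_len(ncol(A)),
               r = vapply(res, `[[`, 0, "r"),
               p = vapply(res, `[[`, 0, "p"))
  })
  list(table = do.call(rbind, tabs), loadings = loadings)
}
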