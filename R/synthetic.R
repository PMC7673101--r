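#' Generate a synthetic phenotype table
#'
#' Builds a cohort table with the fields used throughout the pipeline:
#' subject id, acquisition site, diagnostic group (one control group plus
#' named patient subtypes), age, handedness, full-scale IQ, ADOS total and
#' its three subdomain scores (communication, social interaction,
#' stereotyped behaviors), SRS total, and mean framewise displacement.
#' Symptom scores are missing (`NA`) for controls; for patients the ADOS
#' total is the sum of the three subdomains by construction.
#'
#' @param n_per_group named integer vector of group sizes. The group named
#'   `"control"` is treated as the control group; every other name defines a
#'   patient subtype. All counts must be at least 2.
#' @param n_sites number of acquisition sites (at least 2). Subjects are
#'   assigned round-robin with a random permutation so sites end up balanced
#'   but not systematically ordered.
#' @param score_params optional list overriding the score distributions.
#'   Elements (all optional): `age_mean`, `age_sd`, `iq_mean`, `iq_sd`,
#'   `srs_mean`, `srs_sd`, `fd_mean`, `fd_sd`, `hand_probs` (length-3
#'   probabilities for R/L/M), and `ados` — a list of per-subdomain
#'   `c(mean, sd, min, max)` rows named `comm`, `social`, `stereo`.
#' @param seed integer seed; identical arguments and seed reproduce the
#'   table exactly.
#' @return a `data.frame` with columns `subject_id`, `site`, `group`,
#'   `age`, `handedness`, `iq`, `ados_comm`, `ados_social`, `ados_stereo`,
#'   `ados_total`, `srs`, `mean_fd`.
#' @examples
#' coh <- make_cohort(c(control = 20, aspergers = 20), n_sites = 3, seed = 1)
#' table(coh$group, coh$site)
#' @export
make_cohort <- function(n_per_group, n_sites, score_params = list(), seed = 1) {
  n_per_group <- unlist(n_per_group)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be a named vector of group sizes")
  if (any(n_per_group < 2)) stop("all group counts must be at least 2")
  if (n_sites < 2) stop("n_sites must be at least 2")

  p <- list(
    age_mean = 12, age_sd = 4, iq_mean = 106, iq_sd = 17,
    srs_mean = 87, srs_sd = 30, fd_mean = 0.2, fd_sd = 0.15,
    hand_probs = c(R = 0.78, L = 0.12, M = 0.10),
    ados = list(comm  = c(mean = 4, sd = 1.5, min = 1, max = 8),
                social = c(mean = 6, sd = 2.0, min = 1, max = 14),
                stereo = c(mean = 2, sd = 1.2, min = 0, max = 8))
  )
  p[names(score_params)] <- score_params

  set.seed(seed)
  n <- sum(n_per_group)
  group <- factor(rep(names(n_per_group), n_per_group),
                  levels = names(n_per_group))
  is_patient <- group != "control"

  # round-robin site assignment, then a random permutation as jitter
  site <- factor(paste0("site", rep_len(seq_len(n_sites), n))[sample.int(n)],
                 levels = paste0("site", seq_len(n_sites)))

  draw_clamped <- function(n, mean, sd, lo, hi, digits = 1)
    pmin(pmax(round(stats::rnorm(n, mean, sd), digits), lo), hi)
  draw_subdomain <- function(spec)
    draw_clamped(n, spec["mean"], spec["sd"], spec["min"], spec["max"],
                 digits = 0)

  comm <- draw_subdomain(p$ados$comm)
  social <- draw_subdomain(p$ados$social)
  stereo <- draw_subdomain(p$ados$stereo)
  comm[!is_patient] <- NA
  social[!is_patient] <- NA
  stereo[!is_patient] <- NA
  srs <- round(stats::rnorm(n, p$srs_mean, p$srs_sd))
  srs[!is_patient] <- NA

  out <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    site = site,
    group = group,
    age = draw_clamped(n, p$age_mean, p$age_sd, 5, 35),
    handedness = factor(sample(c("R", "L", "M"), n, replace = TRUE,
                               prob = p$hand_probs),
                        levels = c("R", "L", "M")),
    iq = round(stats::rnorm(n, p$iq_mean, p$iq_sd)),
    ados_comm = comm,
    ados_social = social,
    ados_stereo = stereo,
    ados_total = comm + social + stereo,
    srs = srs,
    mean_fd = abs(stats::rnorm(n, p$fd_mean, p$fd_sd)),
    stringsAsFactors = FALSE
  )
  out
}

#' Generate two-modality feature matrices with planted covarying structure
#'
#' Simulates the generative model behind the fusion pipeline: for each
#' modality `k`, `X_k = A_k S_k + E_k` with shared subject loadings across
#' modalities, super-Gaussian (Laplace) source maps, and i.i.d. Gaussian
#' voxel noise. One designated reference component is planted so that:
#'
#' * its subject loadings correlate with the cohort's ADOS total at exactly
#'   `ref_r` among patients (Gram-Schmidt construction, so the empirical
#'   correlation in the noise-free loadings equals the target);
#' * patients receive a mean loading offset relative to controls
#'   (`group_effect`), giving downstream group-difference tests a planted
#'   effect;
#' * its source map carries a shared "common" region with positive weights
#'   in both modalities.
#'
#' When `unique_spec` names patient subtypes, each listed subtype gets one
#' additional component whose modality-1 source is negative inside a
#' subtype-specific voxel block (disjoint from the common region and from
#' other subtypes' blocks) and whose loadings follow the reference loadings
#' inside that subtype only. Site offsets and linear age/IQ trends are
#' injected through dedicated nuisance loading columns, so the model
#' identity `X = A S` holds exactly at `noise_sd = 0` while covariate
#' residualization still has real structure to remove.
#'
#' @param cohort phenotype table from [make_cohort()].
#' @param n_voxels voxels per modality.
#' @param M number of components; must satisfy
#'   `M < min(n_subjects, n_voxels)` and leave room for the planted
#'   components (`M >= 2 + length(unique_spec)`).
#' @param ref_r target loading/ADOS correlation among patients, `|ref_r| < 1`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param unique_spec character vector of subtype names that receive a
#'   unique negative modality-1 region, or `NULL` for none.
#' @param seed integer seed.
#' @param group_effect mean loading offset of patients vs controls on the
#'   reference component (in loading SD units).
#' @param ref_strength scale of the planted reference source map relative
#'   to the background components; values below 1 make the reference
#'   covariation weak compared to unsupervised structure.
#' @param site_sd,age_beta,iq_beta nuisance effect sizes (site offsets per
#'   loading SD; slopes per year / IQ point).
#' @param loading_noise_sd standard deviation of independent per-modality
#'   perturbations of the subject loadings. 0 (the default) gives
#'   perfectly covarying modalities; positive values weaken the
#'   cross-modal coupling, emulating modalities that share components
#'   imperfectly.
#' @param truth optional `synthetic_truth` from a previous call: its source
#'   maps, component layout and region masks are reused and only new
#'   subject loadings and noise are drawn, emulating an independent cohort
#'   sampled from the same underlying patterns.
#' @return list with `falff` and `gmv` [feature_matrix()] objects and
#'   `truth`, a `synthetic_truth` list holding `mixing_per_modality`,
#'   `sources_per_modality`, `ref_component_index`,
#'   `planted_ref_correlation`, `common_mask`, `unique_region_masks`,
#'   `noise_sd` and `seed`.
#' @export
make_multimodal_data <- function(cohort, n_voxels, M, ref_r = 0.5,
                                 noise_sd = 0.25, unique_spec = NULL,
                                 seed = 1, group_effect = 1,
                                 ref_strength = 1, site_sd = 0.5,
                                 age_beta = 0.05, iq_beta = 0.02,
                                 loading_noise_sd = 0, truth = NULL) {
  n <- nrow(cohort)
  if (!is.null(truth)) {
    n_voxels <- ncol(truth$sources_per_modality[[1]])
    M <- nrow(truth$sources_per_modality[[1]])
    unique_spec <- names(truth$unique_region_masks)
    if (length(unique_spec) == 0L) unique_spec <- NULL
  }
  if (M >= n) stop("M must be smaller than the number of subjects")
  if (M >= n_voxels) stop("M must be smaller than the number of voxels")
  if (abs(ref_r) >= 1) stop("|ref_r| must be below 1")
  subtypes <- setdiff(levels(cohort$group), "control")
  if (!is.null(unique_spec)) {
    unique_spec <- as.character(unique_spec)
    if (!all(unique_spec %in% subtypes))
      stop("unique_spec names must be patient subtypes present in the cohort")
  }
  n_unique <- length(unique_spec)
  if (M < 2 + n_unique)
    stop("M must be at least 2 + length(unique_spec)")

  set.seed(seed)
  is_patient <- cohort$group != "control"
  n_pat <- sum(is_patient)

  # voxel layout: one common block, one candidate unique block per subtype
  if (is.null(truth)) {
    block <- max(10L, floor(n_voxels * 0.05))
    common_mask <- rep(FALSE, n_voxels)
    common_mask[seq_len(block)] <- TRUE
    unique_masks <- lapply(seq_along(subtypes), function(i) {
      m <- rep(FALSE, n_voxels)
      m[(i * block + 1L):((i + 1L) * block)] <- TRUE
      m
    })
    names(unique_masks) <- subtypes
    if ((length(subtypes) + 1L) * block >= n_voxels)
      stop("n_voxels too small for the requested block layout")
    ref_idx <- 1L
    unique_idx <- if (n_unique) seq.int(2L, 1L + n_unique) else integer(0)
  } else {
    common_mask <- truth$common_mask
    unique_masks <- truth$unique_region_masks
    ref_idx <- truth$ref_component_index
    unique_idx <- unname(truth$unique_component_index)
  }

  # ---- loadings (shared across modalities) -------------------------------
  A <- matrix(stats::rnorm(n * M), n, M)

  # reference column: exact target correlation with ADOS among patients
  z <- scale(cohort$ados_total[is_patient])[, 1]
  e <- stats::rnorm(n_pat)
  e <- stats::residuals(stats::lm(e ~ z))
  e <- e / stats::sd(e)
  refcol <- numeric(n)
  refcol[is_patient] <- group_effect + ref_r * z + sqrt(1 - ref_r^2) * e
  refcol[!is_patient] <- stats::rnorm(n - n_pat)
  A[, ref_idx] <- refcol

  # unique components: follow the reference loadings inside their subtype
  for (i in seq_along(unique_spec)) {
    inS <- cohort$group == unique_spec[i]
    col <- stats::rnorm(n, sd = 0.05)
    col[inS] <- refcol[inS]
    A[, unique_idx[i]] <- col
  }

  # nuisance structure on the remaining columns (site, age, IQ)
  spare <- setdiff(seq_len(M), c(ref_idx, unique_idx))
  if (site_sd > 0 && length(spare) >= 1) {
    offs <- stats::rnorm(nlevels(cohort$site), sd = site_sd)
    A[, spare[1]] <- A[, spare[1]] + offs[as.integer(cohort$site)]
  }
  if (age_beta != 0 && length(spare) >= 2)
    A[, spare[2]] <- A[, spare[2]] + age_beta * (cohort$age - mean(cohort$age))
  if (iq_beta != 0 && length(spare) >= 3)
    A[, spare[3]] <- A[, spare[3]] + iq_beta * (cohort$iq - mean(cohort$iq))

  # ---- source maps -------------------------------------------------------
  make_sources <- function(modality1) {
    S <- matrix(rlaplace(M * n_voxels), M, n_voxels)
    ref_row <- rlaplace(n_voxels, b = 0.3)
    ref_row[common_mask] <- 3 + abs(stats::rnorm(block, sd = 0.3))
    for (sub in subtypes) ref_row[unique_masks[[sub]]] <- 0
    S[ref_idx, ] <- ref_strength * ref_row
    for (i in seq_along(unique_spec)) {
      u_row <- numeric(n_voxels)
      if (modality1)
        u_row[unique_masks[[unique_spec[i]]]] <-
          -(3 + abs(stats::rnorm(block, sd = 0.3)))
      u_row <- u_row + rlaplace(n_voxels, b = 0.05)
      S[unique_idx[i], ] <- ref_strength * u_row
    }
    S
  }
  if (is.null(truth)) {
    S1 <- make_sources(TRUE)
    S2 <- make_sources(FALSE)
  } else {
    S1 <- truth$sources_per_modality[[1]]
    S2 <- truth$sources_per_modality[[2]]
  }

  A1 <- A
  A2 <- A
  if (loading_noise_sd > 0) {
    A1 <- A + matrix(stats::rnorm(n * M, sd = loading_noise_sd), n, M)
    A2 <- A + matrix(stats::rnorm(n * M, sd = loading_noise_sd), n, M)
  }
  X1 <- A1 %*% S1
  X2 <- A2 %*% S2
  if (noise_sd > 0) {
    X1 <- X1 + matrix(stats::rnorm(n * n_voxels, sd = noise_sd), n, n_voxels)
    X2 <- X2 + matrix(stats::rnorm(n * n_voxels, sd = noise_sd), n, n_voxels)
  }

  truth <- structure(list(
    mixing_per_modality = list(A1, A2),
    sources_per_modality = list(S1, S2),
    ref_component_index = ref_idx,
    unique_component_index = stats::setNames(unique_idx, unique_spec),
    planted_ref_correlation = ref_r,
    common_mask = common_mask,
    unique_region_masks = unique_masks[unique_spec %||% character(0)],
    noise_sd = noise_sd,
    seed = seed
  ), class = "synthetic_truth")

  list(
    falff = feature_matrix(X1, cohort$subject_id, "falff",
                           provenance = "synthetic"),
    gmv = feature_matrix(X2, cohort$subject_id, "gmv",
                         provenance = "synthetic"),
    truth = truth
  )
}

#' Generate a synthetic 4D fMRI volume with a known spectrum
#'
#' Each voxel's time series is a mixture of sinusoids plus white noise;
#' component entries may carry a voxel mask to restrict where they appear.
#' A rigid-body motion trace (3 translations in mm, 3 rotations in radians)
#' is generated alongside, for exercising motion QC.
#'
#' @param n_timepoints number of volumes (time points).
#' @param tr repetition time in seconds.
#' @param components list of `list(freq = Hz, amp = amplitude,
#'   mask = NULL or logical array over the grid)`; `mask = NULL` applies
#'   the component everywhere. All frequencies must lie below the Nyquist
#'   frequency `1 / (2 * tr)`.
#' @param noise_sd white-noise standard deviation.
#' @param motion_spec `"still"` (all-zero trace), or a list
#'   `list(type = "walk", step_sd_mm = , step_sd_rad = )` for a random walk,
#'   or `list(type = "spike", t = , delta = 6-vector)` for a single jump.
#' @param seed integer seed.
#' @param grid_dim 3D grid, default `c(12, 12, 12)`.
#' @return list with `volume` (4D array, grid x time) and `motion`
#'   (a [motion_trace()]).
#' @export
make_fmri_timeseries <- function(n_timepoints, tr, components,
                                 noise_sd = 0, motion_spec = "still",
                                 seed = 1, grid_dim = c(12, 12, 12)) {
  if (tr <= 0) stop("tr must be positive")
  nyquist <- 1 / (2 * tr)
  for (cmp in components)
    if (cmp$freq >= nyquist)
      stop(sprintf("component frequency %.4g Hz is at or above Nyquist (%.4g Hz)",
                   cmp$freq, nyquist))
  set.seed(seed)
  nv <- prod(grid_dim)
  tt <- (seq_len(n_timepoints) - 1L) * tr

  series <- matrix(0, n_timepoints, nv)
  for (cmp in components) {
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- cmp$amp * sin(2 * pi * cmp$freq * tt + phase)
    idx <- if (is.null(cmp$mask)) seq_len(nv) else which(as.vector(cmp$mask))
    series[, idx] <- series[, idx] + wave
  }
  if (noise_sd > 0)
    series <- series + matrix(stats::rnorm(n_timepoints * nv, sd = noise_sd),
                              n_timepoints, nv)
  vol <- array(t(series), dim = c(grid_dim, n_timepoints))

  motion <- if (identical(motion_spec, "still")) {
    matrix(0, n_timepoints, 6)
  } else if (identical(motion_spec$type, "walk")) {
    steps <- cbind(
      matrix(stats::rnorm(n_timepoints * 3,
                          sd = motion_spec$step_sd_mm %||% 0.05),
             n_timepoints, 3),
      matrix(stats::rnorm(n_timepoints * 3,
                          sd = motion_spec$step_sd_rad %||% 0.001),
             n_timepoints, 3))
    steps[1, ] <- 0
    apply(steps, 2, cumsum)
  } else if (identical(motion_spec$type, "spike")) {
    m <- matrix(0, n_timepoints, 6)
    m[motion_spec$t:n_timepoints, ] <-
      matrix(motion_spec$delta, n_timepoints - motion_spec$t + 1L, 6,
             byrow = TRUE)
    m
  } else stop("unknown motion_spec")

  list(volume = vol, motion = motion_trace(motion, rotation_unit = "radians"))
}

#' Generate paired cohorts with subtype-specific score-generating networks
#'
#' Fixture generator for cross-cohort prediction specificity: each subtype
#' has its own disjoint triplet of regions (functional-positive,
#' functional-negative, structural-positive), and a subject's symptom score
#' is a fixed linear combination of the mean feature values over that
#' subtype's own regions plus noise. Two independent cohorts are drawn from
#' the same generative rule, so a model trained on cohort A for subtype `s`
#' is predictive on cohort B only for subtype `s`.
#'
#' @param n_per_subtype subjects per subtype (same in both cohorts).
#' @param n_subtypes number of subtypes.
#' @param n_voxels voxels per modality.
#' @param effect coefficient scale linking region means to the score.
#' @param noise_sd score noise standard deviation.
#' @param seed integer seed.
#' @return list with cohorts `A` and `B` (each a list per subtype of
#'   `list(falff =, gmv =, scores =)`) and `masks`, a list per subtype of
#'   logical vectors `fpos`, `fneg`, `spos`.
#' @export
make_specificity_cohorts <- function(n_per_subtype = 40, n_subtypes = 3,
                                     n_voxels = 300, effect = 3,
                                     noise_sd = 1, seed = 1) {
  set.seed(seed)
  block <- max(5L, floor(n_voxels / (n_subtypes * 3L + 2L)))
  masks <- lapply(seq_len(n_subtypes), function(s) {
    at <- function(j) {
      m <- rep(FALSE, n_voxels)
      m[((s - 1L) * 3L * block + (j - 1L) * block + 1L):
          ((s - 1L) * 3L * block + j * block)] <- TRUE
      m
    }
    list(fpos = at(1), fneg = at(2), spos = at(3))
  })
  names(masks) <- paste0("subtype", seq_len(n_subtypes))

  draw_cohort <- function(tag) {
    out <- lapply(seq_len(n_subtypes), function(s) {
      X1 <- matrix(stats::rnorm(n_per_subtype * n_voxels),
                   n_per_subtype, n_voxels)
      X2 <- matrix(stats::rnorm(n_per_subtype * n_voxels),
                   n_per_subtype, n_voxels)
      m <- masks[[s]]
      sc <- effect * (rowMeans(X1[, m$fpos, drop = FALSE]) -
                        rowMeans(X1[, m$fneg, drop = FALSE]) +
                        rowMeans(X2[, m$spos, drop = FALSE])) *
        sqrt(sum(m$fpos))   # region means have SD 1/sqrt(block)
      ids <- sprintf("%s_%s_sub%03d", tag, names(masks)[s],
                     seq_len(n_per_subtype))
      list(falff = feature_matrix(X1, ids, "falff", provenance = "synthetic"),
           gmv = feature_matrix(X2, ids, "gmv", provenance = "synthetic"),
           scores = sc + stats::rnorm(n_per_subtype, sd = noise_sd))
    })
    names(out) <- names(masks)
    out
  }
  list(A = draw_cohort("A"), B = draw_cohort("B"), masks = masks)
}
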