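#' Validated pipeline configuration
#'
#' Collects the tunable parameters of the analysis pipeline and validates
#' them eagerly, so a malformed configuration fails before any
#' computation starts.
#'
#' @param M model order (number of joint components), at least 2.
#' @param lam reference weight for [mccar()], non-negative.
#' @param z threshold on |Z| for network masks, positive.
#' @param q FDR level, strictly inside (0, 1).
#' @param qc_mean_fd_max,qc_trans_max,qc_rot_max motion-QC thresholds
#'   (mm, mm, degrees).
#' @param seed integer seed for all random stages.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(M = 30, lam = 0.5, z = 2, q = 0.05,
                          qc_mean_fd_max = 1.0, qc_trans_max = 2.0,
                          qc_rot_max = 1.0, seed = 1) {
  if (M < 2) stop("M must be at least 2")
  if (lam < 0) stop("lam must be non-negative")
  if (z <= 0) stop("z must be positive")
  if (q <= 0 || q >= 1) stop("q must lie strictly inside (0, 1)")
  if (qc_mean_fd_max <= 0 || qc_trans_max <= 0 || qc_rot_max <= 0)
    stop("QC thresholds must be positive")
  structure(list(M = M, lam = lam, z = z, q = q,
                 qc_mean_fd_max = qc_mean_fd_max,
                 qc_trans_max = qc_trans_max, qc_rot_max = qc_rot_max,
                 seed = seed),
            class = "fusion_config")
}

# residualize patients and controls with coefficients fitted on the
# analysis (patient) rows only; the design is built over the full cohort
# so indicator columns stay consistent between the two groups
residualize_split <- function(fm, covariates, fit_rows) {
  design <- covariate_design(covariates)
  X <- cbind(1, design)
  qx <- qr(X[fit_rows, , drop = FALSE])
  if (qx$rank < ncol(X))
    stop("rank-deficient covariate design in the analysis group")
  beta <- qr.coef(qx, fm$values[fit_rows, , drop = FALSE])
  vals <- fm$values - X %*% beta
  feature_matrix(vals, fm$subject_ids, fm$modality, fm$mask,
                 c(fm$provenance, "residualize_covariates"))
}

#' Run one group's fusion analysis end to end
#'
#' Executes the per-group workflow: motion QC on the phenotype table's
#' mean-FD column, covariate residualization (age, IQ, handedness, site;
#' coefficients fitted on the analysis group and applied to controls),
#' sum-of-squares normalization, reference-guided fusion on the patient
#' group with ADOS total as reference, selection of the
#' reference-associated joint component, |Z| thresholding of its source
#' maps, back-reconstruction of control loadings, patient-vs-control
#' loading tests, and clinical correlations (ADOS total, the three
#' subdomains, SRS) with FDR adjustment per modality family.
#'
#' @param pheno phenotype table ([make_cohort()] layout).
#' @param fms list of subject-aligned raw [feature_matrix()] objects
#'   (modality 1 functional, modality 2 structural).
#' @param group `"patients"` for all non-control subjects, or one subtype
#'   name.
#' @param config a [fusion_config()].
#' @return a result bundle: `model`, `selection`, `masks` (per modality:
#'   `positive`, `negative`, `zmap`), `group_stats`, `clinical`,
#'   `loadings` (patients and controls for the selected component),
#'   `qc_excluded`, `group`, `config`.
#' @export
run_group_analysis <- function(pheno, fms, group = "patients",
                               config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  qc_pass <- pheno$mean_fd <= config$qc_mean_fd_max
  excluded <- pheno$subject_id[!qc_pass]
  pheno <- pheno[qc_pass, , drop = FALSE]
  fms <- lapply(fms, function(fm)
    feature_matrix(fm$values[qc_pass, , drop = FALSE],
                   fm$subject_ids[qc_pass], fm$modality, fm$mask,
                   fm$provenance))

  is_control <- pheno$group == "control"
  in_group <- if (identical(group, "patients")) !is_control
              else pheno$group == group
  if (!any(in_group)) stop("selected group is empty after QC")
  if (!any(is_control)) stop("no controls remain after QC")

  covs <- pheno[, intersect(c("age", "iq", "handedness", "site"),
                            names(pheno)), drop = FALSE]
  resid <- lapply(fms, residualize_split, covariates = covs,
                  fit_rows = in_group)

  # one scaling factor per modality, fitted on the analysis group
  scl <- vapply(resid, function(fm)
    1 / sqrt(mean(fm$values[in_group, , drop = FALSE]^2)), numeric(1))
  resid <- Map(function(fm, s)
    feature_matrix(fm$values * s, fm$subject_ids, fm$modality, fm$mask,
                   c(fm$provenance, "normalize_ssq")), resid, scl)

  pat <- lapply(resid, function(fm)
    feature_matrix(fm$values[in_group, , drop = FALSE],
                   fm$subject_ids[in_group], fm$modality, fm$mask,
                   fm$provenance))
  ctl <- lapply(resid, function(fm)
    feature_matrix(fm$values[is_control, , drop = FALSE],
                   fm$subject_ids[is_control], fm$modality, fm$mask,
                   fm$provenance))

  ref <- pheno$ados_total[in_group]
  model <- fuse(pat, ref, M = config$M, lam = config$lam,
                seed = config$seed)
  sel <- select_reference_component(model, q = config$q)

  masks <- lapply(seq_along(model$sources), function(k)
    zscore_threshold(model$sources[[k]][sel$component, ], config$z))
  names(masks) <- model$modalities

  ctl_loadings <- lapply(seq_along(ctl), function(k)
    back_reconstruct(model$sources[[k]], ctl[[k]]))

  group_stats <- lapply(seq_along(model$mixing), function(k) {
    pl <- model$mixing[[k]][, sel$component]
    cl <- ctl_loadings[[k]][, sel$component]
    gd <- group_difference(c(pl, cl),
                           rep(c("patient", "control"),
                               c(length(pl), length(cl))))
    c(list(modality = model$modalities[k]), gd)
  })

  clin_scores <- c("ados_total", "ados_comm", "ados_social",
                   "ados_stereo", "srs")
  clin <- do.call(rbind, lapply(seq_along(model$mixing), function(k) {
    pl <- model$mixing[[k]][, sel$component]
    do.call(rbind, lapply(clin_scores, function(sc) {
      cl <- correlate_loadings(pl, pheno[[sc]][in_group])
      data.frame(modality = model$modalities[k], score = sc,
                 r = cl$r, p_raw = cl$p, n = cl$n)
    }))
  }))
  clin$p_fdr <- NA_real_
  for (k in unique(clin$modality)) {
    rows <- clin$modality == k & clin$score != "ados_total"
    clin$p_fdr[rows] <- fdr_adjust(clin$p_raw[rows], config$q)$p_adjusted
  }

  list(model = model, selection = sel, masks = masks,
       group_stats = group_stats, clinical = clin,
       loadings = list(patients = lapply(model$mixing, function(A)
         A[, sel$component]),
         controls = lapply(ctl_loadings, function(A) A[, sel$component])),
       features = list(patients = pat, controls = ctl),
       qc_excluded = excluded, group = group, config = config)
}

# set algebra on the per-subtype thresholded masks: the common network is
# the intersection across subtypes; a subtype's unique network is its own
# mask minus the union of the others'
common_unique_masks <- function(mask_list) {
  combine <- function(side) {
    per <- lapply(mask_list, `[[`, side)
    common <- Reduce(`&`, per)
    uniq <- lapply(seq_along(per), function(i)
      per[[i]] & !Reduce(`|`, per[-i]))
    names(uniq) <- names(mask_list)
    list(common = common, unique = uniq)
  }
  list(positive = combine("positive"), negative = combine("negative"))
}

#' Run the full multi-group study
#'
#' Orchestrates the complete design on one discovery cohort: a fusion
#' analysis of the whole patient group followed by one per subtype;
#' common networks (mask intersection across subtypes) and
#' subtype-unique networks (mask set-difference) per modality and sign;
#' the per-subtype clinical-correlation table; and — when an independent
#' replication cohort is supplied — per-subtype symptom-prediction models
#' evaluated across all subtype pairings ([cross_cohort_specificity()]).
#'
#' @param pheno,fms discovery-cohort phenotype table and raw feature
#'   matrices.
#' @param config a [fusion_config()].
#' @param replication optional list with `pheno` and `fms` for an
#'   independent cohort; per-cohort residualization and scaling are
#'   applied there before prediction.
#' @param score symptom score predicted in the specificity analysis
#'   (`"ados_total"` or `"srs"`).
#' @return study bundle: `whole_group`, `subtypes` (named list of
#'   [run_group_analysis()] bundles), `networks` (per modality:
#'   common/unique masks by sign), `clinical` (stacked correlation
#'   table), `specificity` (or `NULL`).
#' @export
run_full_study <- function(pheno, fms, config = fusion_config(),
                           replication = NULL, score = "ados_total") {
  subtype_names <- setdiff(levels(droplevels(factor(pheno$group))),
                           "control")
  if (length(subtype_names) < 2L) stop("need at least 2 subtypes")

  whole <- run_group_analysis(pheno, fms, "patients", config)
  subs <- lapply(subtype_names, function(s)
    run_group_analysis(pheno, fms, s, config))
  names(subs) <- subtype_names

  networks <- lapply(seq_along(fms), function(k) {
    ml <- lapply(subs, function(b) b$masks[[k]])
    common_unique_masks(ml)
  })
  names(networks) <- vapply(fms, `[[`, "", "modality")

  clinical <- do.call(rbind, lapply(subtype_names, function(s)
    cbind(subtype = s, subs[[s]]$clinical)))

  specificity <- NULL
  if (!is.null(replication)) {
    models <- lapply(subtype_names, function(s) {
      b <- subs[[s]]
      masks <- list(fpos = b$masks[[1]]$positive,
                    fneg = b$masks[[1]]$negative,
                    spos = b$masks[[2]]$positive)
      if (any(vapply(masks, sum, 0L) == 0L)) return(NULL)
      feats <- extract_roi_features(b$features$patients[[1]],
                                    b$features$patients[[2]], masks)
      ids <- b$features$patients[[1]]$subject_ids
      fit_symptom_model(feats,
                        pheno[[score]][match(ids, pheno$subject_id)],
                        masks = masks,
                        meta = list(subtype = s, score = score))
    })
    names(models) <- subtype_names
    models <- Filter(Negate(is.null), models)

    rp <- replication
    rcovs <- rp$pheno[, intersect(c("age", "iq", "handedness", "site"),
                                  names(rp$pheno)), drop = FALSE]
    cohort_b <- lapply(subtype_names, function(s) {
      rows <- rp$pheno$group == s
      if (!any(rows)) return(NULL)
      prep <- lapply(rp$fms, function(fm)
        residualize_split(fm, rcovs, fit_rows = rows))
      prep <- normalize_ssq(lapply(prep, function(fm)
        feature_matrix(fm$values[rows, , drop = FALSE],
                       fm$subject_ids[rows], fm$modality, fm$mask,
                       fm$provenance)))
      list(falff = prep[[1]], gmv = prep[[2]],
           scores = rp$pheno[[score]][rows])
    })
    names(cohort_b) <- subtype_names
    specificity <- cross_cohort_specificity(models,
                                            Filter(Negate(is.null),
                                                   cohort_b))
  }

  list(whole_group = whole, subtypes = subs, networks = networks,
       clinical = clinical, specificity = specificity, config = config)
}
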