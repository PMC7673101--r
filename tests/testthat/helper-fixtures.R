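# shared fixtures and independent oracles used across the test files

# residualize covariates and equalize mean sums of squares, the standard
# preparation before fusion
prep_fusion_inputs <- function(dat, cohort, patients = cohort$group != "control") {
  covs <- cohort[patients, c("age", "iq", "handedness", "site")]
  fms <- list(
    feature_matrix(dat$falff$values[patients, , drop = FALSE],
                   cohort$subject_id[patients], "falff"),
    feature_matrix(dat$gmv$values[patients, , drop = FALSE],
                   cohort$subject_id[patients], "gmv"))
  normalize_ssq(lapply(fms, residualize_covariates, covariates = covs))
}

# one full synthetic fit: cohort -> data -> fusion -> selection
fit_synthetic <- function(seed, n_patients = 120, n_voxels = 2000, M = 8,
                          ref_r = 0.5, noise_sd = 0.25, lam = 0.5, ...) {
  coh <- make_cohort(c(control = 20, subtype_a = n_patients),
                     n_sites = 3, seed = seed)
  dat <- make_multimodal_data(coh, n_voxels = n_voxels, M = M,
                              ref_r = ref_r, noise_sd = noise_sd,
                              seed = seed + 1000L, ...)
  pats <- coh$group != "control"
  fms <- prep_fusion_inputs(dat, coh)
  model <- fuse(fms, coh$ados_total[pats], M = M, lam = lam, seed = seed)
  list(cohort = coh, data = dat, fms = fms, model = model,
       selection = select_reference_component(model),
       ref = coh$ados_total[pats], patients = pats)
}

# brute-force DFT amplitude spectrum: direct evaluation of the transform
# definition, independent of stats::fft
brute_force_amplitude <- function(x) {
  n <- length(x)
  k <- 0:(floor(n / 2))
  vapply(k, function(kk) {
    w <- -2 * pi * kk * (0:(n - 1)) / n
    Mod(sum(x * complex(real = cos(w), imaginary = sin(w))))
  }, numeric(1))
}

# fALFF recomputed from the brute-force spectrum
brute_force_falff <- function(x, tr, low = c(0.01, 0.08), cap = 0.25) {
  amp <- brute_force_amplitude(x)
  freq <- (0:(floor(length(x) / 2))) / (length(x) * tr)
  cap <- min(cap, 1 / (2 * tr))
  den <- freq > 0 & freq <= cap
  num <- den & freq >= low[1] & freq <= low[2]
  sum(amp[num]) / sum(amp[den])
}

# Laplace draws via the exponential-mixture representation (independent
# of the package's own sampler)
rlaplace_test <- function(n, b = 1) {
  sample(c(-1, 1), n, replace = TRUE) * stats::rexp(n, rate = 1 / b)
}

# Amari-style separation index of a permutation-scaled matrix; 0 for a
# perfect permutation x diagonal, larger with residual mixing
amari_index <- function(P) {
  P <- abs(P)
  M <- nrow(P)
  row_part <- sum(rowSums(P / apply(P, 1, max)) - 1)
  col_part <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (row_part + col_part) / (2 * M * (M - 1))
}
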