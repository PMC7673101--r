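test_that("PCA whitening recovers exact low rank and matches the SVD error", {
  set.seed(20)
  A <- matrix(rnorm(40 * 2), 40, 2) %*% matrix(rnorm(2 * 30), 2, 30)
  pw <- pca_whiten(A, 2)
  Ac <- sweep(A, 2, colMeans(A))
  expect_lt(norm(pw$scores %*% t(pw$basis) - Ac, "F"), 1e-10)

  X <- A + matrix(rnorm(40 * 30, sd = 0.5), 40, 30)
  pw2 <- pca_whiten(X, 4)
  # whitening contract: orthogonal, unit-variance, zero-mean scores
  expect_equal(crossprod(pw2$scores) / 39, diag(4), tolerance = 1e-10)
  expect_equal(colMeans(pw2$scores), rep(0, 4), tolerance = 1e-10)
  # reconstruction error equals the energy in the discarded singular values
  Xc <- sweep(X, 2, colMeans(X))
  err <- norm(Xc - pw2$scores %*% t(pw2$basis), "F")^2
  expect_equal(err, sum(pw2$d[-(1:4)]^2), tolerance = 1e-8)
  expect_error(pca_whiten(X, 41), "M must not exceed")
})

test_that("MCCA on identical sets reaches perfect column correlations", {
  set.seed(21)
  Y <- pca_whiten(matrix(rnorm(50 * 200), 50, 200), 4)$scores
  mc <- mccar(list(Y, Y), ref = rnorm(50), lam = 0, seed = 1)
  cc <- abs(diag(cor(mc$loadings[[1]], mc$loadings[[2]])))
  expect_true(all(cc > 1 - 1e-6))
})

test_that("lambda = 0 canonical correlations match the generalized-eigenvalue oracle", {
  set.seed(22)
  for (i in 1:10) {
    n <- 50 + 5 * i
    X1 <- matrix(rnorm(n * 30), n, 30)
    X2 <- X1 %*% matrix(rnorm(30 * 30), 30, 30) +
      matrix(rnorm(n * 30), n, 30)
    M <- 4
    p1 <- pca_whiten(X1, M); p2 <- pca_whiten(X2, M)
    mc <- mccar(list(p1$scores, p2$scores), ref = rnorm(n), lam = 0,
                seed = i)
    achieved <- sort(abs(diag(cor(mc$loadings[[1]], mc$loadings[[2]]))),
                     decreasing = TRUE)
    # oracle: canonical correlations of whitened sets are the singular
    # values of their cross-correlation matrix
    oracle <- svd(cor(p1$scores, p2$scores))$d
    expect_lt(max(abs(achieved - oracle)), 1e-4)
  }
})

test_that("the MCCA objective is monotone non-decreasing within components", {
  set.seed(23)
  Y1 <- pca_whiten(matrix(rnorm(60 * 100), 60, 100), 5)$scores
  Y2 <- pca_whiten(matrix(rnorm(60 * 100), 60, 100), 5)$scores
  mc <- mccar(list(Y1, Y2), ref = rnorm(60), lam = 0.5, seed = 2)
  for (comp in unique(mc$objective_log$component)) {
    obj <- mc$objective_log$objective[mc$objective_log$component == comp]
    expect_true(all(diff(obj) > -1e-9))
  }
  # M = 1 special case agrees with the first canonical correlation
  mc1 <- mccar(list(Y1[, 1:3], Y2[, 1:3]), ref = rnorm(60), lam = 0,
               seed = 3)
  expect_equal(abs(cor(mc1$loadings[[1]][, 1], mc1$loadings[[2]][, 1])),
               svd(cor(Y1[, 1:3], Y2[, 1:3]))$d[1], tolerance = 1e-6)
})

test_that("joint ICA separates super-Gaussian sources up to permutation and sign", {
  set.seed(24)
  M <- 6; V <- 3000
  S <- matrix(rlaplace_test(M * V), M, V)
  A <- matrix(rnorm(M * M), M, M)
  res <- joint_ica(list(A %*% S), seed = 1)
  expect_gt(abs(det(res$W)), 1e-8)
  cc <- abs(cor(t(res$sources[[1]]), t(S)))
  expect_true(all(apply(cc, 2, max) > 0.99))
  expect_lt(amari_index(res$W %*% A), 0.05)

  # already-independent input: unmixing is permutation x diagonal
  res2 <- joint_ica(list(S), seed = 2)
  expect_lt(amari_index(res2$W), 0.05)
})

test_that("fusion is deterministic and obeys the reference sign convention", {
  fit <- fit_synthetic(seed = 31, n_patients = 60, n_voxels = 400, M = 5)
  fit2 <- fit_synthetic(seed = 31, n_patients = 60, n_voxels = 400, M = 5)
  expect_identical(fit$model$mixing, fit2$model$mixing)
  expect_identical(fit$model$sources, fit2$model$sources)
  for (m in seq_len(fit$model$M))
    expect_gte(cor(fit$model$mixing[[1]][, m], fit$ref), 0)
  expect_gte(fit$selection$r[[1]], 0)
})

test_that("fusion recovers the planted reference component", {
  fit <- fit_synthetic(seed = 32, n_patients = 100, n_voxels = 800, M = 6)
  sel <- fit$selection
  expect_true(sel$significant)
  tr <- fit$data$truth
  for (k in 1:2) {
    r <- cor(fit$model$sources[[k]][sel$component, ],
             tr$sources_per_modality[[k]][tr$ref_component_index, ])
    expect_gt(abs(r), 0.9)
  }
  # reconstruction is tight at this noise level
  expect_true(all(fit$model$recon_error < 0.2))
})

test_that("voxel permutation permutes sources and leaves loadings essentially unchanged", {
  coh <- make_cohort(c(control = 10, subtype_a = 60), n_sites = 2, seed = 33)
  dat <- make_multimodal_data(coh, n_voxels = 400, M = 5, ref_r = 0.5,
                              noise_sd = 0.3, seed = 34)
  pats <- coh$group != "control"
  fms <- prep_fusion_inputs(dat, coh)
  set.seed(35)
  pp <- sample.int(400)
  datP <- dat
  datP$falff$values <- dat$falff$values[, pp]
  datP$gmv$values <- dat$gmv$values[, pp]
  fmsP <- prep_fusion_inputs(datP, coh)
  m1 <- fuse(fms, coh$ados_total[pats], M = 5, seed = 36)
  m2 <- fuse(fmsP, coh$ados_total[pats], M = 5, seed = 36)
  for (m in 1:5) {
    expect_gt(cor(m1$mixing[[1]][, m], m2$mixing[[1]][, m]), 0.99)
    expect_gt(cor(m1$sources[[1]][m, pp], m2$sources[[1]][m, ]), 0.99)
  }
})

test_that("component selection controls its false-selection rate under the null", {
  # no planted effect: selection must stay non-significant almost always
  hits <- 0L
  n_seeds <- 15L
  for (s in seq_len(n_seeds)) {
    set.seed(s + 700)
    n <- 50; V <- 250; M <- 4
    fms <- list(feature_matrix(matrix(rnorm(n * V), n, V),
                               paste0("s", 1:n), "a"),
                feature_matrix(matrix(rnorm(n * V), n, V),
                               paste0("s", 1:n), "b"))
    model <- fuse(fms, rnorm(n), M = M, seed = s)
    if (select_reference_component(model)$significant) hits <- hits + 1L
  }
  expect_lte(hits / n_seeds, 0.2)
})

test_that("z thresholding matches normal tails and is shift invariant", {
  set.seed(26)
  src <- rnorm(1e4)
  th <- zscore_threshold(src, z = 2)
  expect_lt(abs(mean(th$positive) - pnorm(-2)), 0.005)
  th_shift <- zscore_threshold(src + 100, z = 2)
  expect_identical(th$positive, th_shift$positive)
  expect_identical(th$negative, th_shift$negative)

  th1 <- zscore_threshold(c(0, 0, 0, 10), z = 1)
  expect_identical(th1$positive, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(zscore_threshold(rep(1, 5)), "variance")
})
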