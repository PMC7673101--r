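#' PCA reduction with whitening
#'
#' Column-demeans the feature matrix and keeps the top `M` left singular
#' directions, scaled to zero mean and unit variance. `scores %*% t(basis)`
#' is the best rank-`M` approximation (minimal Frobenius error) of the
#' demeaned data.
#'
#' @param fm a [feature_matrix()] or a plain subjects x voxels matrix.
#' @param M number of components to keep,
#'   `M <= min(subjects - 1, voxels)`.
#' @return list with `scores` (subjects x M, whitened), `basis`
#'   (voxels x M), `d` (all singular values), `center` (column means).
#' @export
pca_whiten <- function(fm, M) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- nrow(X)
  if (M > min(n - 1L, ncol(X)))
    stop("M must not exceed min(subjects - 1, voxels)")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = M, nv = M)
  scores <- sv$u * sqrt(n - 1)
  basis <- sv$v %*% diag(sv$d[seq_len(M)] / sqrt(n - 1), M)
  list(scores = scores, basis = basis, d = sv$d, center = center)
}

#' Multiset canonical correlation analysis with a reference (MCCA-R)
#'
#' Finds, for each of `M` components in turn, one weight vector per data
#' set maximizing
#' \deqn{\sum_{k \ne j} \mathrm{corr}(Y_k w_k, Y_j w_j)^2 +
#'       2\lambda \sum_k \mathrm{corr}(Y_k w_k, \mathrm{ref})^2,}
#' i.e. the squared inter-set correlations of the canonical loadings plus
#' a reward, weighted by `lam`, for correlation with a clinical reference
#' vector. Optimization alternates over sets; for whitened inputs each
#' set's update is an exact rank-restricted eigenproblem, so the objective
#' is non-decreasing within a component (the iteration log records it).
#' Later components are constrained to weight vectors orthogonal to the
#' earlier ones, which keeps each set's loading columns mutually
#' decorrelated.
#'
#' With `lam = 0` and two sets this reduces to ordinary two-set canonical
#' correlation analysis on the whitened scores.
#'
#' @param reduced list of whitened subjects x M score matrices sharing
#'   subject order (from [pca_whiten()]).
#' @param ref numeric reference vector (e.g. ADOS total), non-constant.
#' @param lam reference weight, `lam >= 0`.
#' @param seed integer seed for the weight initialization.
#' @param tol convergence tolerance on the per-component objective.
#' @param max_iter maximal alternating iterations per component.
#' @return list with `weights` (per set, M x M orthonormal), `loadings`
#'   (per set, subjects x M with unit-norm columns), `objective_log`
#'   (data frame: component, iteration, objective), `converged` (per
#'   component), `lam`.
#' @export
mccar <- function(reduced, ref, lam = 0.5, seed = 1, tol = 1e-6,
                  max_iter = 500) {
  K <- length(reduced)
  if (K < 2L) stop("need at least two data sets")
  n <- nrow(reduced[[1]])
  M <- ncol(reduced[[1]])
  for (Y in reduced)
    if (!identical(dim(Y), c(n, M)))
      stop("all reduced sets must share dimensions and subject order")
  if (length(ref) != n) stop("ref length must match subjects")
  if (stats::sd(ref) == 0) stop("ref must not be constant")
  if (lam < 0) stop("lam must be non-negative")
  set.seed(seed)
  refc <- (ref - mean(ref)) / stats::sd(ref)

  W <- lapply(seq_len(K), function(k) matrix(0, M, 0))
  A <- lapply(seq_len(K), function(k) matrix(0, n, 0))
  logs <- list()
  converged <- logical(M)

  for (comp in seq_len(M)) {
    Q <- lapply(W, orth_complement, m = M)
    Z <- Map(function(Y, q) Y %*% q, reduced, Q)
    mc <- ncol(Q[[1]])
    v <- lapply(seq_len(K), function(k) {
      x <- stats::rnorm(mc); x / sqrt(sum(x^2))
    })
    a <- Map(function(z, vv) drop(z %*% vv), Z, v)

    obj_of <- function(a) {
      o <- 0
      for (k in seq_len(K)) for (j in seq_len(K)) if (j != k)
        o <- o + stats::cor(a[[k]], a[[j]])^2
      o + 2 * lam * sum(vapply(a, function(x) stats::cor(x, refc)^2, 0))
    }

    prev <- -Inf
    conv <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      for (k in seq_len(K)) {
        # corr(Z v, x) = (v' g_x) / ||v||  with  g_x = Z' x / ((n-1) sd(x));
        # maximizing a sum of squared correlations is a Rayleigh quotient,
        # solved by the top left singular vector of the stacked g's.
        G <- vapply(setdiff(seq_len(K), k), function(j)
          drop(crossprod(Z[[k]], a[[j]])) / ((n - 1) * stats::sd(a[[j]])),
          numeric(mc))
        G <- cbind(G, sqrt(2 * lam) *
                     drop(crossprod(Z[[k]], refc)) / (n - 1))
        v[[k]] <- svd(G, nu = 1, nv = 0)$u[, 1]
        a[[k]] <- drop(Z[[k]] %*% v[[k]])
      }
      cur <- obj_of(a)
      logs[[length(logs) + 1L]] <-
        data.frame(component = comp, iteration = it, objective = cur)
      if (is.finite(prev) && abs(cur - prev) < tol) { conv <- TRUE; break }
      prev <- cur
    }
    converged[comp] <- conv
    if (!conv)
      warning(sprintf("component %d did not converge in %d iterations",
                      comp, max_iter))
    for (k in seq_len(K)) {
      w <- Q[[k]] %*% v[[k]]
      w <- w / sqrt(sum(w^2))
      ak <- drop(reduced[[k]] %*% w)
      # per-set sign convention: align every set to set 1 so the joint
      # components share one orientation across modalities
      if (k > 1L) {
        s <- sign(stats::cor(ak, A[[1]][, comp]))
        if (s < 0) { w <- -w; ak <- -ak }
      }
      W[[k]] <- cbind(W[[k]], w)
      A[[k]] <- cbind(A[[k]], ak / sqrt(sum(ak^2)))
    }
  }
  list(weights = W, loadings = A,
       objective_log = do.call(rbind, logs),
       converged = converged, lam = lam)
}

#' Joint Infomax independent component analysis
#'
#' Runs natural-gradient Infomax ICA (logistic nonlinearity) on the
#' modality-concatenated component maps, so one shared unmixing matrix
#' `W` rotates all modalities and the joint components stay linked across
#' them. The maps are row-centered and sphered first; learning uses
#' randomized sample blocks, learning-rate annealing, a weight-change
#' stopping tolerance, and automatic restarts with a halved learning rate
#' if the weights diverge. Components are ordered by decreasing variance
#' of the concatenated source maps.
#'
#' @param maps list of aligned M x voxels component-map matrices, one per
#'   modality.
#' @param loadings optional list of subjects x M mixing matrices; when
#'   given, the rotated mixings `A %*% solve(W)` are returned as well.
#' @param seed integer seed.
#' @param lrate initial learning rate.
#' @param max_passes maximal number of passes over the data.
#' @param tol weight-change stopping tolerance.
#' @param max_restarts divergence restarts before giving up.
#' @return list with `W` (M x M unmixing applied to the centered maps),
#'   `sources` (list per modality, M x voxels), `mixing` (rotated
#'   loadings, if supplied), `converged`, `passes`, `lrate`.
#' @export
joint_ica <- function(maps, loadings = NULL, seed = 1, lrate = 5e-3,
                      max_passes = 512, tol = 1e-6, max_restarts = 8) {
  M <- nrow(maps[[1]])
  if (M < 2L) stop("joint ICA needs at least 2 components")
  for (g in maps)
    if (nrow(g) != M) stop("all map matrices must share the component count")
  G <- do.call(cbind, maps)
  V <- ncol(G)
  rowmu <- rowMeans(G)
  Gc <- G - rowmu

  # symmetric sphering
  C <- tcrossprod(Gc) / (V - 1)
  ec <- eigen(C, symmetric = TRUE)
  if (min(ec$values) <= 1e-12 * max(ec$values))
    stop("component maps are rank deficient; cannot sphere")
  Sph <- ec$vectors %*% (t(ec$vectors) / sqrt(ec$values))
  Gs <- Sph %*% Gc

  block <- max(8L, min(ceiling(5 * log(V)), floor(V / 4)))
  set.seed(seed)
  restart <- 0L
  lr <- lrate
  repeat {
    Wu <- diag(M)
    oldW <- Wu
    olddelta <- NULL
    diverged <- FALSE
    converged <- FALSE
    passes <- 0L
    while (passes < max_passes) {
      passes <- passes + 1L
      perm <- sample.int(V)
      for (start in seq(1L, V - block + 1L, by = block)) {
        xb <- Gs[, perm[start:(start + block - 1L)], drop = FALSE]
        u <- Wu %*% xb
        y <- 1 / (1 + exp(-u))
        Wu <- Wu + lr * ((diag(M) * block + (1 - 2 * y) %*% t(u)) %*% Wu) /
          block
        if (!all(is.finite(Wu)) || max(abs(Wu)) > 1e8) {
          diverged <- TRUE
          break
        }
      }
      if (diverged) break
      delta <- Wu - oldW
      change <- sum(delta^2) / sum(Wu^2)
      # anneal only when successive update directions disagree by more
      # than 60 degrees; otherwise keep the rate and let learning proceed
      if (!is.null(olddelta)) {
        denom <- sqrt(sum(delta^2) * sum(olddelta^2))
        cosang <- if (denom > 0) sum(delta * olddelta) / denom else 1
        if (cosang < 0.5) {
          lr <- lr * 0.98
          olddelta <- delta
        }
      } else olddelta <- delta
      oldW <- Wu
      if (change < tol) { converged <- TRUE; break }
    }
    if (!diverged) break
    restart <- restart + 1L
    if (restart > max_restarts)
      stop("Infomax diverged despite repeated learning-rate reductions")
    lr <- lr / 2
  }

  Wtot <- Wu %*% Sph
  # unmix the raw (uncentered) maps so A %*% sources reconstructs the
  # input exactly; learning above used the centered, sphered data
  U <- Wtot %*% G
  ord <- order(apply(U, 1, stats::var), decreasing = TRUE)
  Wtot <- Wtot[ord, , drop = FALSE]
  U <- U[ord, , drop = FALSE]

  offsets <- c(0L, cumsum(vapply(maps, ncol, 0L)))
  sources <- lapply(seq_along(maps), function(k)
    U[, (offsets[k] + 1L):offsets[k + 1L], drop = FALSE])

  mixing <- NULL
  if (!is.null(loadings)) {
    Winv <- solve(Wtot)
    mixing <- lapply(loadings, function(A) A %*% Winv)
  }
  list(W = Wtot, sources = sources, mixing = mixing,
       converged = converged, passes = passes, lrate = lr)
}

#' Reference-guided two-modality fusion (MCCA-R + joint ICA)
#'
#' The full supervised fusion decomposition: each modality's feature
#' matrix is demeaned and PCA-whitened to `M` components, the whitened
#' scores are jointly rotated by reference-guided multiset CCA
#' ([mccar()]), the resulting canonical component maps are concatenated
#' across modalities and unmixed by joint Infomax ICA ([joint_ica()]),
#' and every joint component is sign-flipped so that its modality-1
#' loading correlates non-negatively with the reference. The result
#' satisfies `X_k ≈ A_k S_k` per modality (rank-`M` reconstruction).
#'
#' @param fms list of subject-aligned [feature_matrix()] objects (two
#'   modalities in the standard design).
#' @param ref numeric reference vector (e.g. ADOS total), aligned with
#'   the subjects.
#' @param M model order (number of joint components), default 30.
#' @param lam reference weight passed to [mccar()].
#' @param seed integer seed controlling all random stages.
#' @param ... further arguments passed to [mccar()].
#' @return a `fusion_model` object: `mixing` (list of subjects x M),
#'   `sources` (list of M x voxels), `pca` (per-modality basis and
#'   centering), `recon_error` (per-modality relative Frobenius error),
#'   `mccar_log`, `ref`, `lam`, `M`, `seed`, `subject_ids`, `modalities`,
#'   `masks`.
#' @export
fuse <- function(fms, ref, M = 30, lam = 0.5, seed = 1, ...) {
  if (length(fms) < 2L) stop("fusion needs at least two modalities")
  ids <- fms[[1]]$subject_ids
  for (fm in fms)
    if (!identical(fm$subject_ids, ids))
      stop("feature matrices are not subject-aligned")
  if (length(ref) != length(ids)) stop("ref must align with subjects")
  if (anyNA(ref)) stop("ref must not contain missing values")

  pcs <- lapply(fms, pca_whiten, M = M)
  mcc <- mccar(lapply(pcs, `[[`, "scores"), ref, lam = lam, seed = seed, ...)

  Xc <- lapply(fms, function(fm) sweep(fm$values, 2L, colMeans(fm$values)))
  maps <- Map(function(A, X) pseudo_inverse(A) %*% X, mcc$loadings, Xc)
  jica <- joint_ica(maps, loadings = mcc$loadings, seed = seed)

  mixing <- jica$mixing
  sources <- jica$sources
  for (m in seq_len(M)) {
    r <- stats::cor(mixing[[1]][, m], ref)
    if (is.finite(r) && r < 0)
      for (k in seq_along(mixing)) {
        mixing[[k]][, m] <- -mixing[[k]][, m]
        sources[[k]][m, ] <- -sources[[k]][m, ]
      }
  }
  recon <- vapply(seq_along(fms), function(k)
    norm(Xc[[k]] - mixing[[k]] %*% sources[[k]], "F") / norm(Xc[[k]], "F"),
    numeric(1))

  structure(list(
    M = M, lam = lam, mixing = mixing, sources = sources,
    pca = lapply(pcs, function(p) p[c("basis", "d", "center")]),
    recon_error = recon, mccar_log = mcc$objective_log,
    mccar_converged = mcc$converged, ica_converged = jica$converged,
    ref = ref, seed = seed, subject_ids = ids,
    modalities = vapply(fms, `[[`, "", "modality"),
    masks = lapply(fms, `[[`, "mask")
  ), class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %d components, lambda = %g, modalities: %s\n",
              x$M, x$lam, paste(x$modalities, collapse = ", ")))
  cat(sprintf("  reconstruction error: %s\n",
              paste(sprintf("%.3f", x$recon_error), collapse = ", ")))
  invisible(x)
}

#' Select the reference-associated joint component
#'
#' For every component and modality, computes the Pearson correlation of
#' the loadings with the reference and its two-sided p-value, adjusts all
#' `2 M` p-values by Benjamini-Hochberg FDR, and selects — among the
#' components significant in every modality — the one maximizing the
#' minimum absolute correlation across modalities (ties broken toward the
#' lower index). If no component survives, the selection is returned with
#' `significant = FALSE`.
#'
#' @param model a [fuse()] result.
#' @param ref reference vector; defaults to the one stored in the model.
#' @param q FDR level.
#' @return a `component_selection` list: `component`, `r` and `p_raw`
#'   (per-modality values for the selected component), `p_fdr`,
#'   `significant`, and `table` (all components x modalities).
#' @export
select_reference_component <- function(model, ref = model$ref, q = 0.05) {
  if (stats::sd(ref) == 0) stop("ref must not be constant")
  K <- length(model$mixing)
  M <- model$M
  n <- length(ref)
  tab <- expand.grid(component = seq_len(M), modality = seq_len(K))
  tab$r <- mapply(function(m, k) stats::cor(model$mixing[[k]][, m], ref),
                  tab$component, tab$modality)
  tab$p_raw <- vapply(tab$r, cor_pvalue, 0, n = n)
  tab$p_fdr <- stats::p.adjust(tab$p_raw, method = "BH")
  tab$modality <- model$modalities[tab$modality]

  sig_all <- vapply(seq_len(M), function(m)
    all(tab$p_fdr[tab$component == m] < q), logical(1))
  min_abs_r <- vapply(seq_len(M), function(m)
    min(abs(tab$r[tab$component == m])), numeric(1))

  if (any(sig_all)) {
    cand <- which(sig_all)
    comp <- cand[which.max(min_abs_r[cand])]
    significant <- TRUE
  } else {
    comp <- which.max(min_abs_r)
    significant <- FALSE
  }
  rows <- tab$component == comp
  structure(list(component = comp,
                 r = stats::setNames(tab$r[rows], tab$modality[rows]),
                 p_raw = stats::setNames(tab$p_raw[rows], tab$modality[rows]),
                 p_fdr = stats::setNames(tab$p_fdr[rows], tab$modality[rows]),
                 significant = significant, q = q, table = tab),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> component %d (%s)\n", x$component,
              if (x$significant) "significant in all modalities"
              else "not significant"))
  print(data.frame(modality = names(x$r), r = x$r, p_raw = x$p_raw,
                   p_fdr = x$p_fdr, row.names = NULL))
  invisible(x)
}

#' Z-score a source map and threshold it
#'
#' Standardizes a component's voxel pattern to zero mean and unit SD and
#' returns the z-map together with the positive (`z > threshold`) and
#' negative (`z < -threshold`) voxel masks used to define networks.
#'
#' @param source numeric voxel vector (one row of a source matrix).
#' @param z threshold on |Z|, default 2.
#' @return list with `zmap`, `positive`, `negative` (logical vectors).
#' @export
zscore_threshold <- function(source, z = 2) {
  s <- stats::sd(source)
  if (s == 0) stop("source map has zero variance")
  zmap <- (source - mean(source)) / s
  list(zmap = zmap, positive = zmap > z, negative = zmap < -z)
}
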