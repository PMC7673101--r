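test_that("framewise displacement matches hand evaluation", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(motion_trace(m)), rep(0, 10))

  m[5:10, 1] <- 0.5                       # one 0.5 mm translation step
  fd <- framewise_displacement(motion_trace(m))
  expect_equal(fd[5], 0.5)
  expect_equal(fd[-5], rep(0, 9))

  m2 <- matrix(0, 10, 6)
  m2[3:10, 4] <- 0.02                     # one 0.02 rad rotation step
  fd2 <- framewise_displacement(motion_trace(m2), head_radius = 50)
  expect_equal(fd2[3], 1.0)               # 50 mm * 0.02 rad

  # constant offsets never contribute to FD
  expect_equal(framewise_displacement(motion_trace(m2 + 3)), fd2)
})

test_that("framewise displacement honors the recorded rotation unit", {
  m <- matrix(0, 5, 6)
  m[3:5, 5] <- 1                          # one 1-degree step
  fd_deg <- framewise_displacement(motion_trace(m, "degrees"))
  expect_equal(fd_deg[3], 50 * pi / 180)
  bad <- motion_trace(m)
  attr(bad, "rotation_unit") <- NULL
  expect_error(framewise_displacement(bad), "unit")
})

test_that("motion QC applies the mean-FD, translation and rotation rules", {
  still <- motion_trace(matrix(0, 50, 6))
  qc <- motion_qc(still)
  expect_true(qc$passed)
  expect_length(qc$reasons, 0)

  m <- matrix(0, 50, 6); m[20, 1] <- 2.5
  qc2 <- motion_qc(motion_trace(m))
  expect_false(qc2$passed)
  expect_true("max-translation" %in% qc2$reasons)

  # alternating large steps push mean FD above 1 mm without breaking the
  # per-axis translation limit
  m3 <- matrix(0, 50, 6); m3[, 2] <- rep(c(0, 1.9), 25)
  qc3 <- motion_qc(motion_trace(m3))
  expect_gt(qc3$mean_fd, 1)
  expect_true("mean-FD" %in% qc3$reasons)

  m4 <- matrix(0, 50, 6); m4[30:50, 6] <- 1.2 * pi / 180
  expect_true("max-rotation" %in% motion_qc(motion_trace(m4))$reasons)
})

test_that("nuisance regression removes regressors and demeans without them", {
  set.seed(1)
  vol <- array(rnorm(4 * 4 * 2 * 60), dim = c(4, 4, 2, 60))
  out <- regress_nuisance(vol)
  expect_equal(apply(out, 1:3, mean), array(0, dim = c(4, 4, 2)),
               tolerance = 1e-12)

  reg <- cbind(sin(1:60 / 5), rnorm(60))
  res <- regress_nuisance(vol, reg)
  series <- matrix(res, 32, 60)
  expect_lt(max(abs(series %*% scale(reg, scale = FALSE))), 1e-8)

  # a voxel equal to a regressor is annihilated
  vol2 <- vol
  vol2[1, 1, 1, ] <- reg[, 1]
  res2 <- regress_nuisance(vol2, reg)
  expect_equal(res2[1, 1, 1, ], rep(0, 60), tolerance = 1e-10)

  expect_error(regress_nuisance(vol, cbind(reg[, 1], reg[, 1])),
               "collinear")
})

test_that("gaussian smoothing preserves constants and matches the closed-form kernel", {
  vol <- array(5, dim = c(8, 8, 8))
  expect_equal(gaussian_smooth(vol, fwhm = 6, voxel_size = 3), vol,
               tolerance = 1e-10)
  set.seed(2)
  noisy <- array(rnorm(512), dim = c(8, 8, 8))
  expect_identical(gaussian_smooth(noisy, fwhm = 0), noisy)
  expect_equal(mean(gaussian_smooth(noisy, 6, 3)), mean(noisy),
               tolerance = 1e-6)

  # delta image: center-to-neighbor ratio equals the Gaussian ratio
  delta <- array(0, dim = c(15, 15, 15))
  delta[8, 8, 8] <- 1
  sm <- gaussian_smooth(delta, fwhm = 6, voxel_size = 3)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sm[8, 8, 8] / sm[9, 8, 8],
               dnorm(0, sd = sigma) / dnorm(1, sd = sigma),
               tolerance = 1e-6)
  expect_error(gaussian_smooth(delta, fwhm = -1), "non-negative")
})

test_that("fALFF matches the brute-force spectral oracle on sinusoids and noise", {
  tt <- seq(0, by = 2, length.out = 200)
  low <- sin(2 * pi * 0.05 * tt)          # on-bin: 0.05 = 20 / (200 * 2)
  high <- sin(2 * pi * 0.15 * tt)
  f_low <- compute_falff(low, tr = 2)
  f_high <- compute_falff(high, tr = 2)
  expect_lt(abs(f_low - 1), 0.02)
  expect_lt(abs(f_high - 0), 0.02)
  expect_equal(f_low, brute_force_falff(low, 2), tolerance = 1e-10)
  expect_equal(f_high, brute_force_falff(high, 2), tolerance = 1e-10)

  set.seed(3)
  wn <- rnorm(10000)
  f_wn <- compute_falff(wn, tr = 2)
  expect_lt(abs(f_wn - (0.08 - 0.01) / 0.25), 0.03)
  expect_equal(f_wn, brute_force_falff(wn, 2), tolerance = 1e-10)
})

test_that("fALFF is scale invariant, bounded by 1, and 0 for silent series", {
  set.seed(4)
  x <- rnorm(128) + sin(2 * pi * 0.04 * seq(0, by = 2, length.out = 128))
  f <- compute_falff(x, tr = 2)
  expect_equal(compute_falff(7.3 * x, tr = 2), f, tolerance = 1e-12)
  expect_gte(f, 0)
  expect_lte(f, 1)
  expect_warning(f0 <- compute_falff(rep(0, 64), tr = 2), "zero")
  expect_equal(f0, 0)
  expect_error(compute_falff(rnorm(10), tr = 2), "32")
})

test_that("fALFF maps apply the scalar operator voxelwise under a mask", {
  ts <- make_fmri_timeseries(
    128, tr = 2,
    components = list(list(freq = 0.04, amp = 2,
                           mask = array(rep(c(TRUE, FALSE), each = 32),
                                        dim = c(4, 4, 4))),
                      list(freq = 0.2, amp = 2,
                           mask = array(rep(c(FALSE, TRUE), each = 32),
                                        dim = c(4, 4, 4)))),
    noise_sd = 0.2, seed = 5, grid_dim = c(4, 4, 4))
  mask <- array(TRUE, dim = c(4, 4, 4))
  map <- falff_map(ts$volume, tr = 2, mask = mask)
  in_band <- map[rep(c(TRUE, FALSE), each = 32)]
  out_band <- map[rep(c(FALSE, TRUE), each = 32)]
  expect_true(min(in_band) > max(out_band))

  single <- array(FALSE, dim = c(4, 4, 4)); single[2, 3, 1] <- TRUE
  map1 <- falff_map(ts$volume, tr = 2, mask = single)
  expect_equal(map1[2, 3, 1], compute_falff(ts$volume[2, 3, 1, ], tr = 2))
  expect_equal(sum(!is.na(map1)), 1L)
  expect_error(falff_map(ts$volume, 2, array(FALSE, dim = c(4, 4, 4))),
               "no voxels")
})
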