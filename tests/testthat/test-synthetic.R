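test_that("cohort generation respects counts, sites, and score structure", {
  coh <- make_cohort(c(control = 20, subtype_a = 20), n_sites = 3, seed = 1)
  expect_equal(nrow(coh), 40)
  expect_equal(nlevels(coh$site), 3)
  expect_false(any(duplicated(coh$subject_id)))

  pats <- coh$group != "control"
  expect_equal(coh$ados_total[pats],
               coh$ados_comm[pats] + coh$ados_social[pats] +
                 coh$ados_stereo[pats])
  expect_true(all(is.na(coh$ados_total[!pats])))
  expect_true(all(is.na(coh$srs[!pats])))
})

test_that("cohort generation is deterministic under a seed and varies across seeds", {
  a <- make_cohort(c(control = 10, subtype_a = 12), n_sites = 2, seed = 1)
  b <- make_cohort(c(control = 10, subtype_a = 12), n_sites = 2, seed = 1)
  c <- make_cohort(c(control = 10, subtype_a = 12), n_sites = 2, seed = 2)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$iq, c$iq)) &&
                 isTRUE(all.equal(a$age, c$age)))
})

test_that("cohort generation rejects degenerate arguments", {
  expect_error(make_cohort(c(control = 1, subtype_a = 10), 3), "at least 2")
  expect_error(make_cohort(c(control = 10, subtype_a = 10), 1), "n_sites")
  expect_error(make_cohort(c(10, 10), 3), "named")
})

test_that("multimodal generator satisfies the noise-free generative identity", {
  coh <- make_cohort(c(control = 10, subtype_a = 30), n_sites = 2, seed = 3)
  dat <- make_multimodal_data(coh, n_voxels = 300, M = 5, ref_r = 0.4,
                              noise_sd = 0, seed = 4)
  tr <- dat$truth
  expect_equal(dat$falff$values,
               tr$mixing_per_modality[[1]] %*% tr$sources_per_modality[[1]],
               tolerance = 1e-12)
  expect_equal(dat$gmv$values,
               tr$mixing_per_modality[[2]] %*% tr$sources_per_modality[[2]],
               tolerance = 1e-12)
})

test_that("planted loading-score correlation is realized among patients", {
  coh <- make_cohort(c(control = 10, subtype_a = 120), n_sites = 3, seed = 5)
  for (target in c(0.3, 0.5, 0.7)) {
    dat <- make_multimodal_data(coh, n_voxels = 200, M = 4, ref_r = target,
                                noise_sd = 0, seed = 6)
    pats <- coh$group != "control"
    got <- cor(dat$truth$mixing_per_modality[[1]][pats,
                 dat$truth$ref_component_index],
               coh$ados_total[pats])
    expect_lt(abs(got - target), 0.05)
  }
})

test_that("unique regions are negative in modality 1 only and disjoint from the common region", {
  coh <- make_cohort(c(control = 10, subtype_a = 20, subtype_b = 20),
                     n_sites = 2, seed = 7)
  dat <- make_multimodal_data(coh, n_voxels = 400, M = 5, ref_r = 0.4,
                              noise_sd = 0, unique_spec = "subtype_a",
                              seed = 8)
  tr <- dat$truth
  ua <- tr$unique_region_masks[["subtype_a"]]
  uidx <- tr$unique_component_index[["subtype_a"]]
  expect_true(all(tr$sources_per_modality[[1]][uidx, ua] < 0))
  # modality 2 carries no unique-region weights beyond tiny background
  expect_true(all(abs(tr$sources_per_modality[[2]][uidx, ua]) < 0.5))
  # the candidate region of the unlisted subtype stays empty
  b_region <- seq_len(400) > sum(tr$common_mask) + sum(ua) &
    seq_len(400) <= sum(tr$common_mask) + 2 * sum(ua)
  expect_true(all(abs(tr$sources_per_modality[[1]][uidx, b_region]) < 0.5))
  expect_false(any(tr$common_mask & ua))
})

test_that("generator rejects inconsistent model orders", {
  coh <- make_cohort(c(control = 5, subtype_a = 5), n_sites = 2, seed = 1)
  expect_error(make_multimodal_data(coh, n_voxels = 100, M = 10), "subjects")
  expect_error(make_multimodal_data(coh, n_voxels = 100, M = 5, ref_r = 1.2),
               "ref_r")
})

test_that("synthetic time series carry the requested spectral peak", {
  ts <- make_fmri_timeseries(200, tr = 2,
                             components = list(list(freq = 0.05, amp = 1)),
                             noise_sd = 0, seed = 1, grid_dim = c(3, 3, 3))
  x <- ts$volume[1, 1, 1, ]
  amp <- Mod(stats::fft(x))[2:100]
  freq <- (1:99) / (200 * 2)
  expect_equal(freq[which.max(amp)], 0.05)
  expect_true(sum(amp > max(amp) / 2) <= 2)
  expect_equal(unclass(ts$motion), matrix(0, 200, 6), ignore_attr = TRUE)
})

test_that("time-series noise has the requested variance and frequencies respect Nyquist", {
  ts <- make_fmri_timeseries(500, tr = 2, components = list(),
                             noise_sd = 1, seed = 2, grid_dim = c(4, 4, 4))
  v <- apply(matrix(ts$volume, 64, 500), 1, var)
  expect_lt(abs(mean(v) - 1), 0.1)
  expect_error(
    make_fmri_timeseries(100, tr = 2,
                         components = list(list(freq = 0.3, amp = 1))),
    "Nyquist")
})
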