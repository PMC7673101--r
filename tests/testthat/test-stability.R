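test_that("occurrence masks follow the fraction and absolute-count rules", {
  m <- c(1L, -1L, 0L, 1L)
  same <- replicate(5, m, simplify = FALSE)
  occ <- occurrence_mask(same, fraction = 0.7)
  expect_equal(occ$mask, m)

  # a voxel surviving in 6 of 9 runs: excluded at 70% (needs >= 7), kept
  # with the absolute-count override of 6
  runs <- c(replicate(6, c(1L, 0L), simplify = FALSE),
            replicate(3, c(0L, 0L), simplify = FALSE))
  expect_equal(occurrence_mask(runs, fraction = 0.7)$mask, c(0L, 0L))
  expect_equal(occurrence_mask(runs, count = 6)$mask, c(1L, 0L))

  # disjoint run masks never stabilize
  disj <- lapply(1:4, function(i) { v <- integer(4); v[i] <- 1L; v })
  expect_equal(occurrence_mask(disj, fraction = 0.7)$mask, integer(4))

  # opposite signs do not accumulate
  flip <- list(c(1L, 0L), c(-1L, 0L), c(1L, 0L))
  expect_equal(occurrence_mask(flip, count = 3)$mask, c(0L, 0L))
  expect_error(occurrence_mask(list()), "at least one")
})

test_that("occurrence masks shrink monotonically in the threshold fraction", {
  set.seed(70)
  runs <- replicate(9, sample(c(-1L, 0L, 1L), 200, TRUE,
                              prob = c(0.15, 0.55, 0.3)),
                    simplify = FALSE)
  sizes <- sapply(seq(0.1, 1, by = 0.1), function(f)
    sum(occurrence_mask(runs, fraction = f)$mask != 0L))
  expect_true(all(diff(sizes) <= 0))
  # counts are invariant to the order of the runs
  occ1 <- occurrence_mask(runs, fraction = 0.5)
  occ2 <- occurrence_mask(rev(runs), fraction = 0.5)
  expect_identical(occ1$mask, occ2$mask)
})

test_that("leave-one-site-out produces one deterministic run per site", {
  coh <- make_cohort(c(control = 10, subtype_a = 72), n_sites = 4, seed = 71)
  dat <- make_multimodal_data(coh, n_voxels = 400, M = 5, ref_r = 0.6,
                              noise_sd = 0.25, seed = 72)
  pats <- coh$group != "control"
  fms <- list(feature_matrix(dat$falff$values[pats, ],
                             coh$subject_id[pats], "falff"),
              feature_matrix(dat$gmv$values[pats, ],
                             coh$subject_id[pats], "gmv"))
  covs <- coh[pats, c("age", "iq", "handedness", "site")]
  runs <- leave_one_site_out(fms, coh$ados_total[pats], covs, M = 5,
                             seed = 73)
  expect_length(runs, 4L)
  expect_setequal(names(runs), paste0("site", 1:4))
  runs2 <- leave_one_site_out(fms, coh$ados_total[pats], covs, M = 5,
                              seed = 73)
  expect_identical(lapply(runs, `[[`, "sign_mask"),
                   lapply(runs2, `[[`, "sign_mask"))
  # every run recovers the planted reference map
  for (r in runs) {
    expect_true(r$significant)
    rr <- cor(r$source[[1]],
              dat$truth$sources_per_modality[[1]][1, ])
    expect_gt(abs(rr), 0.8)
  }
  expect_error(leave_one_site_out(fms, coh$ados_total[pats],
                                  data.frame(site = rep(c("a", "b"),
                                                        length.out = 72)),
                                  M = 5), "3 sites")
})

test_that("projected components replicate the planted score correlation across cohorts", {
  fit <- fit_synthetic(seed = 74, n_patients = 150, n_voxels = 600, M = 5)
  # an independent cohort drawn from the same generative rule
  coh_b <- make_cohort(c(control = 10, subtype_a = 150), n_sites = 3,
                       seed = 75)
  dat_b <- make_multimodal_data(coh_b, n_voxels = 600, M = 5, ref_r = 0.5,
                                noise_sd = 0.25, seed = 76,
                                truth = fit$data$truth)
  fms_b <- prep_fusion_inputs(dat_b, coh_b)
  proj <- project_components(fit$model, fms_b,
                             coh_b$ados_total[coh_b$group != "control"])
  sel <- fit$selection$component
  tab <- proj$table
  r_sel <- tab$r[tab$component == sel]
  expect_true(all(abs(r_sel - 0.5) < 0.15))

  # projecting the training cohort reproduces the in-sample correlation
  proj_self <- project_components(fit$model, fit$fms, fit$ref)
  r_self <- proj_self$table$r[proj_self$table$component == sel]
  expect_equal(unname(r_self[1]), unname(fit$selection$r[1]),
               tolerance = 0.02)
})
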