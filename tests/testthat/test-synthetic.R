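test_that("cohort spec rejects inconsistent parameters", {
  expect_error(cohort_spec(n_per_group = 0), "positive count")
  expect_error(cohort_spec(trait_behavior_corr = 1.2), "must lie in")
  expect_error(cohort_spec(persistence_base = 1), "must lie in")
  expect_error(cohort_spec(volume_shape = c(8, 8)), "3 dimensions")
  expect_error(cohort_spec(cluster_center = c(2, 2, 2),
                           cluster_radius_mm = 30),
               "outside the volume")
  expect_error(cohort_spec(trait_behavior_corr = 0.9,
                           behavior_attenuation = 0.8), "too high")
})

test_that("identical spec and seed reproduce the identical cohort", {
  spec <- fixture_small_spec(seed = 10)
  a <- generate_cohort(spec, generate_volumes = FALSE)
  b <- generate_cohort(spec, generate_volumes = FALSE)
  expect_identical(a$subjects, b$subjects)
  c <- generate_cohort(fixture_small_spec(seed = 11),
                       generate_volumes = FALSE)
  expect_false(identical(a$subjects[[1]]$spontaneous_trials,
                         c$subjects[[1]]$spontaneous_trials))
})

test_that("every generated stimulus has a unique brightest figure distinct from the circle", {
  spec <- fixture_small_spec(seed = 3)
  tr <- generate_spontaneous_session(0, spec, seed = 3)
  expect_true(all(tr$target_index != tr$brightest_index))
  B <- as.matrix(tr[, c("b1", "b2", "b3", "b4")])
  expect_true(all(apply(B, 1, max) == 4))
  expect_true(all(rowSums(B == 4) == 1))
  expect_true(all(B[cbind(seq_len(nrow(tr)), tr$brightest_index)] == 4))
})

test_that("percept timelines alternate clear percepts and respect the run length", {
  spec <- cohort_spec()
  tl <- generate_percept_timeline(0, spec, seed = 5)
  expect_true(all(tl$onset_s >= 0 & tl$onset_s < spec$run_length_s))
  expect_true(all(diff(tl$onset_s) > 0))
  clear <- tl$label[tl$label != "mixed"]
  expect_true(all(clear[-1] != clear[-length(clear)]))
})

test_that("higher rigidity lengthens percepts and repetition runs in expectation", {
  spec <- cohort_spec()
  set.seed(41)
  lo <- replicate(8, {
    tls <- lapply(1:3, function(r)
      generate_percept_timeline(-1, spec, r))
    median_percept_duration(tls)
  })
  hi <- replicate(8, {
    tls <- lapply(1:3, function(r)
      generate_percept_timeline(1.5, spec, r))
    median_percept_duration(tls)
  })
  expect_gt(mean(hi), mean(lo))
})

test_that("generated volumes carry the planted negative rigidity effect inside the cluster", {
  spec <- cohort_spec(seed = 6)
  g <- generate_gmv_images(c(-2, 2), c("TD", "TD"), spec, seed = 6)
  cl <- g$cluster_mask
  diff_in <- mean(g$volumes[[2]][cl]) - mean(g$volumes[[1]][cl])
  out <- g$mask & !cl
  diff_out <- mean(g$volumes[[2]][out]) - mean(g$volumes[[1]][out])
  expect_lt(diff_in, 4 * spec$cluster_effect * 0.5)  # strongly negative
  expect_lt(abs(diff_out), abs(spec$cluster_effect))
  # voxels outside the brain mask are zero
  expect_true(all(g$volumes[[1]][!g$mask] == 0))
})

test_that("the ellipsoid mask contains the planted sphere and excludes grid corners", {
  spec <- cohort_spec()
  mask <- ellipsoid_mask(spec$volume_shape)
  cl <- sphere_mask(spec$volume_shape, spec$cluster_center,
                    spec$cluster_radius_mm / spec$voxel_size_mm)
  expect_true(all(mask[cl]))
  expect_false(mask[1, 1, 1])
  expect_gt(sum(cl), 0)
})

test_that("gaussian smoothing preserves the mean and shrinks the variance of noise", {
  set.seed(2)
  x <- array(rnorm(20^3), c(20, 20, 20))
  s <- gaussian_smooth_3d(x, fwhm_mm = 8, voxel_size_mm = 3)
  expect_equal(mean(s), mean(x), tolerance = 0.02)
  expect_lt(stats::var(as.vector(s)), 0.1 * stats::var(as.vector(x)))
})

test_that("demographics match the calibrated group profile", {
  spec <- cohort_spec(n_per_group = 150L, n_runs = 2L,
                      trial_budget_s = 60, seed = 13)
  cohort <- generate_cohort(spec, generate_volumes = FALSE)
  tab <- score_cohort(cohort)
  asd <- tab[tab$group == "ASD", ]
  td <- tab[tab$group == "TD", ]
  expect_true(all(tab$full_iq >= 85))            # high-functioning floor
  expect_equal(mean(asd$full_iq), 119.7, tolerance = 3)
  expect_equal(mean(td$full_iq), 112.8, tolerance = 3)
  expect_equal(mean(asd$ados_rrb), 0.8, tolerance = 0.2)
  expect_true(all(asd$ados_rrb %in% 0:2))
})
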