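make_noise_volumes <- function(n, dims, sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(dims), 0, sd), dims))
}

test_that("voxelwise t statistics agree with per-voxel lm fits", {
  dims <- c(4, 4, 3)
  mask <- array(TRUE, dims)
  vols <- make_noise_volumes(20, dims, seed = 21)
  set.seed(22)
  beh <- rnorm(20)
  cov <- cbind(age = rnorm(20, 30, 5), iq = rnorm(20, 110, 10))
  map <- voxelwise_regression(vols, beh, cov, mask)
  for (v in c(1, 17, 48)) {
    y <- vapply(vols, function(a) a[v], numeric(1))
    fit <- summary(lm(y ~ beh + cov))$coefficients
    expect_equal(map$t[v], fit["beh", "t value"], tolerance = 1e-10)
    expect_equal(map$p[v], fit["beh", "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_equal(map$dof, 20 - 4)
})

test_that("voxelwise regression rejects degenerate designs", {
  dims <- c(3, 3, 3)
  mask <- array(TRUE, dims)
  vols <- make_noise_volumes(10, dims, seed = 3)
  expect_error(voxelwise_regression(vols, rep(1, 10), NULL, mask),
               "constant")
  beh <- rnorm(10)
  expect_error(voxelwise_regression(vols, beh, cbind(x = beh), mask),
               "rank-deficient")
})

test_that("BH thresholding reproduces the step-up rule on a worked example", {
  dims <- c(4, 1, 1)
  mask <- array(TRUE, dims)
  p <- array(c(0.01, 0.02, 0.5, 0.9), dims)
  map <- structure(list(t = array(c(3, -3, 1, 0.1), dims), p = p,
                        dof = 10, mask = mask, regressor = "behavior"),
                   class = "voxel_stat_map")
  # sorted p: .01 <= 1/4*.05? no (.0125 >= .01 yes). .02 <= 2/4*.05 = .025
  # yes -> reject the two smallest; .5 and .9 fail
  surv <- fdr_threshold(map, q = 0.05)
  expect_identical(as.vector(surv), c(TRUE, TRUE, FALSE, FALSE))
  s <- signed_maps(map, surv)
  expect_identical(as.vector(s$positive), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(as.vector(s$negative), c(FALSE, TRUE, FALSE, FALSE))
  # signed maps partition the survivors
  expect_true(all(!(s$positive & s$negative)))
  expect_identical(s$positive | s$negative, surv)
})

test_that("conjunction is a commutative intersection bounded by its inputs", {
  a <- fixture_blob_mask()
  b <- array(FALSE, dim(a)); b[2:5, 2:5, 2:5] <- TRUE
  cj <- conjunction(a, b)
  expect_identical(cj, conjunction(b, a))
  expect_true(all(!cj | a))
  expect_true(all(!cj | b))
  expect_identical(conjunction(a, a), a)
  expect_error(conjunction(a, array(FALSE, c(2, 2, 2))), "different grids")
})

test_that("cluster extraction labels 26-connected components with peak locations", {
  mask <- fixture_blob_mask()
  tmap <- array(NA_real_, dim(mask))
  tmap[mask] <- c(-2, -5, -1, -3, 4)[seq_len(sum(mask))]
  cl <- extract_clusters(mask, tmap, voxel_size_mm = 3)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$size), c(1, 4))
  expect_equal(sum(cl$size), sum(mask))
  big <- cl[cl$size == 4, ]
  expect_equal(big$peak_t, min(tmap[mask][1:4]))  # largest |t| in the blob
  labels <- attr(cl, "labels")
  expect_identical(labels > 0, mask)
  # diagonal touch merges under 26-connectivity
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE
  m2[2, 2, 2] <- TRUE
  expect_equal(nrow(extract_clusters(m2)), 1)
  # empty masks yield an empty table
  expect_equal(nrow(extract_clusters(array(FALSE, c(3, 3, 3)))), 0)
})

test_that("ROI summaries compute means, totals, and scale-invariant ratios", {
  v <- array(2, c(3, 3, 3))
  brain <- array(TRUE, c(3, 3, 3))
  roi <- array(FALSE, c(3, 3, 3)); roi[1:2, 1, 1] <- TRUE
  expect_equal(roi_mean_gmv(v, roi), 2)
  expect_equal(whole_brain_gmv(v, brain), 54)
  expect_equal(relative_gmv(v, roi, brain), 2 / 54)
  # global scaling cancels out of the ratio
  expect_equal(relative_gmv(2 * v, roi, brain),
               relative_gmv(v, roi, brain))
  expect_error(roi_mean_gmv(v, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("group difference map equals the pooled t test without covariates", {
  dims <- c(3, 3, 2)
  mask <- array(TRUE, dims)
  va <- make_noise_volumes(8, dims, seed = 31)
  vb <- make_noise_volumes(8, dims, seed = 32)
  gd <- group_difference_map(va, vb, NULL, mask, q = 0.05,
                             tail = "two.sided")
  v <- 5
  ya <- vapply(va, function(a) a[v], numeric(1))
  yb <- vapply(vb, function(a) a[v], numeric(1))
  tt <- t.test(yb, ya, var.equal = TRUE)
  expect_equal(gd$map$t[v], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(gd$map$p[v], tt$p.value, tolerance = 1e-10)
  # one-tailed p is half the two-tailed p on the matching side
  gd1 <- group_difference_map(va, vb, NULL, mask, tail = "less")
  neg <- !is.na(gd$map$t) & gd$map$t < 0
  expect_equal(gd1$map$p[neg], gd$map$p[neg] / 2, tolerance = 1e-10)
})
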