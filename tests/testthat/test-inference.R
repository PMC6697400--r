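test_that("correlation rule selects Spearman for ordinal inputs and Pearson otherwise", {
  set.seed(51)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  r <- correlate(x, y)
  ct <- cor.test(x, y)
  expect_identical(r$method, "pearson")
  expect_equal(r$estimate, unname(ct$estimate))
  expect_equal(r$p, ct$p.value)
  ados <- sample(0:2, 30, replace = TRUE)
  rs <- correlate(x, ados, y_ordinal = TRUE)
  cts <- suppressWarnings(cor.test(x, ados, method = "spearman"))
  expect_identical(rs$method, "spearman")
  expect_equal(rs$estimate, unname(cts$estimate))
  expect_error(correlate(x, rep(1, 30)), "zero-variance")
})

test_that("partial correlation matches the inversion of the correlation matrix", {
  set.seed(52)
  z <- rnorm(40)
  x <- 0.7 * z + rnorm(40)
  y <- 0.7 * z + rnorm(40)
  pc <- partial_correlation(x, y, z)
  R <- cor(cbind(x, y, z))
  P <- solve(R)
  expect_equal(pc, -P[1, 2] / sqrt(P[1, 1] * P[2, 2]), tolerance = 1e-10)
  # conditioning a variable on itself leaves nothing to correlate
  expect_error(partial_correlation(x, y, x), "collinear")
})

test_that("mediation recovers the exact paths of a noiseless chain", {
  x <- scale(1:22)[, 1]
  e <- rep(c(1, -1), 11)
  e <- residuals(lm(e ~ x))        # orthogonal to intercept and x
  m <- 2 * x + e
  y <- 3 * m                        # all of x's effect flows through m
  md <- mediate(x, m, y, n_boot = 500, seed = 1)
  expect_equal(md$alpha, 2, tolerance = 1e-10)
  expect_equal(md$beta, 3, tolerance = 1e-10)
  expect_equal(md$indirect, 6, tolerance = 1e-10)
  expect_equal(md$gamma, 0, tolerance = 1e-10)
  expect_lt(md$p_indirect, 0.05)
  expect_true(md$ci_lower <= 6 && 6 <= md$ci_upper)
})

test_that("mediation p values are floored at the bootstrap resolution and reproducible", {
  set.seed(53)
  x <- rnorm(40)
  m <- x + rnorm(40, 0, 0.3)
  y <- m + rnorm(40, 0, 0.3)
  md1 <- mediate(x, m, y, n_boot = 1000, seed = 7)
  md2 <- mediate(x, m, y, n_boot = 1000, seed = 7)
  expect_identical(md1$p_indirect, md2$p_indirect)
  expect_gte(md1$p_indirect, 1 / 1000)
  expect_error(mediate(x[1:5], m[1:5], y[1:5]), "at least 10")
})

test_that("mediation with covariates adjusts both regressions", {
  set.seed(54)
  n <- 60
  c1 <- rnorm(n)
  x <- 0.8 * c1 + rnorm(n)
  m <- 0.5 * x + 0.8 * c1 + rnorm(n)
  y <- 0.5 * m + 0.8 * c1 + rnorm(n)
  md <- mediate(x, m, y, n_boot = 500, seed = 3, covariates = cbind(c1))
  f1 <- lm(m ~ x + c1)
  f2 <- lm(y ~ x + m + c1)
  expect_equal(md$alpha, unname(coef(f1)["x"]), tolerance = 1e-10)
  expect_equal(md$beta, unname(coef(f2)["m"]), tolerance = 1e-10)
  expect_equal(md$gamma, unname(coef(f2)["x"]), tolerance = 1e-10)
})

test_that("voxelwise mediation agrees with the scalar paths voxel by voxel", {
  set.seed(55)
  n <- 24
  dims <- c(3, 3, 2)
  mask <- array(TRUE, dims)
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  vols <- lapply(seq_len(n), function(i)
    array(rnorm(prod(dims)), dims))
  vols <- lapply(seq_len(n), function(i) {
    v <- vols[[i]]
    v[1, 1, 1] <- 0.9 * x[i] + rnorm(1, 0, 0.2)   # one mediating voxel
    v
  })
  vm <- voxelwise_mediation(x, vols, y, mask, n_boot = 400, seed = 9)
  mv <- vapply(vols, function(v) v[2, 2, 1], numeric(1))
  pt <- flexlink:::mediation_paths(x, mv, y)
  expect_equal(vm$indirect[2, 2, 1], pt$alpha * pt$beta, tolerance = 1e-8)
  expect_true(all(dim(vm$p) == dims))
  expect_true(all(vm$p[mask] >= 1 / 400))
})

test_that("the latent flexibility model recovers loadings of simulated indicators", {
  set.seed(56)
  n <- 1500
  z <- rnorm(n)
  X <- cbind(a = 0.9 * z + rnorm(n, 0, sqrt(1 - 0.81)),
             b = 0.7 * z + rnorm(n, 0, sqrt(1 - 0.49)),
             c = 0.5 * z + rnorm(n, 0, sqrt(1 - 0.25)))
  fit <- fit_latent_model(X, standardize = TRUE)
  expect_true(fit$converged)
  expect_equal(unname(fit$loadings), c(0.9, 0.7, 0.5), tolerance = 0.07)
  expect_equal(fit$df, 0)           # 3 indicators: just identified
  expect_equal(fit$RMSEA, 0)
  expect_lt(fit$SRMR, 0.01)
  expect_error(fit_latent_model(X[, 1:2]), "at least 3")
})

test_that("group statistics match their base-R references", {
  set.seed(57)
  a <- rnorm(15, 1)
  b <- rnorm(18)
  tt <- two_sample_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)
  expect_equal(tt$dof, 31)
  sp <- sqrt((14 * var(a) + 17 * var(b)) / 31)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  g <- list(rnorm(10), rnorm(10, 0.5), rnorm(10, 1))
  av <- one_way_anova(g)
  y <- unlist(g)
  f <- factor(rep(1:3, each = 10))
  ref_aov <- summary(aov(y ~ f))[[1]]
  expect_equal(av$F, ref_aov[1, "F value"])
  expect_equal(av$p, ref_aov[1, "Pr(>F)"])
})

test_that("split-plot group F uses the subject-within-group error stratum", {
  set.seed(58)
  n <- 10; k <- 4
  subj_eff <- rnorm(2 * n, rep(c(0, 1), each = n), 1)
  vals <- matrix(rnorm(2 * n * k, subj_eff, 0.5), 2 * n, k)
  g <- rep(c("A", "B"), each = n)
  sp <- split_plot_anova(vals, g)
  # oracle: one-way ANOVA on subject means has the same F for the group
  # effect (balanced design)
  ref <- one_way_anova(split(rowMeans(vals), g))
  expect_equal(sp$F, ref$F, tolerance = 1e-8)
  expect_equal(sp$p, ref$p, tolerance = 1e-8)
  expect_equal(sp$dof, c(1, 2 * n - 2))
  expect_error(split_plot_anova(vals[-1, ], g[-c(1, 2)]), "label")
})

test_that("Bonferroni correction divides the familywise level", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("RRB strata comparison tests high against zero scorers", {
  set.seed(59)
  roi <- c(rnorm(8, 0.5, 0.05), rnorm(8, 0.42, 0.05))
  rrb <- c(rep(0L, 8), rep(1L, 4), rep(2L, 4))
  st <- rrb_strata_test(roi, rrb)
  ref <- t.test(roi[9:16], roi[1:8], var.equal = TRUE)
  expect_equal(st$t, unname(ref$statistic))
  expect_equal(st$n_rrb_ge1, 8)
  expect_error(rrb_strata_test(roi, rep(2L, 16)), "empty")
})
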