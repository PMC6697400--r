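#' Correlation with the parametric/nonparametric rule
#'
#' Uses Spearman's rank correlation when either variable is flagged ordinal
#' (e.g. ADOS scores), Pearson otherwise, with a two-sided p value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param x_ordinal,y_ordinal Logical flags marking nonparametric variables.
#' @return List with \code{method}, \code{estimate}, \code{p}, \code{n}.
#' @export
correlate <- function(x, y, x_ordinal = FALSE, y_ordinal = FALSE) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors with n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input")
  method <- if (x_ordinal || y_ordinal) "spearman" else "pearson"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(method = method, estimate = unname(ct$estimate), p = ct$p.value,
       n = length(x))
}

#' Partial correlation of x and y given z
#'
#' Pearson correlation of the residuals of x and y after regressing each on
#' z (with intercept). z may have several columns.
#'
#' @param x,y Numeric vectors.
#' @param z Numeric vector or matrix of conditioning variables.
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  z <- as.matrix(z)
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  Z <- cbind(1, z)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop("degenerate residuals: a variable is collinear with z")
  stats::cor(rx, ry)
}

row_centered_ss <- function(M) {
  if (nrow(M) == 0L) return(numeric(0))
  rowSums((M - rowMeans(M))^2)
}

# closed-form OLS paths of the two mediation regressions on (x, m, y) rows;
# resamples are expressed as index matrices so the bootstrap is vectorized
mediation_paths <- function(x, m, y, covariates = NULL) {
  X1 <- cbind(1, x)
  X2 <- cbind(1, x, m)
  if (!is.null(covariates)) {
    X1 <- cbind(X1, covariates)
    X2 <- cbind(X2, covariates)
  }
  f1 <- stats::lm.fit(X1, m)
  f2 <- stats::lm.fit(X2, y)
  a <- unname(f1$coefficients[2])
  g <- unname(f2$coefficients[2])
  b <- unname(f2$coefficients[3])
  se <- function(fit, j, Xc) {
    s2 <- sum(fit$residuals^2) / fit$df.residual
    sqrt(s2 * chol2inv(chol(crossprod(Xc)))[j, j])
  }
  list(alpha = a, beta = b, gamma = g,
       alpha_se = se(f1, 2, X1), beta_se = se(f2, 3, X2))
}

#' Nonparametric bootstrap mediation analysis
#'
#' Estimates the indirect effect of \code{x} on \code{y} through the
#' mediator \code{m} as the product of the x-to-m path (alpha) and the
#' m-to-y path controlling x (beta), with a percentile bootstrap over
#' subjects: both regressions are refit on each resample and the indirect
#' effect's CI and two-sided p value are read off the bootstrap
#' distribution (p floored at 1/n_boot).
#'
#' @param x Independent variable (e.g. median percept duration).
#' @param m Mediator (e.g. ROI gray-matter volume).
#' @param y Dependent variable (e.g. median task repetition length).
#' @param n_boot Number of bootstrap resamples (>= 1000 recommended).
#' @param seed Integer seed for the resampling.
#' @param covariates Optional per-subject covariate matrix.
#' @param conf Confidence level of the percentile interval.
#' @return A \code{mediation_result}: alpha, beta, gamma, indirect
#'   (= alpha * beta), SEs of the paths, CI, p_indirect, n, n_boot, seed.
#' @export
mediate <- function(x, m, y, n_boot = 10000L, seed = 1L, covariates = NULL,
                    conf = 0.95) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 subjects")
  if (length(m) != n || length(y) != n) stop("inputs must align")
  pt <- mediation_paths(x, m, y, covariates)
  set.seed(seed)
  redraws <- 0L
  if (is.null(covariates)) {
    # closed-form paths per resample, fully vectorized over resamples
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    xb <- matrix(x[idx], n_boot, n)
    mb <- matrix(m[idx], n_boot, n)
    yb <- matrix(y[idx], n_boot, n)
    bad <- which(row_centered_ss(xb) == 0 | row_centered_ss(mb) == 0)
    while (length(bad)) {
      redraws <- redraws + length(bad)
      if (redraws > 100L * n_boot) stop("too many degenerate resamples")
      idx[bad, ] <- sample.int(n, length(bad) * n, replace = TRUE)
      xb[bad, ] <- matrix(x[idx[bad, ]], length(bad), n)
      mb[bad, ] <- matrix(m[idx[bad, ]], length(bad), n)
      yb[bad, ] <- matrix(y[idx[bad, ]], length(bad), n)
      bad <- bad[row_centered_ss(xb[bad, , drop = FALSE]) == 0 |
                   row_centered_ss(mb[bad, , drop = FALSE]) == 0]
    }
    xc <- xb - rowMeans(xb)
    mc <- mb - rowMeans(mb)
    yc <- yb - rowMeans(yb)
    sxx <- rowSums(xc^2)
    sxm <- rowSums(xc * mc)
    sxy <- rowSums(xc * yc)
    smm <- rowSums(mc^2)
    smy <- rowSums(mc * yc)
    alpha_b <- sxm / sxx
    beta_b <- (sxx * smy - sxm * sxy) / (sxx * smm - sxm^2)
    boot_ind <- alpha_b * beta_b
  } else {
    boot_ind <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::var(x[idx]) > 0 && stats::var(m[idx]) > 0) break
        redraws <- redraws + 1L
        if (redraws > 100L * n_boot) stop("too many degenerate resamples")
      }
      pb <- mediation_paths(x[idx], m[idx], y[idx],
                            covariates[idx, , drop = FALSE])
      boot_ind[b] <- pb$alpha * pb$beta
    }
  }
  alpha_lvl <- 1 - conf
  ci <- stats::quantile(boot_ind, c(alpha_lvl / 2, 1 - alpha_lvl / 2),
                        names = FALSE)
  p <- 2 * min(mean(boot_ind <= 0), mean(boot_ind >= 0))
  p <- min(1, max(p, 1 / n_boot))
  structure(list(alpha = pt$alpha, beta = pt$beta, gamma = pt$gamma,
                 alpha_se = pt$alpha_se, beta_se = pt$beta_se,
                 indirect = pt$alpha * pt$beta,
                 ci_lower = ci[1], ci_upper = ci[2], p_indirect = p,
                 n = n, n_boot = n_boot, seed = seed,
                 boot_redraws = redraws),
            class = "mediation_result")
}

#' Voxelwise nonparametric mediation map
#'
#' Runs the scalar mediation at every in-mask voxel with that voxel's GMV
#' as mediator, using one shared set of bootstrap resample indices across
#' voxels (coherent null, tractable runtime), and applies BH-FDR to the
#' per-voxel indirect-effect p values.
#'
#' @param x Independent variable per subject.
#' @param volumes List of 3D GMV arrays.
#' @param y Dependent variable per subject.
#' @param mask Logical in-brain mask.
#' @param q FDR level.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the shared resample indices.
#' @return List with \code{indirect} and \code{p} 3D arrays,
#'   \code{fdr_mask}, \code{n_boot}, \code{seed}.
#' @export
voxelwise_mediation <- function(x, volumes, y, mask, q = 0.05,
                                n_boot = 1000L, seed = 1L) {
  n <- length(x)
  V <- sum(mask)
  M <- t(vapply(volumes, function(v) v[mask], numeric(V)))   # n x V
  set.seed(seed)
  idxmat <- matrix(0L, n_boot, n)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[idx]) > 0) break
    }
    idxmat[b, ] <- idx
  }
  point <- med_paths_matrix(x, M, y)
  ind0 <- point$alpha * point$beta
  count_le <- numeric(V)
  count_ge <- numeric(V)
  for (b in seq_len(n_boot)) {
    idx <- idxmat[b, ]
    pb <- med_paths_matrix(x[idx], M[idx, , drop = FALSE], y[idx])
    ind <- pb$alpha * pb$beta
    count_le <- count_le + (ind <= 0)
    count_ge <- count_ge + (ind >= 0)
  }
  p <- 2 * pmin(count_le, count_ge) / n_boot
  p <- pmin(1, pmax(p, 1 / n_boot))
  ind_map <- p_map <- array(NA_real_, dim = dim(mask))
  ind_map[mask] <- ind0
  p_map[mask] <- p
  surv <- stats::p.adjust(p, "BH") <= q
  fdr <- array(FALSE, dim = dim(mask))
  fdr[mask] <- surv
  list(indirect = ind_map, p = p_map, fdr_mask = fdr, n_boot = n_boot,
       seed = seed)
}

# vectorized mediation paths with a matrix of mediators (n x V):
# alpha_v from m_v ~ 1 + x; beta_v from y ~ 1 + x + m_v via
# Frisch-Waugh: residualize y and m_v on (1, x), then simple regression
med_paths_matrix <- function(x, M, y) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Mc <- sweep(M, 2, colMeans(M))
  alpha <- as.numeric(crossprod(xc, Mc)) / sxx
  yc <- y - mean(y)
  ry <- yc - xc * (sum(xc * yc) / sxx)
  RM <- Mc - outer(xc, alpha)
  denom <- colSums(RM^2)
  beta <- as.numeric(crossprod(ry, RM)) / denom
  list(alpha = alpha, beta = beta)
}

#' One-factor latent flexibility model fit by maximum likelihood
#'
#' Fits a single-latent-variable measurement model (factor variance fixed
#' at 1, free loadings, free residual variances) to the sample covariance
#' of the indicators by quasi-Newton maximization of the Wishart
#' log-likelihood, and reports conventional covariance-based fit indices:
#' AGFI, CFI (against the independence baseline), RMSEA, and SRMR. Sign
#' indeterminacy is resolved by forcing the first loading non-negative;
#' Heywood cases are bounded away from zero residual variance and flagged.
#'
#' @param indicators n x p numeric matrix (p >= 3, n > p).
#' @param standardize Standardize indicators to unit variance first
#'   (default TRUE).
#' @return A \code{sem_fit}: loadings, residual variances, fit indices,
#'   chi-square, dof, converged/heywood flags, log-likelihood.
#' @export
fit_latent_model <- function(indicators, standardize = TRUE) {
  X <- as.matrix(indicators)
  n <- nrow(X)
  p <- ncol(X)
  if (p < 3L) stop("need at least 3 indicators")
  if (n <= p) stop("need more observations than indicators")
  if (standardize) X <- scale(X)
  S <- stats::cov(X)
  lds <- sqrt(pmax(diag(S) * 0.5, 1e-4))
  start <- c(lds, log(pmax(diag(S) * 0.5, 1e-4)))
  fml <- function(par) {
    l <- par[1:p]
    psi <- exp(par[(p + 1):(2 * p)])
    Sigma <- tcrossprod(l) + diag(psi, p)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    ldet + sum(diag(chol2inv(ch) %*% S))
  }
  opt <- stats::optim(start, fml, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  l <- opt$par[1:p]
  psi <- exp(opt$par[(p + 1):(2 * p)])
  if (l[1] < 0) l <- -l
  heywood <- any(psi < 1e-6)
  psi <- pmax(psi, 1e-6)
  Sigma <- tcrossprod(l) + diag(psi, p)
  # ML fit function and chi-square
  F_ml <- opt$value - determinant(S, logarithm = TRUE)$modulus[1] - p
  F_ml <- max(F_ml, 0)
  df <- p * (p + 1) / 2 - 2 * p
  chisq <- (n - 1) * F_ml
  # baseline (independence) model
  S0 <- diag(diag(S), p)
  F0 <- determinant(S0, TRUE)$modulus[1] +
    sum(diag(solve(S0) %*% S)) - determinant(S, TRUE)$modulus[1] - p
  df0 <- p * (p - 1) / 2
  chisq0 <- (n - 1) * F0
  cfi <- if (max(chisq0 - df0, 0) == 0) 1 else
    1 - max(chisq - df, 0) / max(chisq0 - df0, chisq - df, 0)
  rmsea <- if (df <= 0) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))
  Sinv <- solve(Sigma)
  gfi_num <- sum(diag((Sinv %*% S - diag(p)) %*% (Sinv %*% S - diag(p))))
  gfi_den <- sum(diag((Sinv %*% S) %*% (Sinv %*% S)))
  gfi <- 1 - gfi_num / gfi_den
  agfi <- if (df <= 0) gfi else 1 - (p * (p + 1) / (2 * df)) * (1 - gfi)
  Dm <- diag(1 / sqrt(diag(S)), p)
  resid_std <- Dm %*% (S - Sigma) %*% Dm
  srmr <- sqrt(mean(resid_std[lower.tri(resid_std, diag = TRUE)]^2))
  loglik <- -n / 2 * (p * log(2 * pi) + opt$value)
  structure(list(loadings = l, residual_variances = psi,
                 chisq = chisq, df = df, AGFI = agfi, CFI = min(max(cfi, 0), 1),
                 RMSEA = rmsea, SRMR = srmr,
                 converged = opt$convergence == 0, heywood = heywood,
                 loglik = loglik, n = n),
            class = "sem_fit")
}

#' Group-comparison statistics
#'
#' Pooled-variance two-sample t test, pooled-SD Cohen's d, one-way ANOVA,
#' and the split-plot (repeated-measures) F for a group main effect over a
#' balanced subjects-by-runs layout (between-group mean square over
#' subject-within-group mean square).
#'
#' @param a,b Numeric vectors (one value per subject).
#' @return \code{two_sample_t}: list(t, dof, p); \code{cohens_d}: d.
#' @export
two_sample_t <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value)
}

#' @rdname two_sample_t
#' @export
cohens_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}

#' @rdname two_sample_t
#' @param groups List of numeric vectors, one per factor level.
#' @export
one_way_anova <- function(groups) {
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s[1, "F value"], dof = c(s[1, "Df"], s[2, "Df"]),
       p = s[1, "Pr(>F)"])
}

#' @rdname two_sample_t
#' @param values Matrix of subjects (rows) by runs (columns).
#' @param group_labels Factor/vector of group membership per subject.
#' @export
split_plot_anova <- function(values, group_labels) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  g <- factor(group_labels)
  if (length(g) != n) stop("one group label per subject required")
  if (length(unique(table(g))) != 1L)
    stop("unbalanced split-plot design not supported")
  subj <- factor(rep(seq_len(n), k))
  run <- factor(rep(seq_len(k), each = n))
  grp <- factor(rep(as.character(g), k))
  y <- as.vector(values)
  fit <- stats::aov(y ~ grp * run + Error(subj))
  s <- summary(fit)
  tab <- s[["Error: subj"]][[1]]
  F_grp <- tab["grp", "Mean Sq"] / tab["Residuals", "Mean Sq"]
  df1 <- tab["grp", "Df"]
  df2 <- tab["Residuals", "Df"]
  list(F = unname(F_grp), dof = c(df1, df2),
       p = stats::pf(F_grp, df1, df2, lower.tail = FALSE))
}

#' Bonferroni-adjusted alpha
#' @param alpha Familywise level; \code{k} number of comparisons.
#' @param k Number of comparisons.
#' @return alpha / k.
#' @export
bonferroni_alpha <- function(alpha, k) {
  if (k < 1) stop("'k' must be at least 1")
  alpha / k
}

#' ROI GMV comparison between RRB strata
#'
#' Two-sample t test (pooled variance) of ROI gray-matter volume between
#' clinical subjects with restricted-repetitive-behavior score >= 1 and
#' those with score 0.
#'
#' @param roi_means ROI mean GMV per subject.
#' @param ados_rrb Ordinal RRB scores aligned with \code{roi_means}.
#' @return List with t, dof, p, group means, and stratum sizes.
#' @export
rrb_strata_test <- function(roi_means, ados_rrb) {
  hi <- roi_means[ados_rrb >= 1]
  lo <- roi_means[ados_rrb == 0]
  if (length(hi) == 0L) stop("stratum 'RRB >= 1' is empty")
  if (length(lo) == 0L) stop("stratum 'RRB = 0' is empty")
  tt <- two_sample_t(hi, lo)
  c(tt, list(mean_rrb_ge1 = mean(hi), mean_rrb_0 = mean(lo),
             n_rrb_ge1 = length(hi), n_rrb_0 = length(lo)))
}
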