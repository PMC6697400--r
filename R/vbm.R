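#' Voxelwise regression of gray-matter volume on a behavioral index
#'
#' Fits, at every in-mask voxel, an ordinary least-squares regression of GMV
#' on an intercept, the behavioral index, and optional covariates (age and
#' full IQ in the canonical analysis), and returns the t statistic and
#' two-sided p value for the behavioral coefficient.
#'
#' @param volumes List of 3D GMV arrays, one per subject.
#' @param behavior Numeric vector, one value per subject.
#' @param covariates Numeric matrix or data frame of per-subject covariates
#'   (or \code{NULL}).
#' @param mask Logical 3D array of in-brain voxels.
#' @return A \code{voxel_stat_map}: list with \code{t} and \code{p} 3D
#'   arrays (NA outside the mask), \code{dof}, \code{mask},
#'   \code{regressor}.
#' @export
voxelwise_regression <- function(volumes, behavior, covariates = NULL,
                                 mask) {
  n <- length(volumes)
  if (length(behavior) != n)
    stop("'behavior' must have one value per subject")
  if (stats::var(behavior) == 0)
    stop("'behavior' is constant; regression undefined")
  X <- cbind(intercept = 1, behavior = behavior)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (n < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L, " subjects for ", ncol(X),
         " predictors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- vapply(volumes, function(v) v[mask], numeric(sum(mask)))
  Y <- t(Y)                                     # n x V
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)               # p x V
  res <- Y - X %*% B
  dof <- n - ncol(X)
  sigma2 <- colSums(res^2) / dof
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tv <- B[2, ] / se
  pv <- 2 * stats::pt(abs(tv), dof, lower.tail = FALSE)
  t_map <- p_map <- array(NA_real_, dim = dim(mask))
  t_map[mask] <- tv
  p_map[mask] <- pv
  structure(list(t = t_map, p = p_map, dof = dof, mask = mask,
                 regressor = "behavior"), class = "voxel_stat_map")
}

#' Benjamini-Hochberg FDR threshold over in-mask voxels
#'
#' @param stat_map A \code{voxel_stat_map}.
#' @param q FDR level in (0, 1).
#' @return Logical 3D array of surviving voxels.
#' @export
fdr_threshold <- function(stat_map, q = 0.05) {
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  mask <- stat_map$mask
  if (sum(mask) == 0L) stop("mask is empty")
  p <- stat_map$p[mask]
  surv <- stats::p.adjust(p, method = "BH") <= q
  out <- array(FALSE, dim = dim(mask))
  out[mask] <- surv
  out
}

#' Split an FDR-surviving mask by the sign of t
#'
#' @param stat_map A \code{voxel_stat_map}.
#' @param fdr_mask Logical array from \code{\link{fdr_threshold}} on the
#'   same map.
#' @return List with \code{positive} and \code{negative} logical arrays;
#'   disjoint, with union equal to \code{fdr_mask}.
#' @export
signed_maps <- function(stat_map, fdr_mask) {
  pos <- fdr_mask & !is.na(stat_map$t) & stat_map$t > 0
  neg <- fdr_mask & !is.na(stat_map$t) & stat_map$t < 0
  list(positive = pos, negative = neg)
}

#' Conjunction (voxelwise intersection) of two masks
#'
#' @param mask_a,mask_b Logical arrays on the same grid.
#' @return Logical array of voxels present in both.
#' @export
conjunction <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks are on different grids")
  mask_a & mask_b
}

#' Connected-component clusters of a suprathreshold mask
#'
#' Labels 26-connected components and reports, per cluster, its size and
#' the peak |t| voxel in 0-based voxel indices and in mm (volume-centered
#' coordinates derived from the voxel size).
#'
#' @param mask Logical 3D array.
#' @param t_map 3D array of t values (for peak localization); may contain
#'   NAs outside the mask.
#' @param voxel_size_mm Isotropic voxel size for mm coordinates.
#' @return Data frame with one row per cluster: \code{label}, \code{size},
#'   \code{peak_t}, \code{peak_i/j/k} (0-based), \code{peak_x/y/z_mm};
#'   plus attribute \code{labels}, the labeled 3D array.
#' @export
extract_clusters <- function(mask, t_map = NULL, voxel_size_mm = 1) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  idx_all <- which(mask)
  if (length(idx_all) == 0L) {
    out <- data.frame(label = integer(0), size = integer(0),
                      peak_t = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0))
    attr(out, "labels") <- labels
    return(out)
  }
  # 26-neighbourhood linear-index offsets
  nb <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  nb <- nb[!(nb$di == 0 & nb$dj == 0 & nb$dk == 0), ]
  coords <- arrayInd(idx_all, dims)
  in_mask <- array(FALSE, dims)
  in_mask[idx_all] <- TRUE
  lab <- 0L
  rows <- list()
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    members <- start
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(cur, dims)
      for (r in seq_len(nrow(nb))) {
        ni <- ci[1] + nb$di[r]; nj <- ci[2] + nb$dj[r]; nk <- ci[3] + nb$dk[r]
        if (ni < 1 || nj < 1 || nk < 1 || ni > dims[1] || nj > dims[2] ||
            nk > dims[3]) next
        lin <- ni + (nj - 1L) * dims[1] + (nk - 1L) * dims[1] * dims[2]
        if (in_mask[lin] && labels[lin] == 0L) {
          labels[lin] <- lab
          queue <- c(queue, lin)
          members <- c(members, lin)
        }
      }
    }
    tv <- if (is.null(t_map)) rep(0, length(members)) else t_map[members]
    pk <- members[which.max(abs(tv))]
    pc <- arrayInd(pk, dims)
    ctr <- (dims + 1) / 2
    rows[[lab]] <- data.frame(
      label = lab, size = length(members),
      peak_t = if (is.null(t_map)) NA_real_ else t_map[pk],
      peak_i = pc[1] - 1L, peak_j = pc[2] - 1L, peak_k = pc[3] - 1L,
      peak_x_mm = (pc[1] - ctr[1]) * voxel_size_mm,
      peak_y_mm = (pc[2] - ctr[2]) * voxel_size_mm,
      peak_z_mm = (pc[3] - ctr[3]) * voxel_size_mm)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$size), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

#' ROI and whole-brain GMV summaries
#'
#' \code{roi_mean_gmv} is the mean GMV over an ROI; \code{whole_brain_gmv}
#' is the sum over the in-brain mask; \code{relative_gmv} is the ratio of
#' the ROI mean to the whole-brain total (scale-invariant).
#'
#' @param volume 3D GMV array.
#' @param roi_mask Logical array, subset of the in-brain mask.
#' @param brain_mask Logical in-brain mask.
#' @return A single numeric value.
#' @export
roi_mean_gmv <- function(volume, roi_mask) {
  if (sum(roi_mask) == 0L) stop("ROI mask is empty")
  mean(volume[roi_mask])
}

#' @rdname roi_mean_gmv
#' @export
whole_brain_gmv <- function(volume, brain_mask) {
  sum(volume[brain_mask])
}

#' @rdname roi_mean_gmv
#' @export
relative_gmv <- function(volume, roi_mask, brain_mask) {
  roi_mean_gmv(volume, roi_mask) / whole_brain_gmv(volume, brain_mask)
}

#' Voxelwise group-difference map
#'
#' Per-voxel comparison of two groups implemented as OLS on a group
#' indicator (group B coded 1) with optional covariates; with no covariates
#' this equals the pooled-variance two-sample t test. One- or two-tailed p
#' values; BH-FDR mask at level \code{q}.
#'
#' @param volumes_a,volumes_b Lists of 3D arrays for the two groups.
#' @param covariates Per-subject covariate matrix for all subjects of both
#'   groups (A first), or \code{NULL}.
#' @param mask Logical in-brain mask.
#' @param q FDR level.
#' @param tail \code{"two.sided"}, \code{"less"} (B < A), or
#'   \code{"greater"} (B > A).
#' @return List with \code{map} (a \code{voxel_stat_map}, t for the group-B
#'   indicator) and \code{fdr_mask}.
#' @export
group_difference_map <- function(volumes_a, volumes_b, covariates = NULL,
                                 mask, q = 0.05, tail = "two.sided") {
  if (length(volumes_a) < 3L || length(volumes_b) < 3L)
    stop("each group needs at least 3 subjects")
  grp <- c(rep(0, length(volumes_a)), rep(1, length(volumes_b)))
  map <- voxelwise_regression(c(volumes_a, volumes_b), grp, covariates,
                              mask)
  if (tail != "two.sided") {
    tv <- map$t[mask]
    pv <- stats::pt(tv, map$dof,
                    lower.tail = (tail == "less"))
    map$p[mask] <- pv
  }
  list(map = map, fdr_mask = fdr_threshold(map, q))
}
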