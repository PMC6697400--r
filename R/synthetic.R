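#' Generate one bistable-perception run for a given rigidity component
#'
#' Produces an alternating stream of clear up/down percepts with
#' gamma-distributed durations whose scale -- and hence median -- increases
#' monotonically with the subject's perceptual rigidity component. With
#' probability \code{mixed_prob}, a short exponential mixed/unsure interval
#' follows a clear percept. Events are truncated at the run end. Uses the
#' current RNG state unless \code{seed} is given.
#'
#' @param trait Perceptual rigidity component (finite scalar).
#' @param spec A \code{\link{cohort_spec}}.
#' @param run_index Run number stored in the timeline.
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{run_index}, \code{onset_s},
#'   \code{label}.
#' @export
generate_percept_timeline <- function(trait, spec, run_index = 1L,
                                      seed = NULL) {
  stopifnot(is.finite(trait))
  if (!is.null(seed)) set.seed(seed)
  scale <- spec$percept_scale_base * exp(spec$percept_slope * trait)
  t <- 0
  onsets <- numeric(0)
  labels <- character(0)
  lab <- if (stats::runif(1) < 0.5) "up" else "down"
  while (t < spec$run_length_s) {
    onsets <- c(onsets, t)
    labels <- c(labels, lab)
    t <- t + stats::rgamma(1, shape = spec$percept_shape, scale = scale)
    if (spec$mixed_prob > 0 && t < spec$run_length_s &&
        stats::runif(1) < spec$mixed_prob) {
      onsets <- c(onsets, t)
      labels <- c(labels, "mixed")
      t <- t + stats::rexp(1, rate = 1 / spec$mixed_mean_s)
    }
    lab <- if (lab == "up") "down" else "up"
  }
  data.frame(run_index = run_index, onset_s = onsets, label = labels)
}

# n trials' stimuli: 4 figures each, exactly one circle (the target shape)
# and one uniquely brightest figure that is never the circle
random_stimuli <- function(n) {
  target <- sample.int(4L, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  brightest <- ((target - 1L + shift) %% 4L) + 1L   # any position != target
  perms3 <- matrix(c(1L,2L,3L, 1L,3L,2L, 2L,1L,3L, 2L,3L,1L, 3L,1L,2L,
                     3L,2L,1L), ncol = 3L, byrow = TRUE)
  pk <- perms3[sample.int(6L, n, replace = TRUE), , drop = FALSE]
  levels <- matrix(0L, n, 4L)
  others <- matrix(0L, n, 3L)           # column indices != brightest
  for (j in 1:3) others[, j] <- ((brightest - 1L + j) %% 4L) + 1L
  idx <- rep(seq_len(n), 3L)
  levels[cbind(idx, as.vector(others))] <- as.vector(pk)
  levels[cbind(seq_len(n), brightest)] <- 4L
  list(target_index = target, brightest_index = brightest,
       brightness_levels = levels)
}

#' Generate one spontaneous task-switching run
#'
#' Task choice follows a two-state persistence process: the subject repeats
#' the previous task with their persistence probability and switches
#' otherwise, yielding geometric run lengths. Each trial carries a stimulus
#' of four figures in which exactly one is the designated shape (circle) and
#' a distinct one is uniquely brightest, so retrospective task inference is
#' well defined. A small lapse rate yields unclassifiable choices; timeouts
#' end a trial with no response. Trials accumulate until the run's time
#' budget (RT plus inter-trial interval) is exhausted.
#'
#' @param trait Cognitive rigidity component (finite scalar).
#' @param spec A \code{\link{cohort_spec}}.
#' @param run_index Run number stored in the trial log.
#' @param seed Optional integer seed.
#' @return Data frame of trials: \code{run_index}, \code{trial_index},
#'   \code{mode}, \code{cue}, \code{task} (the latent intended task),
#'   \code{target_index}, \code{brightest_index}, \code{b1..b4} brightness
#'   levels, \code{choice_index} (NA on timeout), \code{rt_ms}.
#' @export
generate_spontaneous_session <- function(trait, spec, run_index = 1L,
                                         seed = NULL) {
  stopifnot(is.finite(trait))
  if (!is.null(seed)) set.seed(seed)
  p <- stats::plogis(stats::qlogis(spec$persistence_base) +
                       spec$persistence_slope * trait)
  rp <- spec$rt_params
  budget_ms <- spec$trial_budget_s * 1000
  # generous upper bound on trial count, trimmed by cumulative time below
  n_max <- ceiling(budget_ms / (rp$rt_repeat_ms * 0.5 + rp$iti_ms)) + 10L
  switch_draw <- stats::runif(n_max) >= p
  switch_draw[1] <- stats::runif(1) < 0.5   # first trial: coin flip on task
  tasks <- ifelse(cumsum(switch_draw) %% 2L == 0L, "shape", "brightness")
  is_switch <- c(FALSE, tasks[-1L] != tasks[-n_max])
  stim <- random_stimuli(n_max)
  u <- stats::runif(n_max)
  timeout <- u < spec$timeout_prob
  lapse <- !timeout & u < spec$timeout_prob + spec$lapse_rate
  choice <- ifelse(tasks == "shape", stim$target_index, stim$brightest_index)
  if (any(lapse)) {
    # lapse: a figure that is neither the circle nor the brightest
    for (i in which(lapse))
      choice[i] <- sample(setdiff(1:4, c(stim$target_index[i],
                                         stim$brightest_index[i])), 1L)
  }
  choice[timeout] <- NA_integer_
  rt <- stats::rnorm(n_max, rp$rt_repeat_ms +
                       ifelse(is_switch, rp$switch_cost_ms, 0), rp$rt_sd_ms)
  rt <- pmin(pmax(rt, 200), 3000)
  rt[timeout] <- 3000
  n <- which(cumsum(rt + rp$iti_ms) >= budget_ms)[1]
  if (is.na(n)) n <- n_max
  keep <- seq_len(n)
  data.frame(run_index = run_index, trial_index = keep,
             mode = "spontaneous", cue = "none", task = tasks[keep],
             target_index = stim$target_index[keep],
             brightest_index = stim$brightest_index[keep],
             b1 = stim$brightness_levels[keep, 1],
             b2 = stim$brightness_levels[keep, 2],
             b3 = stim$brightness_levels[keep, 3],
             b4 = stim$brightness_levels[keep, 4],
             choice_index = choice[keep], rt_ms = rt[keep])
}

#' Yoke an instructed session to a classified spontaneous session
#'
#' The instruction cue sequence equals the spontaneous session's inferred
#' task sequence with unclassifiable trials omitted; stimuli are
#' regenerated and fresh reaction times are drawn with instructed-mode
#' parameters (slower, with a substantial switch cost). Choices follow the
#' cue with probability \code{instructed_accuracy}.
#'
#' @param spont_trials Data frame of spontaneous trials (one run).
#' @param spec A \code{\link{cohort_spec}}.
#' @param seed Optional integer seed.
#' @return Data frame of instructed trials with the same columns as
#'   \code{\link{generate_spontaneous_session}} (mode "instructed",
#'   \code{cue} set, \code{task} equal to the cue).
#' @export
yoke_instructed_session <- function(spont_trials, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- classify_session(spont_trials)
  cues <- labels[labels != "unclassifiable"]
  if (length(cues) == 0L)
    stop("spontaneous session has no classifiable trials to yoke")
  rp <- spec$rt_params
  run <- spont_trials$run_index[1]
  n <- length(cues)
  stim <- random_stimuli(n)
  correct <- ifelse(cues == "shape", stim$target_index,
                    stim$brightest_index)
  choice <- correct
  err <- stats::runif(n) >= spec$instructed_accuracy
  for (i in which(err))
    choice[i] <- sample(setdiff(1:4, correct[i]), 1L)
  is_switch <- c(FALSE, cues[-1L] != cues[-n])
  rt <- stats::rnorm(n, rp$rt_repeat_ms + rp$instructed_offset_ms +
                       ifelse(is_switch, rp$instructed_switch_cost_ms, 0),
                     rp$rt_sd_ms)
  data.frame(run_index = run, trial_index = seq_len(n),
             mode = "instructed", cue = cues, task = cues,
             target_index = stim$target_index,
             brightest_index = stim$brightest_index,
             b1 = stim$brightness_levels[, 1],
             b2 = stim$brightness_levels[, 2],
             b3 = stim$brightness_levels[, 3],
             b4 = stim$brightness_levels[, 4],
             choice_index = choice,
             rt_ms = pmin(pmax(rt, 200), 3000))
}

#' Generate per-subject gray-matter-volume images
#'
#' Each volume is a baseline GMV field plus Gaussian-smoothed voxel noise
#' inside an ellipsoidal in-brain mask. Within the planted spherical
#' cluster, mean GMV is shifted by \code{cluster_effect} times the
#' standardized latent trait, applied after smoothing so the planted effect
#' is uniform over the sphere. A whole-brain group offset emulates the
#' marginally larger total GMV of the clinical group.
#'
#' @param traits Numeric vector of structural rigidity substrates (one per
#'   subject; group means \code{trait_mean_*}, within-group SD
#'   \code{trait_sd}).
#' @param groups Character vector ("ASD"/"TD") aligned with \code{traits}.
#' @param spec A \code{\link{cohort_spec}}.
#' @param seed Optional integer seed.
#' @return List with \code{volumes} (list of 3D arrays), \code{mask}
#'   (logical 3D array), \code{cluster_mask}, and \code{voxel_size_mm}.
#' @export
generate_gmv_images <- function(traits, groups, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- spec$volume_shape
  mask <- ellipsoid_mask(dims)
  cl <- sphere_mask(dims, spec$cluster_center,
                    spec$cluster_radius_mm / spec$voxel_size_mm)
  if (!all(mask[cl]))
    stop("planted cluster extends outside the in-brain mask")
  zc <- (traits - spec$trait_mean_td) / spec$trait_sd
  vols <- vector("list", length(traits))
  for (s in seq_along(traits)) {
    noise <- array(stats::rnorm(prod(dims), 0, spec$noise_sd), dim = dims)
    if (spec$noise_sd > 0)
      noise <- gaussian_smooth_3d(noise, spec$smooth_fwhm_mm,
                                  spec$voxel_size_mm)
    v <- array(spec$baseline_gmv, dim = dims) + noise
    if (groups[s] == "ASD") v <- v + spec$group_gmv_offset
    v[cl] <- v[cl] + spec$cluster_effect * zc[s]
    v[!mask] <- 0
    vols[[s]] <- v
  }
  list(volumes = vols, mask = mask, cluster_mask = cl,
       voxel_size_mm = spec$voxel_size_mm)
}

#' Generate a full synthetic cohort
#'
#' Draws one latent rigidity trait per subject (group-specific means), maps
#' it to percept timelines, spontaneous and yoked instructed task-switching
#' sessions, GMV volumes with the planted cluster, demographics, and ADOS
#' scores (clinical group only; the ordinal RRB score is a fixed-quantile
#' discretization of the trait). Identical spec and seed give identical
#' cohorts.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param generate_volumes Logical; set \code{FALSE} to skip GMV volumes
#'   (behavior-only cohorts, e.g. large-n calibration checks).
#' @return An object of class \code{cohort_dataset}: list with \code{spec},
#'   \code{subjects} (per-subject lists), \code{mask},
#'   \code{cluster_mask}, \code{voxel_size_mm}.
#' @export
generate_cohort <- function(spec, generate_volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_group
  groups <- rep(c("ASD", "TD"), each = n)
  means <- ifelse(groups == "ASD", spec$trait_mean_asd, spec$trait_mean_td)
  z <- stats::rnorm(2 * n, means, spec$trait_sd)
  # inflate the latent loading so the realized (measured) behavioral
  # correlation converges to the target despite finite-sampling attenuation
  lam2 <- spec$trait_behavior_corr / spec$behavior_attenuation
  lam <- sqrt(lam2)
  resid_sd <- sqrt(1 - lam2) * spec$trait_sd
  u_percept <- lam * (z - means) + stats::rnorm(2 * n, 0, resid_sd) +
    means
  u_task <- lam * (z - means) + stats::rnorm(2 * n, 0, resid_sd) + means
  # structural rigidity substrate: the region underlies both behaviors, so
  # its planted effect tracks the mean of the two latent components
  # (rescaled to unit within-group SD), not only their common factor
  w_sd <- sqrt((1 + lam2) / 2) * spec$trait_sd
  w <- means + ((u_percept + u_task) / 2 - means) * spec$trait_sd / w_sd

  demo <- spec$demo_calibration
  draw_demo <- function(cal, grp)
    stats::rnorm(1, cal[[tolower(grp)]]["mean"], cal[[tolower(grp)]]["sd"])
  cuts <- stats::qnorm(demo$rrb_quantile_cuts, spec$trait_mean_asd,
                       spec$trait_sd)

  subjects <- vector("list", 2 * n)
  for (s in seq_len(2 * n)) {
    grp <- groups[s]
    age <- max(18, draw_demo(demo$age, grp))
    draw_iq <- function(cal) {
      iq <- round(draw_demo(cal, grp))
      max(iq, demo$iq_floor)          # high-functioning inclusion criterion
    }
    ados_soc <- ados_com <- ados_rrb <- NA_integer_
    if (grp == "ASD") {
      ados_soc <- max(0L, as.integer(round(stats::rnorm(
        1, demo$ados_social["mean"], demo$ados_social["sd"]))))
      ados_com <- max(0L, as.integer(round(stats::rnorm(
        1, demo$ados_communication["mean"], demo$ados_communication["sd"]))))
      ados_rrb <- as.integer(findInterval(z[s], cuts))
    }
    timelines <- lapply(seq_len(spec$n_runs), function(r)
      generate_percept_timeline(u_percept[s], spec, run_index = r))
    spont <- lapply(seq_len(spec$n_runs), function(r)
      generate_spontaneous_session(u_task[s], spec, run_index = r))
    instr <- lapply(spont, yoke_instructed_session, spec = spec)
    subjects[[s]] <- list(
      id = sprintf("%s%02d", tolower(grp), ((s - 1L) %% n) + 1L),
      group = grp, trait = z[s],
      age = age, full_iq = draw_iq(demo$full_iq),
      verbal_iq = draw_iq(demo$verbal_iq),
      performance_iq = draw_iq(demo$performance_iq),
      ados_social = ados_soc, ados_communication = ados_com,
      ados_rrb = ados_rrb,
      percept_timelines = timelines,
      spontaneous_trials = do.call(rbind, spont),
      instructed_trials = do.call(rbind, instr))
  }
  mask <- cl <- NULL
  if (generate_volumes) {
    gmv <- generate_gmv_images(w, groups, spec)
    for (s in seq_len(2 * n)) subjects[[s]]$gmv <- gmv$volumes[[s]]
    mask <- gmv$mask
    cl <- gmv$cluster_mask
  }
  structure(list(spec = spec, subjects = subjects, mask = mask,
                 cluster_mask = cl,
                 voxel_size_mm = spec$voxel_size_mm),
            class = "cohort_dataset")
}

# ---- geometry helpers -------------------------------------------------

#' Ellipsoidal in-brain mask inscribed in a voxel grid
#' @param dims Integer vector of 3 grid dimensions.
#' @param margin Voxels left free along each semi-axis (default 4).
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(dims, margin = 4) {
  ctr <- (dims + 1) / 2
  semi <- (dims - 2 * margin) / 2
  g <- expand_grid_indices(dims)
  d2 <- ((g[, 1] - ctr[1]) / semi[1])^2 + ((g[, 2] - ctr[2]) / semi[2])^2 +
    ((g[, 3] - ctr[3]) / semi[3])^2
  array(d2 <= 1, dim = dims)
}

#' Spherical mask in voxel units
#' @param dims Grid dimensions; \code{center} in 1-based voxel indices;
#'   \code{radius_vox} in voxels.
#' @param center,radius_vox Sphere geometry.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(dims, center, radius_vox) {
  g <- expand_grid_indices(dims)
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
    (g[, 3] - center[3])^2
  array(d2 <= radius_vox^2, dim = dims)
}

expand_grid_indices <- function(dims) {
  as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                        k = seq_len(dims[3])))
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with a separable Gaussian kernel specified by its
#' full width at half maximum in mm, converted to voxels via the voxel
#' size. Kernels are truncated at three standard deviations and
#' renormalized; edges use zero padding implicitly through renormalized
#' partial kernels (convolution matrix rows renormalized to sum 1).
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm Full width at half maximum, mm.
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @return Smoothed 3D array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  dims <- dim(arr)
  conv_mat <- function(n) {
    r <- ceiling(3 * sigma)
    k <- stats::dnorm(-r:r, sd = sigma)
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      lo <- max(1, i - r); hi <- min(n, i + r)
      M[i, lo:hi] <- k[(lo:hi) - i + r + 1]
    }
    M / rowSums(M)
  }
  x <- arr
  # axis 1
  x <- array(conv_mat(dims[1]) %*% matrix(x, dims[1]), dim = dims)
  # axis 2
  xp <- aperm(x, c(2, 1, 3))
  xp <- array(conv_mat(dims[2]) %*% matrix(xp, dims[2]), dim = dim(xp))
  x <- aperm(xp, c(2, 1, 3))
  # axis 3
  xp <- aperm(x, c(3, 1, 2))
  xp <- array(conv_mat(dims[3]) %*% matrix(xp, dims[3]), dim = dim(xp))
  aperm(xp, c(2, 3, 1))
}
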