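#' Specification of a synthetic study cohort
#'
#' Defines every parameter of the synthetic cohort generator. One scalar
#' latent rigidity trait per subject drives the percept-duration scale, the
#' task-persistence probability, the planted gray-matter cluster, and (for
#' the clinical group) the ordinal restricted-repetitive-behavior score;
#' the correlation between the two behavioral indices is induced solely
#' through this shared trait. Demographic calibration follows a matched
#' two-group design of high-functioning adults (22 per group by default).
#'
#' @param n_per_group Subjects per group (ASD and TD).
#' @param trait_mean_td,trait_mean_asd Latent rigidity-trait means
#'   (dimensionless); the ASD mean is higher by default, producing longer
#'   percept durations and repetition runs.
#' @param trait_sd Within-group trait standard deviation.
#' @param trait_behavior_corr Target correlation between the two realized
#'   behavioral indices within a group, in (0, 1); induced by loading each
#'   behavior on the shared trait.
#' @param behavior_attenuation Product of the measurement reliabilities of
#'   the two median behavioral indices under the default run structure
#'   (finite trials and runs attenuate the latent correlation). The latent
#'   loading is inflated by this factor so the realized correlation matches
#'   \code{trait_behavior_corr}; the default 0.85 was estimated once from
#'   the generating model at large n.
#' @param percept_shape Gamma shape parameter of percept durations.
#' @param percept_scale_base Gamma scale (seconds) at trait 0.
#' @param percept_slope Log-scale increment of the gamma scale per unit of
#'   the perceptual rigidity component.
#' @param mixed_prob Probability that a mixed/unsure interval follows a
#'   clear percept; with \code{mixed_mean_s} calibrated so mixed intervals
#'   occupy about 1.7\% of run time.
#' @param mixed_mean_s Mean duration (seconds) of a mixed interval.
#' @param persistence_base Task-persistence probability at trait 0.
#' @param persistence_slope Logit-scale increment of persistence per unit of
#'   the cognitive rigidity component.
#' @param run_length_s Bistable-perception run length in seconds.
#' @param n_runs Number of runs per test.
#' @param trial_budget_s Seconds of task-switching trials per run.
#' @param rt_params List of reaction-time parameters in ms:
#'   \code{rt_repeat_ms}, \code{switch_cost_ms} (spontaneous, near zero),
#'   \code{rt_sd_ms}, \code{iti_ms}, \code{instructed_offset_ms},
#'   \code{instructed_switch_cost_ms}.
#' @param lapse_rate Per-trial probability of an unclassifiable choice.
#' @param timeout_prob Per-trial probability of a response timeout.
#' @param instructed_accuracy Probability of following the cue in the
#'   instructed session.
#' @param volume_shape Integer vector of 3 voxel-grid dimensions.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param cluster_center Planted-cluster center in voxel indices (1-based).
#' @param cluster_radius_mm Planted-cluster radius in mm.
#' @param cluster_effect Loading of the standardized latent trait on mean
#'   GMV inside the cluster (negative in the default scenario: more rigid
#'   subjects have less gray matter there).
#' @param baseline_gmv Baseline in-brain GMV value (arbitrary modulated
#'   units).
#' @param noise_sd Voxel noise SD before spatial smoothing.
#' @param smooth_fwhm_mm FWHM of the generator's Gaussian smoothing; models
#'   the spatial correlation of preprocessed maps, not the preprocessing
#'   itself.
#' @param group_gmv_offset Whole-brain GMV offset added to ASD subjects
#'   (slightly positive by default).
#' @param demo_calibration Named list of per-group age/IQ means and SDs and
#'   ADOS score means and SDs.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 22L,
                        trait_mean_td = 0, trait_mean_asd = 1.0,
                        trait_sd = 1,
                        trait_behavior_corr = 0.45,
                        behavior_attenuation = 0.85,
                        percept_shape = 2.5,
                        percept_scale_base = 2.3,
                        percept_slope = 0.35,
                        mixed_prob = 0.066,
                        mixed_mean_s = 1.5,
                        persistence_base = 0.75,
                        persistence_slope = 0.35,
                        run_length_s = 90,
                        n_runs = 5L,
                        trial_budget_s = 180,
                        rt_params = list(rt_repeat_ms = 600,
                                         switch_cost_ms = 10,
                                         rt_sd_ms = 150,
                                         iti_ms = 250,
                                         instructed_offset_ms = 80,
                                         instructed_switch_cost_ms = 150),
                        lapse_rate = 0.01,
                        timeout_prob = 0.002,
                        instructed_accuracy = 0.965,
                        volume_shape = c(32L, 32L, 32L),
                        voxel_size_mm = 3,
                        cluster_center = c(20, 18, 19),
                        cluster_radius_mm = 18,
                        cluster_effect = -0.08,
                        baseline_gmv = 0.5,
                        noise_sd = 0.12,
                        smooth_fwhm_mm = 8,
                        group_gmv_offset = 0.005,
                        demo_calibration = default_demo_calibration(),
                        seed = 1L) {
  chk_pos <- function(x, nm) if (!is.numeric(x) || any(x <= 0))
    stop(sprintf("'%s' must be positive", nm))
  chk_prob <- function(x, nm) if (!is.numeric(x) || x < 0 || x >= 1)
    stop(sprintf("'%s' must be a probability in [0, 1)", nm))
  if (n_per_group < 1) stop("'n_per_group' must be a positive count")
  chk_pos(trait_sd, "trait_sd")
  if (trait_behavior_corr <= 0 || trait_behavior_corr >= 1)
    stop("'trait_behavior_corr' must lie in (0, 1)")
  if (behavior_attenuation <= 0 || behavior_attenuation > 1)
    stop("'behavior_attenuation' must lie in (0, 1]")
  if (trait_behavior_corr / behavior_attenuation >= 1)
    stop("'trait_behavior_corr' too high to realize at this 'behavior_attenuation'")
  chk_pos(percept_shape, "percept_shape")
  chk_pos(percept_scale_base, "percept_scale_base")
  chk_prob(mixed_prob, "mixed_prob")
  chk_pos(mixed_mean_s, "mixed_mean_s")
  if (persistence_base <= 0 || persistence_base >= 1)
    stop("'persistence_base' must lie in (0, 1)")
  chk_pos(run_length_s, "run_length_s")
  if (n_runs < 1) stop("'n_runs' must be a positive count")
  chk_pos(trial_budget_s, "trial_budget_s")
  chk_prob(lapse_rate, "lapse_rate")
  chk_prob(timeout_prob, "timeout_prob")
  if (instructed_accuracy <= 0 || instructed_accuracy > 1)
    stop("'instructed_accuracy' must lie in (0, 1]")
  if (length(volume_shape) != 3L || any(volume_shape < 4))
    stop("'volume_shape' must be 3 dimensions of at least 4 voxels")
  chk_pos(voxel_size_mm, "voxel_size_mm")
  chk_pos(cluster_radius_mm, "cluster_radius_mm")
  r_vox <- cluster_radius_mm / voxel_size_mm
  if (any(cluster_center - r_vox < 1) ||
      any(cluster_center + r_vox > volume_shape))
    stop("'cluster_center'/'cluster_radius_mm': planted cluster extends outside the volume")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  chk_pos(smooth_fwhm_mm, "smooth_fwhm_mm")
  structure(list(
    n_per_group = as.integer(n_per_group),
    trait_mean_td = trait_mean_td, trait_mean_asd = trait_mean_asd,
    trait_sd = trait_sd, trait_behavior_corr = trait_behavior_corr,
    behavior_attenuation = behavior_attenuation,
    percept_shape = percept_shape, percept_scale_base = percept_scale_base,
    percept_slope = percept_slope,
    mixed_prob = mixed_prob, mixed_mean_s = mixed_mean_s,
    persistence_base = persistence_base,
    persistence_slope = persistence_slope,
    run_length_s = run_length_s, n_runs = as.integer(n_runs),
    trial_budget_s = trial_budget_s, rt_params = rt_params,
    lapse_rate = lapse_rate, timeout_prob = timeout_prob,
    instructed_accuracy = instructed_accuracy,
    volume_shape = as.integer(volume_shape),
    voxel_size_mm = voxel_size_mm,
    cluster_center = cluster_center,
    cluster_radius_mm = cluster_radius_mm,
    cluster_effect = cluster_effect, baseline_gmv = baseline_gmv,
    noise_sd = noise_sd, smooth_fwhm_mm = smooth_fwhm_mm,
    group_gmv_offset = group_gmv_offset,
    demo_calibration = demo_calibration,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Default demographic calibration
#'
#' Group means and SDs for age and Wechsler IQ subscales, and ADOS score
#' distributions for the clinical group, matching a matched cohort of
#' high-functioning adults (IQ floor 85). SDs are on the subject level.
#'
#' @return Named list used by \code{\link{cohort_spec}}.
#' @export
default_demo_calibration <- function() {
  list(
    age = list(td = c(mean = 30.8, sd = 7.5), asd = c(mean = 33.0, sd = 9.4)),
    full_iq = list(td = c(mean = 112.8, sd = 14.1),
                   asd = c(mean = 119.7, sd = 12.2)),
    verbal_iq = list(td = c(mean = 114.5, sd = 13.6),
                     asd = c(mean = 120.6, sd = 14.5)),
    performance_iq = list(td = c(mean = 108.0, sd = 15.0),
                          asd = c(mean = 114.7, sd = 12.2)),
    iq_floor = 85,
    ados_social = c(mean = 2.7, sd = 1.4),
    ados_communication = c(mean = 6.2, sd = 2.3),
    # fixed quantile cuts of the ASD trait distribution for the ordinal
    # RRB score {0, 1, 2}: P = (0.4, 0.4, 0.2) gives mean 0.8
    rrb_quantile_cuts = c(0.4, 0.8)
  )
}
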