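#' Configuration for the full analysis pipeline
#'
#' @param spec A \code{\link{cohort_spec}} used by the simulate stage, or
#'   \code{NULL} when \code{input_dir} points at logs written by
#'   \code{\link{write_cohort}}.
#' @param input_dir Directory of previously written cohort data, or
#'   \code{NULL} to simulate.
#' @param stages Character vector of stages to run, a subset of
#'   \code{c("simulate", "behavior", "randomness", "vbm", "roi",
#'   "mediation", "voxelwise_mediation", "sem", "replication")}. Neuro
#'   stages are skipped automatically when no volumes are available.
#' @param q FDR level for all voxelwise thresholds.
#' @param n_boot Bootstrap resamples for the mediation stages.
#' @param n_steps Steps per random-walk simulation in the randomness stage.
#' @param p_trans_grid,n_hidden_grid Randomness-validation grids.
#' @param replication_tail Tail for the group-difference contrast
#'   (\code{"less"}: clinical group smaller).
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory for artifacts, or \code{NULL} for an
#'   in-memory report only.
#' @return An \code{analysis_config} list.
#' @export
analysis_config <- function(spec = cohort_spec(), input_dir = NULL,
                            stages = c("simulate", "behavior", "randomness",
                                       "vbm", "roi", "mediation",
                                       "voxelwise_mediation", "sem",
                                       "replication"),
                            q = 0.05, n_boot = 5000L, n_steps = 1e5,
                            p_trans_grid = seq(0.5, 0.9, by = 0.1),
                            n_hidden_grid = 1:5,
                            replication_tail = "less",
                            seed = 1L, out_dir = NULL) {
  known <- c("simulate", "behavior", "randomness", "vbm", "roi",
             "mediation", "voxelwise_mediation", "sem", "replication")
  if (length(setdiff(stages, known)))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  if (n_boot < 100) stop("'n_boot' too small for stable percentile CIs")
  structure(list(spec = spec, input_dir = input_dir, stages = stages,
                 q = q, n_boot = as.integer(n_boot), n_steps = n_steps,
                 p_trans_grid = p_trans_grid, n_hidden_grid = n_hidden_grid,
                 replication_tail = replication_tail,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Run the full study analysis end to end
#'
#' Executes, in dependency order: cohort simulation (or loading), behavioral
#' scoring and group comparisons, random-walk randomness validation of the
#' task-switch run lengths, voxelwise morphometry for both behavioral
#' indices with age/IQ covariates and FDR thresholding, conjunction of the
#' two negative maps defining the region of interest, ROI statistics and
#' partial correlations, bootstrap mediation (scalar and optionally
#' voxelwise), the one-factor latent flexibility model, and the
#' replication-style group-difference and RRB-strata tests. Every
#' stochastic stage consumes a seed derived from the master seed, recorded
#' in the report.
#'
#' @param config An \code{\link{analysis_config}}.
#' @return An \code{analysis_report} list; if \code{config$out_dir} is set,
#'   TSV/JSON artifacts are also written there.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  st <- config$stages
  report <- list(config = list(q = config$q, n_boot = config$n_boot,
                               n_steps = config$n_steps,
                               seed = config$seed,
                               stages = st),
                 seeds = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # ---- data ----
  cohort <- NULL
  if (!is.null(config$input_dir)) {
    cohort <- run_stage("load", load_cohort(config$input_dir))
  } else {
    cohort <- run_stage("simulate", generate_cohort(config$spec))
    report$seeds$simulate <- config$spec$seed
  }
  have_vols <- !is.null(cohort$mask)

  # ---- behavior ----
  beh <- grp <- NULL
  if ("behavior" %in% st) {
    beh <- run_stage("behavior", score_cohort(cohort))
    asd <- beh[beh$group == "ASD", ]
    td <- beh[beh$group == "TD", ]
    grp <- list(
      percept_duration = c(two_sample_t(asd$median_percept_duration_s,
                                        td$median_percept_duration_s),
                           d = cohens_d(asd$median_percept_duration_s,
                                        td$median_percept_duration_s)),
      repetition_length = c(two_sample_t(asd$median_repetition_length,
                                         td$median_repetition_length),
                            d = cohens_d(asd$median_repetition_length,
                                         td$median_repetition_length)),
      switch_cost = two_sample_t(asd$switch_cost_ms, td$switch_cost_ms),
      behavior_correlation_asd = correlate(asd$median_percept_duration_s,
                                           asd$median_repetition_length),
      rrb_anova = tryCatch(
        one_way_anova(split(asd$median_repetition_length, asd$ados_rrb)),
        error = function(e) NULL))
    report$behavior_table <- beh
    report$group_comparisons <- grp
  }

  # ---- randomness validation ----
  if ("randomness" %in% st && !is.null(beh)) {
    report$seeds$randomness <- config$seed + 101L
    report$randomness <- run_stage("randomness", {
      out <- list()
      for (g in c("ASD", "TD")) {
        ids <- which(vapply(cohort$subjects, function(s) s$group == g,
                            logical(1)))
        runs <- unlist(lapply(cohort$subjects[ids], function(s) {
          labels <- classify_session(s$spontaneous_trials)
          unlist(lapply(split(labels, s$spontaneous_trials$run_index),
                        repetition_runs))
        }))
        emp <- duration_distribution(runs)
        out[[g]] <- randomness_grid(emp, config$p_trans_grid,
                                    config$n_hidden_grid,
                                    n_steps = config$n_steps,
                                    seed = config$seed + 101L)
      }
      out
    })
  }

  # ---- voxelwise morphometry ----
  roi_mask <- NULL
  if ("vbm" %in% st && have_vols && !is.null(beh)) {
    report$vbm <- run_stage("vbm", {
      asd_idx <- which(vapply(cohort$subjects,
                              function(s) s$group == "ASD", logical(1)))
      vols <- lapply(cohort$subjects[asd_idx], `[[`, "gmv")
      basd <- beh[beh$group == "ASD", ]
      cov <- cbind(age = basd$age, full_iq = basd$full_iq)
      maps <- lapply(list(percept = basd$median_percept_duration_s,
                          repetition = basd$median_repetition_length),
                     function(bv) {
                       m <- voxelwise_regression(vols, bv, cov, cohort$mask)
                       f <- fdr_threshold(m, config$q)
                       s <- signed_maps(m, f)
                       list(map = m, fdr = f, signed = s)
                     })
      conj_neg <- conjunction(maps$percept$signed$negative,
                              maps$repetition$signed$negative)
      conj_pos <- conjunction(maps$percept$signed$positive,
                              maps$repetition$signed$positive)
      cl <- extract_clusters(conj_neg, maps$percept$map$t,
                             cohort$voxel_size_mm)
      peaks <- lapply(maps, function(mm) list(
        negative = extract_clusters(mm$signed$negative, mm$map$t,
                                    cohort$voxel_size_mm),
        positive = extract_clusters(mm$signed$positive, mm$map$t,
                                    cohort$voxel_size_mm)))
      list(maps = maps, conjunction_negative = conj_neg,
           conjunction_positive = conj_pos, clusters = cl,
           peak_tables = peaks)
    })
    roi_mask <- report$vbm$conjunction_negative
    report$roi_n_voxels <- sum(roi_mask)
  }

  # ---- ROI statistics ----
  roi_all <- NULL
  if ("roi" %in% st && !is.null(roi_mask) && sum(roi_mask) > 0) {
    report$roi_stats <- run_stage("roi", {
      roi_all <- vapply(cohort$subjects, function(s)
        roi_mean_gmv(s$gmv, roi_mask), numeric(1))
      groups <- vapply(cohort$subjects, `[[`, character(1), "group")
      asd_sel <- groups == "ASD"
      basd <- beh[beh$group == "ASD", ]
      rel <- vapply(cohort$subjects, function(s)
        relative_gmv(s$gmv, roi_mask, cohort$mask), numeric(1))
      list(
        roi_mean = roi_all,
        group_t = two_sample_t(roi_all[asd_sel], roi_all[!asd_sel]),
        group_d = cohens_d(roi_all[asd_sel], roi_all[!asd_sel]),
        relative_gmv_t = two_sample_t(rel[asd_sel], rel[!asd_sel]),
        corr_percept = correlate(roi_all[asd_sel],
                                 basd$median_percept_duration_s),
        corr_repetition = correlate(roi_all[asd_sel],
                                    basd$median_repetition_length),
        corr_rrb = correlate(roi_all[asd_sel], basd$ados_rrb,
                             y_ordinal = TRUE),
        bonferroni_alpha_behavior = bonferroni_alpha(0.05, 2),
        partial_roi_repetition_given_percept = partial_correlation(
          roi_all[asd_sel], basd$median_repetition_length,
          basd$median_percept_duration_s),
        partial_percept_repetition_given_roi = partial_correlation(
          basd$median_percept_duration_s, basd$median_repetition_length,
          roi_all[asd_sel]))
    })
    roi_all <- report$roi_stats$roi_mean
  }

  # ---- mediation ----
  if ("mediation" %in% st && !is.null(roi_all)) {
    report$seeds$mediation <- config$seed + 202L
    report$mediation <- run_stage("mediation", {
      basd <- beh[beh$group == "ASD", ]
      groups <- vapply(cohort$subjects, `[[`, character(1), "group")
      mediate(scale(basd$median_percept_duration_s)[, 1],
              scale(roi_all[groups == "ASD"])[, 1],
              scale(basd$median_repetition_length)[, 1],
              n_boot = config$n_boot, seed = config$seed + 202L)
    })
  }

  if ("voxelwise_mediation" %in% st && have_vols && !is.null(beh)) {
    report$seeds$voxelwise_mediation <- config$seed + 303L
    report$voxelwise_mediation <- run_stage("voxelwise_mediation", {
      basd <- beh[beh$group == "ASD", ]
      asd_idx <- which(vapply(cohort$subjects,
                              function(s) s$group == "ASD", logical(1)))
      vols <- lapply(cohort$subjects[asd_idx], `[[`, "gmv")
      vm <- voxelwise_mediation(
        scale(basd$median_percept_duration_s)[, 1], vols,
        scale(basd$median_repetition_length)[, 1],
        cohort$mask, q = config$q, n_boot = min(config$n_boot, 2000L),
        seed = config$seed + 303L)
      list(n_survivors = sum(vm$fdr_mask), fdr_mask = vm$fdr_mask,
           indirect = vm$indirect, p = vm$p)
    })
  }

  # ---- latent flexibility model ----
  if ("sem" %in% st && !is.null(roi_all)) {
    report$sem <- run_stage("sem", {
      basd <- beh[beh$group == "ASD", ]
      groups <- vapply(cohort$subjects, `[[`, character(1), "group")
      ind <- cbind(percept = basd$median_percept_duration_s,
                   repetition = basd$median_repetition_length,
                   roi_gmv = -roi_all[groups == "ASD"])
      fit_latent_model(ind, standardize = TRUE)
    })
  }

  # ---- replication-style analyses ----
  if ("replication" %in% st && have_vols) {
    report$replication <- run_stage("replication", {
      groups <- vapply(cohort$subjects, `[[`, character(1), "group")
      vols_td <- lapply(cohort$subjects[groups == "TD"], `[[`, "gmv")
      vols_asd <- lapply(cohort$subjects[groups == "ASD"], `[[`, "gmv")
      gd <- group_difference_map(vols_td, vols_asd, covariates = NULL,
                                 mask = cohort$mask, q = config$q,
                                 tail = config$replication_tail)
      cl <- extract_clusters(gd$fdr_mask, gd$map$t, cohort$voxel_size_mm)
      strata <- NULL
      if (!is.null(roi_all)) {
        basd_rrb <- vapply(cohort$subjects[groups == "ASD"], `[[`,
                           integer(1), "ados_rrb")
        strata <- tryCatch(
          rrb_strata_test(roi_all[groups == "ASD"], basd_rrb),
          error = function(e) list(error = conditionMessage(e)))
      }
      list(n_survivors = sum(gd$fdr_mask), clusters = cl,
           rrb_strata = strata)
    })
  }

  # mark skipped neuro stages explicitly
  neuro <- c("vbm", "roi", "mediation", "voxelwise_mediation", "sem",
             "replication")
  report$skipped <- c(
    setdiff(neuro, st),
    if (!have_vols) intersect(neuro, st))
  report$skipped <- unique(report$skipped)

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  structure(report, class = "analysis_report")
}

#' Write the machine-readable report artifacts
#'
#' @param report An \code{analysis_report}.
#' @param dir Output directory.
#' @return Invisibly, the path of the JSON summary.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$behavior_table))
    write_tsv(report$behavior_table, file.path(dir, "behavior.tsv"))
  if (!is.null(report$vbm$clusters))
    write_tsv(report$vbm$clusters, file.path(dir, "conjunction_clusters.tsv"))
  if (!is.null(report$randomness)) {
    for (g in names(report$randomness)) {
      kl <- report$randomness[[g]]$kl
      df <- data.frame(p_trans = rep(rownames(kl), ncol(kl)),
                       n_hidden = rep(colnames(kl), each = nrow(kl)),
                       kl = as.vector(kl))
      write_tsv(df, file.path(dir, paste0("kl_grid_", g, ".tsv")))
    }
  }
  summ <- summarize_report(report)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Scalar summary of an analysis report
#'
#' Flattens the report into the headline numbers (group tests, behavioral
#' correlation, best-matching transition probability, conjunction ROI size,
#' ROI correlations, mediation paths and p, latent-model fit indices,
#' replication tests), suitable for JSON serialization.
#'
#' @param report An \code{analysis_report}.
#' @return A named list of scalars and small vectors.
#' @export
summarize_report <- function(report) {
  out <- list(config = report$config, seeds = report$seeds,
              skipped = report$skipped)
  gc_ <- report$group_comparisons
  if (!is.null(gc_)) {
    out$percept_t <- gc_$percept_duration$t
    out$percept_p <- gc_$percept_duration$p
    out$percept_d <- gc_$percept_duration$d
    out$repetition_t <- gc_$repetition_length$t
    out$repetition_p <- gc_$repetition_length$p
    out$repetition_d <- gc_$repetition_length$d
    out$behavior_corr_asd <- gc_$behavior_correlation_asd$estimate
    out$behavior_corr_p <- gc_$behavior_correlation_asd$p
    if (!is.null(gc_$rrb_anova)) {
      out$rrb_anova_F <- gc_$rrb_anova$F
      out$rrb_anova_p <- gc_$rrb_anova$p
    }
  }
  if (!is.null(report$randomness)) {
    out$best_p_trans <- lapply(report$randomness, function(r)
      as.numeric(names(which.min(r$mean_kl))))
    out$mean_kl <- lapply(report$randomness, function(r) unname(r$mean_kl))
  }
  if (!is.null(report$roi_n_voxels)) out$roi_n_voxels <- report$roi_n_voxels
  if (!is.null(report$roi_stats)) {
    out$roi_group_t <- report$roi_stats$group_t$t
    out$roi_group_p <- report$roi_stats$group_t$p
    out$roi_corr_percept <- report$roi_stats$corr_percept$estimate
    out$roi_corr_repetition <- report$roi_stats$corr_repetition$estimate
    out$roi_corr_rrb <- report$roi_stats$corr_rrb$estimate
  }
  if (!is.null(report$mediation)) {
    m <- report$mediation
    out$mediation_alpha <- m$alpha
    out$mediation_beta <- m$beta
    out$mediation_gamma <- m$gamma
    out$mediation_indirect <- m$indirect
    out$mediation_p <- m$p_indirect
    out$mediation_ci <- c(m$ci_lower, m$ci_upper)
  }
  if (!is.null(report$voxelwise_mediation))
    out$voxelwise_mediation_survivors <-
      report$voxelwise_mediation$n_survivors
  if (!is.null(report$sem)) {
    s <- report$sem
    out$sem_loadings <- s$loadings
    out$sem_AGFI <- s$AGFI
    out$sem_CFI <- s$CFI
    out$sem_RMSEA <- s$RMSEA
    out$sem_SRMR <- s$SRMR
  }
  if (!is.null(report$replication)) {
    out$replication_survivors <- report$replication$n_survivors
    if (!is.null(report$replication$rrb_strata$t)) {
      out$rrb_strata_t <- report$replication$rrb_strata$t
      out$rrb_strata_p <- report$replication$rrb_strata$p
    }
  }
  out
}
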