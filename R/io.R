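#' Write cohort behavioral logs, cohort table, and volumes to disk
#'
#' Produces the on-disk layout consumed by the scoring and morphometry
#' stages: a percept-events TSV (subject, run, onset_s, label), a trial-log
#' TSV (subject, run, trial, mode, cue, figure attributes, choice, RT), a
#' cohort table TSV, per-subject NIfTI volumes plus a brain-mask volume,
#' and a manifest JSON recording the generator parameters and seed.
#'
#' @param cohort A \code{cohort_dataset}.
#' @param dir Output directory (created if needed).
#' @param volumes Write NIfTI volumes too (default TRUE when present).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir, volumes = !is.null(cohort$mask)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  percept <- do.call(rbind, lapply(cohort$subjects, function(s) {
    tl <- do.call(rbind, s$percept_timelines)
    cbind(subject_id = s$id, tl)
  }))
  write_tsv(percept, file.path(dir, "percept_events.tsv"))
  trials <- do.call(rbind, lapply(cohort$subjects, function(s) {
    rbind(cbind(subject_id = s$id, s$spontaneous_trials),
          cbind(subject_id = s$id, s$instructed_trials))
  }))
  write_tsv(trials, file.path(dir, "trials.tsv"))
  tab <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$id, group = s$group, age = s$age,
               full_iq = s$full_iq, verbal_iq = s$verbal_iq,
               performance_iq = s$performance_iq,
               ados_social = s$ados_social,
               ados_communication = s$ados_communication,
               ados_rrb = s$ados_rrb)))
  write_tsv(tab, file.path(dir, "cohort.tsv"))
  if (volumes) {
    vdir <- file.path(dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (s in cohort$subjects)
      write_gmv(s$gmv, file.path(vdir, paste0(s$id, ".nii.gz")),
                cohort$voxel_size_mm)
    write_gmv(cohort$mask * 1, file.path(vdir, "brain_mask.nii.gz"),
              cohort$voxel_size_mm)
  }
  manifest <- list(spec = cohort$spec[setdiff(names(cohort$spec),
                                              "demo_calibration")],
                   n_subjects = length(cohort$subjects),
                   volumes_written = volumes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read and write gray-matter-volume images
#'
#' \code{write_gmv}/\code{read_gmv} use NIfTI (.nii or .nii.gz) when the
#' path carries that extension; any other extension falls back to a
#' gzipped plain-text value stream with a JSON sidecar carrying
#' dimensions and voxel size.
#'
#' @param volume 3D numeric array.
#' @param path Output path.
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return \code{read_gmv}: list with \code{values} (3D array) and
#'   \code{voxel_size_mm}.
#' @export
write_gmv <- function(volume, path, voxel_size_mm = 1) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume)
    RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
    RNifti::writeNifti(img, path)
  } else {
    con <- gzfile(paste0(path, ".txt.gz"), "w")
    writeLines(format(as.vector(volume), digits = 10), con)
    close(con)
    jsonlite::write_json(list(dim = dim(volume),
                              voxel_size_mm = voxel_size_mm),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_gmv
#' @export
read_gmv <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    list(values = array(as.numeric(img), dim = dim(img)),
         voxel_size_mm = RNifti::pixdim(img)[1])
  } else {
    side <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    con <- gzfile(paste0(path, ".txt.gz"), "r")
    vals <- as.numeric(readLines(con))
    close(con)
    list(values = array(vals, dim = side$dim),
         voxel_size_mm = side$voxel_size_mm)
  }
}

#' Rebuild a cohort object from logs written by \code{\link{write_cohort}}
#'
#' Reconstructs the in-memory structure expected by the analysis stages
#' (per-subject percept timelines, trial logs, demographics, volumes) from
#' the on-disk TSV/NIfTI layout.
#'
#' @param dir Directory written by \code{\link{write_cohort}}.
#' @param volumes Load NIfTI volumes if present.
#' @return A \code{cohort_dataset} (with \code{spec = NULL}).
#' @export
load_cohort <- function(dir, volumes = TRUE) {
  raw <- read_cohort_dir(dir, volumes = volumes)
  tab <- raw$cohort_table
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$subject_id[i]
    pe <- raw$percept_events[raw$percept_events$subject_id == id, ]
    timelines <- lapply(split(pe, pe$run_index), function(d)
      data.frame(run_index = d$run_index, onset_s = d$onset_s,
                 label = d$label))
    tr <- raw$trials[raw$trials$subject_id == id, ]
    s <- list(id = id, group = tab$group[i], age = tab$age[i],
              full_iq = tab$full_iq[i], verbal_iq = tab$verbal_iq[i],
              performance_iq = tab$performance_iq[i],
              ados_social = tab$ados_social[i],
              ados_communication = tab$ados_communication[i],
              ados_rrb = tab$ados_rrb[i],
              percept_timelines = unname(timelines),
              spontaneous_trials = tr[tr$mode == "spontaneous",
                                      names(tr) != "subject_id"],
              instructed_trials = tr[tr$mode == "instructed",
                                     names(tr) != "subject_id"])
    if (!is.null(raw$volumes)) s$gmv <- raw$volumes[[id]]
    s
  })
  structure(list(spec = NULL, subjects = subjects, mask = raw$mask,
                 cluster_mask = NULL,
                 voxel_size_mm = raw$voxel_size_mm),
            class = "cohort_dataset")
}

#' Read behavioral logs written by \code{\link{write_cohort}}
#'
#' @param dir Directory holding \code{percept_events.tsv},
#'   \code{trials.tsv}, \code{cohort.tsv}, and optionally
#'   \code{volumes/}.
#' @param volumes Also load NIfTI volumes if present.
#' @return List with \code{cohort_table}, \code{percept_events},
#'   \code{trials}, and optionally \code{volumes} (named list) and
#'   \code{mask}.
#' @export
read_cohort_dir <- function(dir, volumes = TRUE) {
  out <- list(cohort_table = read_tsv(file.path(dir, "cohort.tsv")),
              percept_events = read_tsv(file.path(dir,
                                                  "percept_events.tsv")),
              trials = read_tsv(file.path(dir, "trials.tsv")))
  vdir <- file.path(dir, "volumes")
  if (volumes && dir.exists(vdir)) {
    ids <- out$cohort_table$subject_id
    vols <- lapply(ids, function(id)
      read_gmv(file.path(vdir, paste0(id, ".nii.gz"))))
    out$volumes <- stats::setNames(lapply(vols, `[[`, "values"), ids)
    out$voxel_size_mm <- vols[[1]]$voxel_size_mm
    msk <- read_gmv(file.path(vdir, "brain_mask.nii.gz"))
    out$mask <- msk$values > 0.5
  }
  out
}
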