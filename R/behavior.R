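#' Clear-percept durations from a bistable-perception timeline
#'
#' A timeline is the ordered stream of button-press events reported while a
#' participant views an ambiguous structure-from-motion stimulus. Each event
#' marks the onset of a new percept (\code{"up"}, \code{"down"}) or of a
#' mixed/unsure interval (\code{"mixed"}). The duration of a clear percept
#' runs from its onset to the next event onset. Mixed intervals are
#' excluded, and so is the final percept, whose duration is truncated by
#' the end of the run.
#'
#' @param timeline A data frame with columns \code{onset_s} (strictly
#'   increasing, within \code{[0, run_length_s)}) and \code{label}.
#' @param run_length_s Run length in seconds (default 90).
#' @return Numeric vector of clear-percept durations in seconds.
#' @export
percept_durations <- function(timeline, run_length_s = 90) {
  n <- nrow(timeline)
  if (is.null(n) || n == 0L) return(numeric(0))
  onset <- timeline$onset_s
  lab <- as.character(timeline$label)
  if (any(diff(onset) <= 0)) stop("event onsets must be strictly increasing")
  if (any(onset < 0) || any(onset >= run_length_s))
    stop("event onsets must lie in [0, run_length_s)")
  if (n == 1L) return(numeric(0))
  dur <- diff(onset)
  keep <- lab[-n] %in% c("up", "down")
  dur[keep]
}

#' Median percept duration for a subject
#'
#' Computes the median clear-percept duration within each run, then averages
#' the per-run medians across runs (per-run statistic first, mean second).
#'
#' @param timelines List of per-run timelines (see
#'   \code{\link{percept_durations}}).
#' @param run_length_s Run length in seconds.
#' @return Mean across runs of per-run median durations (seconds).
#' @export
median_percept_duration <- function(timelines, run_length_s = 90) {
  meds <- vapply(timelines, function(tl) {
    d <- percept_durations(tl, run_length_s)
    if (length(d) == 0L) NA_real_ else stats::median(d)
  }, numeric(1))
  if (all(is.na(meds)))
    stop("no run contains a complete clear percept; subject unusable")
  mean(meds, na.rm = TRUE)
}

#' Classify one task-switching trial from the chosen figure
#'
#' On every trial exactly one of the four figures is the designated target
#' shape (a circle) and exactly one distinct figure is the uniquely
#' brightest. Choosing the circle implies a shape trial; choosing the
#' brightest figure implies a brightness trial; any other choice -- or a
#' timeout -- is unclassifiable.
#'
#' @param trial One row of a trial log: needs \code{choice_index} (1-based,
#'   \code{NA} for timeout), \code{target_index}, \code{brightest_index}.
#' @return One of \code{"shape"}, \code{"brightness"},
#'   \code{"unclassifiable"}.
#' @export
classify_trial <- function(trial) {
  if (trial$target_index == trial$brightest_index)
    stop("invalid stimulus: target shape is also the uniquely brightest figure")
  ch <- trial$choice_index
  if (is.na(ch)) return("unclassifiable")
  if (ch == trial$target_index) return("shape")
  if (ch == trial$brightest_index) return("brightness")
  "unclassifiable"
}

#' Classify every trial of a session
#'
#' @param trials Data frame with columns \code{choice_index},
#'   \code{target_index}, \code{brightest_index}.
#' @return Character vector of labels, one per trial.
#' @export
classify_session <- function(trials) {
  if (any(trials$target_index == trials$brightest_index))
    stop("invalid stimulus: target shape is also the uniquely brightest figure")
  ch <- trials$choice_index
  out <- rep("unclassifiable", nrow(trials))
  out[!is.na(ch) & ch == trials$target_index] <- "shape"
  out[!is.na(ch) & ch == trials$brightest_index] <- "brightness"
  out
}

#' Run-length encode a task-label stream
#'
#' Unclassifiable labels must be removed beforehand. The run lengths sum to
#' the number of classified trials.
#'
#' @param labels Character vector of task labels (\code{"shape"} /
#'   \code{"brightness"}).
#' @return Integer vector of maximal repetition run lengths.
#' @export
repetition_runs <- function(labels) {
  labels <- labels[labels != "unclassifiable"]
  if (length(labels) == 0L) return(integer(0))
  rle(labels)$lengths
}

#' Median task repetition length for a subject
#'
#' Per-run median of repetition run lengths, averaged across runs.
#'
#' @param sessions List of per-run task-label vectors (unclassifiable trials
#'   are dropped internally).
#' @return Mean across runs of per-run median run lengths.
#' @export
median_repetition_length <- function(sessions) {
  meds <- vapply(sessions, function(labels) {
    r <- repetition_runs(labels)
    if (length(r) == 0L)
      stop("a run contains no classified trials; subject unusable")
    stats::median(r)
  }, numeric(1))
  mean(meds)
}

#' Reaction-time metrics for a task-switching session
#'
#' Classifies each trial after the first of every run as a repetition or a
#' switch relative to the preceding classified trial, and returns mean RTs
#' and the switch cost (mean switch RT minus mean repetition RT).
#' Unclassifiable and timeout trials are excluded from the RT pools and do
#' not define a predecessor. For instructed sessions, accuracy is the
#' fraction of non-timeout trials whose choice matches the cued task.
#'
#' @param trials Data frame with columns \code{run_index}, \code{rt_ms},
#'   \code{choice_index}, and for instructed sessions \code{cue}.
#' @param labels Task labels per trial (from \code{\link{classify_session}}).
#' @param instructed Logical; also compute accuracy against \code{cue}.
#' @return List with \code{rt_repeat_ms}, \code{rt_switch_ms},
#'   \code{switch_cost_ms}, \code{n_repeat}, \code{n_switch}, and
#'   \code{accuracy} (instructed only, else \code{NA}).
#' @export
rt_metrics <- function(trials, labels, instructed = FALSE) {
  stopifnot(length(labels) == nrow(trials))
  ok <- labels != "unclassifiable" & !is.na(trials$choice_index)
  rep_rt <- numeric(0)
  sw_rt <- numeric(0)
  for (run in unique(trials$run_index)) {
    in_run <- which(trials$run_index == run & ok)
    if (length(in_run) < 2L) next
    labs <- labels[in_run]
    rts <- trials$rt_ms[in_run]
    same <- labs[-1L] == labs[-length(labs)]
    rep_rt <- c(rep_rt, rts[-1L][same])
    sw_rt <- c(sw_rt, rts[-1L][!same])
  }
  if (length(rep_rt) == 0L)
    stop("no repetition trials; RT metrics undefined")
  cost <- if (length(sw_rt) == 0L) NA_real_ else mean(sw_rt) - mean(rep_rt)
  acc <- NA_real_
  if (instructed) {
    answered <- !is.na(trials$choice_index)
    acc <- mean(labels[answered] == trials$cue[answered])
  }
  list(rt_repeat_ms = mean(rep_rt),
       rt_switch_ms = if (length(sw_rt)) mean(sw_rt) else NA_real_,
       switch_cost_ms = cost,
       n_repeat = length(rep_rt), n_switch = length(sw_rt),
       accuracy = acc)
}

#' Score a whole subject into the behavioral summary indices
#'
#' @param percept_timelines List of per-run percept timelines.
#' @param spont_trials Data frame of spontaneous trials (all runs).
#' @param instr_trials Data frame of instructed trials, or \code{NULL}.
#' @param run_length_s Percept run length in seconds.
#' @return One-row data frame with the subject's behavioral indices.
#' @export
score_subject <- function(percept_timelines, spont_trials,
                          instr_trials = NULL, run_length_s = 90) {
  med_pd <- median_percept_duration(percept_timelines, run_length_s)
  labels <- classify_session(spont_trials)
  runs <- split(labels, spont_trials$run_index)
  med_rl <- median_repetition_length(runs)
  rtm <- rt_metrics(spont_trials, labels, instructed = FALSE)
  out <- data.frame(
    median_percept_duration_s = med_pd,
    median_repetition_length = med_rl,
    rt_repeat_ms = rtm$rt_repeat_ms,
    rt_switch_ms = rtm$rt_switch_ms,
    switch_cost_ms = rtm$switch_cost_ms,
    unclassifiable_fraction = mean(labels == "unclassifiable"),
    accuracy_instructed = NA_real_,
    rt_repeat_instructed_ms = NA_real_,
    rt_switch_instructed_ms = NA_real_,
    switch_cost_instructed_ms = NA_real_
  )
  if (!is.null(instr_trials) && nrow(instr_trials) > 0L) {
    ilabels <- classify_session(instr_trials)
    irt <- rt_metrics(instr_trials, ilabels, instructed = TRUE)
    out$accuracy_instructed <- irt$accuracy
    out$rt_repeat_instructed_ms <- irt$rt_repeat_ms
    out$rt_switch_instructed_ms <- irt$rt_switch_ms
    out$switch_cost_instructed_ms <- irt$switch_cost_ms
  }
  out
}

#' Score every subject of a cohort into a behavior table
#'
#' @param cohort A \code{cohort_dataset} from \code{\link{generate_cohort}}.
#' @return Data frame, one row per subject: demographics, clinical scores,
#'   and the behavioral indices from \code{\link{score_subject}}.
#' @export
score_cohort <- function(cohort) {
  run_len <- if (!is.null(cohort$spec)) cohort$spec$run_length_s else 90
  rows <- lapply(cohort$subjects, function(s) {
    beh <- score_subject(s$percept_timelines, s$spontaneous_trials,
                         s$instructed_trials,
                         run_length_s = run_len)
    cbind(data.frame(subject_id = s$id, group = s$group, age = s$age,
                     full_iq = s$full_iq, verbal_iq = s$verbal_iq,
                     performance_iq = s$performance_iq,
                     ados_social = s$ados_social,
                     ados_communication = s$ados_communication,
                     ados_rrb = s$ados_rrb),
          beh)
  })
  do.call(rbind, rows)
}
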