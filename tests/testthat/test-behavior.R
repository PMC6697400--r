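test_that("percept durations exclude mixed intervals and the truncated final percept", {
  tl <- fixture_timeline()
  expect_equal(percept_durations(tl), c(4, 6, 8.5))
  # a single event has no complete percept
  expect_equal(percept_durations(tl[1, ]), numeric(0))
  expect_equal(percept_durations(tl[0, ]), numeric(0))
})

test_that("percept timelines with non-increasing or out-of-range onsets are rejected", {
  bad <- data.frame(onset_s = c(0, 5, 5), label = c("up", "down", "up"))
  expect_error(percept_durations(bad), "strictly increasing")
  bad2 <- data.frame(onset_s = c(0, 95), label = c("up", "down"))
  expect_error(percept_durations(bad2, run_length_s = 90), "onsets must lie")
})

test_that("median percept duration averages per-run medians, skipping empty runs", {
  tl <- fixture_timeline()
  one_event <- data.frame(run_index = 2L, onset_s = 0, label = "up")
  expect_equal(median_percept_duration(list(tl, tl)), 6)          # median(4,6,8.5)
  expect_equal(median_percept_duration(list(tl, one_event)), 6)   # NA run skipped
  expect_error(median_percept_duration(list(one_event)), "unusable")
})

test_that("trial classification follows the chosen-figure rule exactly", {
  tr <- fixture_trials()
  expected <- c("shape", "shape", "brightness", "unclassifiable",
                "brightness", "brightness", "unclassifiable", "shape")
  expect_identical(classify_session(tr), expected)
  for (i in seq_len(nrow(tr)))
    expect_identical(classify_trial(tr[i, ]), expected[i])
  bad <- tr; bad$brightest_index[1] <- bad$target_index[1]
  expect_error(classify_session(bad), "invalid stimulus")
})

test_that("repetition run lengths come from run-length encoding of classified trials", {
  labels <- c("shape", "shape", "brightness", "unclassifiable",
              "brightness", "brightness", "unclassifiable", "shape")
  # after dropping unclassifiables: s s b b b s -> runs 2, 3, 1
  expect_identical(repetition_runs(labels), c(2L, 3L, 1L))
  expect_equal(sum(repetition_runs(labels)),
               sum(labels != "unclassifiable"))
  expect_identical(repetition_runs(character(0)), integer(0))
})

test_that("median repetition length averages per-run medians of run lengths", {
  s1 <- c("shape", "shape", "brightness")            # runs 2,1 -> median 1.5
  s2 <- rep("brightness", 4)                         # run 4   -> median 4
  expect_equal(median_repetition_length(list(s1, s2)), (1.5 + 4) / 2)
  expect_error(median_repetition_length(list(character(0))), "unusable")
})

test_that("switch cost is mean switch RT minus mean repetition RT over classified pairs", {
  tr <- fixture_trials()
  labels <- classify_session(tr)
  m <- rt_metrics(tr, labels)
  # classified trials (1,2,3,5,6,8): pairs 1-2 rep, 2-3 sw, 3-5 rep(b-b),
  # 5-6 rep, 6-8 sw
  expect_equal(m$rt_repeat_ms, mean(c(580, 660, 720)))
  expect_equal(m$rt_switch_ms, mean(c(700, 610)))
  expect_equal(m$switch_cost_ms, mean(c(700, 610)) - mean(c(580, 660, 720)))
  expect_identical(c(m$n_repeat, m$n_switch), c(3L, 2L))
})

test_that("instructed accuracy counts answered trials matching the cue", {
  tr <- fixture_trials()
  tr$mode <- "instructed"
  tr$cue <- c("shape", "shape", "brightness", "brightness",
              "brightness", "brightness", "shape", "shape")
  labels <- classify_session(tr)
  m <- rt_metrics(tr, labels, instructed = TRUE)
  # answered trials: 1,2,3,4,5,6,8; matching cue: 1,2,3,5,6,8 -> 6/7
  expect_equal(m$accuracy, 6 / 7)
})

test_that("yoked instructed cue stream equals the classified spontaneous stream", {
  spec <- fixture_small_spec()
  spont <- generate_spontaneous_session(0.3, spec, seed = 7)
  instr <- yoke_instructed_session(spont, spec, seed = 8)
  labels <- classify_session(spont)
  expect_identical(as.character(instr$cue),
                   labels[labels != "unclassifiable"])
  expect_true(all(instr$mode == "instructed"))
  # a session with only unclassifiable trials cannot be yoked
  broken <- spont
  broken$choice_index <- NA_integer_
  expect_error(yoke_instructed_session(broken, spec), "no classifiable")
})

test_that("subject and cohort scoring produce aligned, complete behavior tables", {
  spec <- fixture_small_spec(seed = 4)
  cohort <- generate_cohort(spec, generate_volumes = FALSE)
  beh <- score_cohort(cohort)
  expect_equal(nrow(beh), 12)
  expect_identical(sort(unique(beh$group)), c("ASD", "TD"))
  expect_true(all(is.finite(beh$median_percept_duration_s)))
  expect_true(all(is.finite(beh$median_repetition_length)))
  expect_true(all(beh$median_repetition_length >= 1))
  expect_true(all(beh$accuracy_instructed > 0.8))
  # ADOS scores exist only for the clinical group
  expect_true(all(is.na(beh$ados_rrb[beh$group == "TD"])))
  expect_true(all(beh$ados_rrb[beh$group == "ASD"] %in% 0:2))
})
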