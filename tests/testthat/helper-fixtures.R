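# Hand-constructed fixtures shared across test files.

# One 90 s percept run with known clear-percept durations.
# Events: up@0, down@4, mixed@10, up@11.5, down@20 (final, truncated).
# Clear durations: up 4, down 6, up 8.5 (mixed interval excluded, final
# percept dropped).
fixture_timeline <- function() {
  data.frame(run_index = 1L,
             onset_s = c(0, 4, 10, 11.5, 20),
             label = c("up", "down", "mixed", "up", "down"))
}

# A 8-trial task log with known classification: choosing the target
# circle implies a shape trial, choosing the brightest figure a
# brightness trial; trial 4 is a lapse (other figure), trial 7 a timeout.
fixture_trials <- function() {
  data.frame(
    run_index = 1L,
    trial_index = 1:8,
    mode = "spontaneous",
    cue = "none",
    target_index = c(1L, 2L, 1L, 3L, 4L, 2L, 1L, 3L),
    brightest_index = c(2L, 3L, 4L, 1L, 2L, 4L, 3L, 2L),
    choice_index = c(1L, 2L, 4L, 2L, 2L, 4L, NA, 3L),
    rt_ms = c(600, 580, 700, 640, 660, 720, 3000, 610))
}
# expected labels: shape shape brightness unclassifiable brightness
#                  brightness unclassifiable shape

# Tiny voxel grid with two disjoint suprathreshold blobs (sizes 4 and 1)
# for cluster extraction tests.
fixture_blob_mask <- function() {
  m <- array(FALSE, c(6, 6, 6))
  m[2:3, 2:2, 2:3] <- TRUE          # 2 x 1 x 2 = 4 voxels
  m[5, 5, 5] <- TRUE                # isolated voxel
  m
}

# Small behavior-only cohort spec used where volumes are irrelevant.
fixture_small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_per_group = 6L, n_runs = 2L, trial_budget_s = 60,
              seed = seed, ...)
}
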