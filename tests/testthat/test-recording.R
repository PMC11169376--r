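test_that("segmentation follows the floor rule and preserves order", {
  rec <- small_recording(n_trials = 2, trial_s = 4)
  segs <- segment_trials(rec, 1)
  expect_equal(nrow(segs), 2 * 4)
  expect_equal(segs$second_index[segs$trial_id == 1], 0:3)

  # a trailing remainder shorter than one window is dropped
  rec2 <- rec
  rec2$trials[[1]]$signal <- cbind(rec2$trials[[1]]$signal,
                                   rec2$trials[[1]]$signal[, 1:64])
  segs2 <- segment_trials(rec2, 1)
  expect_equal(sum(segs2$trial_id == 1), 4)  # 4.5 s -> 4 windows

  # window_s = 2 halves the count
  expect_equal(nrow(segment_trials(rec, 2)), 2 * 2)

  # count equals sum over trials of floor(samples / (window * fs))
  expect_equal(nrow(segs2),
               sum(vapply(rec2$trials,
                          function(tr) ncol(tr$signal) %/% rec2$fs, numeric(1))))
})

test_that("concatenating a trial's segments reproduces its leading samples", {
  rec <- small_recording(n_trials = 1, trial_s = 3)
  segs <- segment_trials(rec, 1)
  rebuilt <- do.call(cbind, segs$signal)
  expect_identical(rebuilt, rec$trials[[1]]$signal[, seq_len(ncol(rebuilt))])
})

test_that("baseline stripping removes exactly the leading seconds", {
  rec <- small_recording(n_trials = 2, trial_s = 5)
  expect_identical(strip_baseline(rec, 0), rec)
  stripped <- strip_baseline(rec, 3)
  expect_equal(ncol(stripped$trials[[1]]$signal), 2 * rec$fs)
  expect_identical(stripped$trials[[1]]$signal,
                   rec$trials[[1]]$signal[, -(1:(3 * rec$fs))])
  expect_identical(stripped$trials[[1]]$ratings, rec$trials[[1]]$ratings)
  # a 63-s DEAP trial keeps 60 s after the 3-s baseline
  expect_equal(8064 - 3 * 128, 60 * 128)
  expect_error(strip_baseline(rec, 70), "baseline")
})

test_that("recording invariants are enforced", {
  rec <- small_recording(n_trials = 2, trial_s = 2)
  bad <- rec
  bad$trials[[1]]$signal <- bad$trials[[1]]$signal[1:10, ]
  expect_error(validate_recording(bad), "channels")

  bad2 <- rec
  bad2$channel_names[2] <- bad2$channel_names[1]
  expect_error(validate_recording(bad2), "unique")

  # dialect rating ranges
  tr <- eeg_trial(1, matrix(rnorm(2 * 128), 2), c(valence = 9.5, arousal = 5,
                                                  dominance = 5))
  expect_error(eeg_recording("s", 128, c("a", "b"), list(tr), "deap"), "ratings")
  tr2 <- eeg_trial(1, matrix(rnorm(2 * 128), 2), c(valence = 2.5, arousal = 3,
                                                   dominance = 3))
  expect_error(eeg_recording("s", 128, c("a", "b"), list(tr2), "dreamer"),
               "integers")
})

test_that("recordings round-trip through disk via the synthetic dialect", {
  rec <- small_recording(n_trials = 2, trial_s = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  write_recording(rec, path)
  expect_identical(load_recording(path, "synthetic"), rec)
})

test_that("load -> strip -> segment is deterministic", {
  run <- function() {
    rec <- small_recording(n_trials = 2, trial_s = 3, seed = 11)
    segment_trials(strip_baseline(rec, 1), 1)
  }
  expect_identical(run(), run())
})
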