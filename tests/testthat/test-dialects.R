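# tiny DEAP-style pickles and DREAMER-style .mat files are built at test time
# with the system python (the same interpreter the loader itself shells out
# to), so the converter is exercised without any dataset download

write_deap_fixture <- function(path, n_trials = 4, n_channels = 40,
                               n_samples = 640) {
  py <- find_python_or_null()
  script <- sprintf('
import pickle, numpy as np
rng = np.random.default_rng(0)
data = rng.normal(size=(%d, %d, %d))
labels = np.column_stack([np.linspace(1, 9, %d)] * 4)
with open(%s, "wb") as fh:
    pickle.dump({"data": data, "labels": labels}, fh)
', n_trials, n_channels, n_samples, n_trials, shQuote(path))
  res <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  stopifnot(is.null(attr(res, "status")) || attr(res, "status") == 0)
  path
}

write_dreamer_fixture <- function(path, n_subjects = 2, n_trials = 3,
                                  n_channels = 14) {
  py <- find_python_or_null()
  script <- sprintf('
import numpy as np
from scipy.io import savemat
rng = np.random.default_rng(1)
subs = []
for s in range(%d):
    stim = np.empty(%d, dtype=object)
    for i in range(%d):
        stim[i] = rng.normal(size=(256 + 128 * i, %d))  # time x channels
    eeg = {"stimuli": stim, "baseline": np.empty(0, dtype=object)}
    subs.append({"EEG": eeg,
                 "ScoreValence": rng.integers(1, 6, %d).astype(float),
                 "ScoreArousal": rng.integers(1, 6, %d).astype(float),
                 "ScoreDominance": rng.integers(1, 6, %d).astype(float)})
data = np.empty(%d, dtype=object)
for s, sub in enumerate(subs):
    data[s] = sub
savemat(%s, {"DREAMER": {"Data": data}})
', n_subjects, n_trials, n_trials, n_channels, n_trials, n_trials, n_trials,
     n_subjects, shQuote(path))
  res <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  stopifnot(is.null(attr(res, "status")) || attr(res, "status") == 0)
  path
}

test_that("interchange bundles round-trip recordings exactly", {
  rec <- small_recording(n_trials = 3, trial_s = 2)
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_bundle(rec, prefix)
  back <- read_bundle(prefix)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$fs, rec$fs)
  for (i in seq_along(rec$trials)) {
    expect_identical(back$trials[[i]]$signal, rec$trials[[i]]$signal)
    expect_equal(back$trials[[i]]$ratings, rec$trials[[i]]$ratings)
  }
})

test_that("generic dialect reads bundles and honours a ratings sidecar", {
  rec <- small_recording(n_trials = 2, trial_s = 2)
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_bundle(rec, prefix)
  got <- load_recording(prefix, "generic")
  expect_equal(got$subject_id, rec$subject_id)
  write.csv(data.frame(trial_id = 1, valence = 8, arousal = 2, dominance = 6),
            paste0(prefix, "_ratings.csv"), row.names = FALSE)
  got2 <- load_recording(prefix, "generic")
  expect_equal(unname(got2$trials[[1]]$ratings["valence"]), 8)
  expect_equal(got2$trials[[2]]$ratings, rec$trials[[2]]$ratings)
  expect_error(load_recording(file.path(tempdir(), "nope"), "generic"),
               "bundle")
})

test_that("DEAP containers load with 32 EEG channels and 1-9 ratings", {
  path <- write_deap_fixture(file.path(withr::local_tempdir(), "s01.dat"))
  rec <- load_recording(path, "deap")
  expect_equal(rec$fs, 128)
  expect_equal(length(rec$channel_names), 32)  # peripheral rows dropped
  expect_equal(rec$channel_names[1], "Fp1")
  expect_length(rec$trials, 4)
  expect_true(all(vapply(rec$trials, function(tr)
    all(tr$ratings >= 1 & tr$ratings <= 9), logical(1))))
  # the baseline is untouched at load; stripping is explicit
  expect_equal(ncol(rec$trials[[1]]$signal), 640)
})

test_that("containers with too few channels raise a dialect error", {
  path <- write_deap_fixture(file.path(withr::local_tempdir(), "bad.dat"),
                             n_channels = 30)
  expect_error(load_recording(path, "deap"), "dialect")
})

test_that("DREAMER containers load stimulus EEG only, per subject", {
  path <- write_dreamer_fixture(file.path(withr::local_tempdir(), "dreamer.mat"))
  rec <- load_recording(path, "dreamer", subject = 2)
  expect_equal(rec$dialect, "dreamer")
  expect_equal(length(rec$channel_names), 14)
  expect_length(rec$trials, 3)
  # stimuli were stored time x channels with growing lengths
  expect_equal(vapply(rec$trials, function(tr) ncol(tr$signal), numeric(1)),
               c(256, 384, 512))
  expect_true(all(vapply(rec$trials, function(tr)
    all(tr$ratings %in% 1:5), logical(1))))
  expect_error(load_recording(path, "dreamer", subject = 9), "out of range")
})
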