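test_that("generation is a pure function of the spec", {
  sp <- synth_spec(n_trials = 4, trial_s = 2, seed = 21)
  expect_identical(generate_recording(sp), generate_recording(sp))
  sp2 <- sp; sp2$seed <- 22L
  expect_false(identical(generate_recording(sp), generate_recording(sp2)))
})

test_that("trials have the DEAP-shaped geometry the defaults emulate", {
  sp <- synth_spec(n_trials = 3, trial_s = 63, seed = 1)
  rec <- generate_recording(sp)
  expect_equal(length(rec$channel_names), 32)
  expect_equal(rec$fs, 128)
  expect_true(all(vapply(rec$trials, function(tr) ncol(tr$signal),
                         numeric(1)) == 8064))
  # defaults mirror the 40-trial protocol
  expect_equal(synth_spec()$n_trials, 40)
  expect_equal(synth_spec()$trial_s, 60)
})

test_that("the class's target band carries elevated spectral power", {
  sp <- synth_spec(n_trials = 8, trial_s = 4, seed = 31)
  rec <- generate_recording(sp)
  classes <- synth_classes(sp)
  band_power <- function(sig, lo, hi, fs) {
    pw <- Mod(stats::mvfft(t(sig)))^2
    f <- (seq_len(nrow(pw)) - 1) * fs / nrow(pw)
    mean(pw[f >= lo & f <= hi, ])
  }
  alpha_p <- vapply(rec$trials, function(tr)
    band_power(tr$signal, 8, 13, rec$fs), numeric(1))
  # gain 4 in alpha: alpha-class trials carry at least twice the alpha power
  # of theta-class trials on average
  expect_gte(mean(alpha_p[classes == 2]) / mean(alpha_p[classes == 1]), 2)
})

test_that("multi-subject datasets share structure but not signals", {
  sp <- synth_spec(n_trials = 5, trial_s = 2, seed = 12)
  ds <- generate_dataset(sp, n_subjects = 2)
  expect_length(ds$recordings, 2)
  expect_false(identical(ds$recordings[[1]]$trials[[1]]$signal,
                         ds$recordings[[2]]$trials[[1]]$signal))
  # manifest classes are balanced within one trial per class
  counts <- table(ds$manifest$class[ds$manifest$subject_id == "synth01"])
  expect_lte(max(counts) - min(counts), 1)
  expect_equal(nrow(ds$manifest), 10)
  # ratings sit at the designed bin centres
  expect_setequal(unique(ds$manifest$valence), c(1.5, 3.5, 5.5, 8.5)[1:4])
  # generated data satisfy all recording invariants unchanged
  for (r in ds$recordings) expect_silent(validate_recording(r))
})

test_that("class-elevated bands separate in differential entropy", {
  # 200 one-second segments per class
  sp <- synth_spec(n_trials = 40, trial_s = 20, seed = 5)
  rec <- generate_recording(sp)
  feat <- build_feature_tensors(rec, feature_set = "de_only")
  classes <- synth_classes(sp)
  seg_class <- classes[feat$trial_id]
  expect_equal(unname(table(seg_class)), rep(200L, 4), ignore_attr = TRUE)
  # mean of the alpha DE plane over mapped cells, per segment
  alpha_mean <- vapply(feat$tensor, function(t) mean(t[2, , ][t[2, , ] != 0]),
                       numeric(1))
  w <- wilcox.test(alpha_mean[seg_class == 2], alpha_mean[seg_class == 1],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("invalid specs are rejected", {
  expect_error(synth_spec(class_map = tibble::tibble(
    class = 1, band = "alpha", gain = 0.5)), "exceed 1")
  expect_error(synth_spec(fs = 64), "fs/2")
  expect_error(synth_spec(rating_map = tibble::tibble(
    class = 1, valence = 5, arousal = 5, dominance = 5)), "cover")
})
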