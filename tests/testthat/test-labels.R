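test_that("binary threshold splits at >= threshold", {
  expect_equal(as.character(binarize(c(5, 4.999, 1, 9), 5)),
               c("high", "low", "low", "high"))
  expect_equal(as.character(binarize(3, 3)), "high")  # DREAMER threshold
  expect_error(binarize(10, 5, range = c(1, 9)), "outside")
})

test_that("bin8 follows the half-open interval boundaries", {
  expect_equal(bin8(c(1, 2, 2.0001, 3, 5.5, 8.0001, 9)),
               c(1L, 1L, 2L, 2L, 5L, 8L, 8L))
  expect_error(bin8(0.5), "outside")
  expect_error(bin8(9.5), "outside")
})

test_that("composite labels are big-endian bit codes over dimensions", {
  lo <- factor("low", levels = c("low", "high"))
  hi <- factor("high", levels = c("low", "high"))
  expect_equal(composite_label(lo, lo, mode = "va"), 0L)
  expect_equal(composite_label(hi, hi, mode = "va"), 3L)
  expect_equal(composite_label(hi, lo, mode = "va"), 2L)

  combos <- expand.grid(v = 0:1, a = 0:1, d = 0:1)
  vad <- composite_label(combos$v, combos$a, combos$d, mode = "vad")
  expect_setequal(vad, 0:7)
  va <- composite_label(combos$v, combos$a, mode = "va")
  expect_equal(sort(unique(va)), 0:3)

  expect_error(composite_label(hi, hi, mode = "vad"), "dominance")
})

test_that("schemes derive thresholds and class sets from the dialect", {
  sc <- label_scheme("binary", "valence", "deap")
  expect_equal(sc$threshold, 5)
  expect_equal(sc$n_classes, 2)
  expect_equal(label_scheme("binary", "arousal", "dreamer")$threshold, 3)
  expect_equal(label_scheme("multiclass", "valence", "deap")$n_classes, 8)
  expect_equal(label_scheme("multiclass", "valence", "dreamer")$n_classes, 5)
  expect_equal(label_scheme("va")$n_classes, 4)
  expect_equal(label_scheme("vad")$n_classes, 8)
  expect_equal(label_scheme("multiclass", "valence", "deap",
                            classes = c(1, 3, 5, 8))$n_classes, 4)
})

test_that("labelling conserves sample counts and is pure", {
  rec <- small_recording(n_trials = 8, trial_s = 2)
  segs <- segment_trials(rec)
  for (mode in c("binary", "multiclass", "va", "vad")) {
    sc <- label_scheme(mode, "valence", "deap")
    lab <- apply_scheme(segs, sc)
    expect_equal(sum(table(lab$label)), nrow(segs))
    expect_identical(lab$label, apply_scheme(segs, sc)$label)
  }
})

test_that("sample counting relabels without dropping and balances dimensions", {
  rec <- small_recording(n_trials = 8, trial_s = 2)
  segs <- segment_trials(rec)
  tab <- sample_count_table(segs, "deap")
  totals <- tab |>
    dplyr::group_by(dimension, scheme) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  # every (dimension, scheme) pair accounts for every segment
  expect_true(all(totals$n == nrow(segs)))
  # per-dimension totals are equal across valence/arousal/dominance
  expect_equal(length(unique(totals$n)), 1L)
})
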