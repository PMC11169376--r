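test_that("band-pass filter passes in-band and rejects out-of-band sines", {
  fs <- 128
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  mid <- (fs + 1):(3 * fs)  # central window, away from filter edge transients

  s10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(s10, fs, "alpha")
  expect_gte(rms(y10[mid]) / rms(s10[mid]), 0.9)

  s40 <- sin(2 * pi * 40 * t)
  y40 <- bandpass(s40, fs, "alpha")
  expect_lte(rms(y40[mid]) / rms(s40[mid]), 0.1)

  # the magnitude-response oracle agrees: evaluate |H(f)|^2 for the designed
  # filter (zero-phase = squared magnitude)
  filt <- signal::butter(4, c(8, 13) / (fs / 2), "pass")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(filt$b * z^(0:(length(filt$b) - 1))) /
          sum(filt$a * z^(0:(length(filt$a) - 1))))^2
  }
  expect_gte(H(10), 0.9)
  expect_lte(H(40), 0.1)

  expect_error(bandpass(s10, fs, c(13, 8)), "low < high")
  expect_error(bandpass(s10, fs, c(30, 70)), "Nyquist")
})

test_that("the vectorised filter engine matches signal::filter row by row", {
  filt <- signal::butter(4, c(4, 8) / 64, "pass")
  X <- matrix(rnorm(4 * 256), 4, 256)
  mine <- eegemotion:::iir_rows(filt$b, filt$a, X)
  ref <- t(apply(X, 1, function(r) as.numeric(signal::filter(filt, r))))
  expect_lt(max(abs(mine - ref)), 1e-9)
})

test_that("differential entropy matches the Gaussian closed form", {
  withr::with_seed(42, {
    for (sigma in c(0.5, 1, 2)) {
      x <- rnorm(4096, sd = sigma)
      expect_lt(abs(differential_entropy(x) -
                      0.5 * log(2 * pi * exp(1) * sigma^2)), 0.05)
    }
    x <- rnorm(512)
    expect_equal(differential_entropy(2 * x) - differential_entropy(x),
                 log(2), tolerance = 1e-12)
  })
  expect_error(differential_entropy(rep(3, 100)), "zero variance")
  expect_error(differential_entropy(1), "2 samples")
})

test_that("min-max normalisation maps to [0,1] with guarded degenerate case", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  withr::with_seed(1, {
    v <- rnorm(50)
    out <- minmax_normalize(v)
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(out[which.min(v)], 0)
    expect_equal(out[which.max(v)], 1)
  })
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("spatial mapping places channels at their cells, zeros elsewhere", {
  lay <- default_layout("deap")
  vals <- setNames(rnorm(32), lay$channel)
  m <- spatial_map(vals, lay)
  expect_equal(sum(m), sum(vals))
  expect_equal(sum(m != 0), 32)           # 32 mapped cells
  expect_equal(sum(m == 0), 81 - 32)      # 49 structurally zero cells
  expect_equal(m[lay$row[1] + 1, lay$col[1] + 1], vals[[1]])

  lay14 <- default_layout("dreamer")
  expect_equal(nrow(lay14), 14)
  m14 <- spatial_map(setNames(rep(1, 14), lay14$channel), lay14)
  expect_equal(sum(m14 != 0), 14)

  expect_error(spatial_map(c(Xx9 = 1), lay), "Xx9")
})

test_that("logarithmic enhancement is anchored and monotone", {
  Z <- matrix(0, 9, 9)
  expect_equal(enhance(Z), Z)
  expect_equal(enhance(matrix(1, 1, 1))[1, 1], log(256))
  v <- seq(0, 1, by = 0.05)
  expect_true(all(diff(enhance(matrix(v, 1))) > 0))
  expect_equal(enhance(matrix(0.5), mode = "outside")[1, 1], 255 * log1p(0.5))
  expect_error(enhance(matrix(1.5)), "\\[0, 1\\]")
})

test_that("feature tensors have the documented shapes and plane order", {
  rec <- small_recording(n_trials = 4, trial_s = 3)
  for (fs in c("both", "de_only", "enhanced_only")) {
    feat <- build_feature_tensors(rec, feature_set = fs)
    expect_equal(nrow(feat), 4 * 3)
    C <- if (fs == "both") 8 else 4
    expect_equal(dim(feat$tensor[[1]]), c(C, 9, 9))
  }
  feat <- build_feature_tensors(rec)
  expect_equal(attr(feat, "plane_order"),
               c("DE_theta", "DE_alpha", "DE_beta", "DE_gamma",
                 "EN_theta", "EN_alpha", "EN_beta", "EN_gamma"))
  # DE planes bounded in [0,1]; enhanced planes equal log1p(255 * DE)
  x <- feat$tensor[[3]]
  expect_true(all(x[1:4, , ] >= 0 & x[1:4, , ] <= 1))
  expect_equal(x[5:8, , ], log1p(255 * x[1:4, , ]))
})

test_that("normalisation attains 0 and 1 per channel and band", {
  rec <- small_recording(n_trials = 4, trial_s = 3)
  feat <- build_feature_tensors(rec)
  de_raw <- attr(feat, "de_raw")
  stats <- attr(feat, "norm_stats")
  for (b in 1:4) {
    nde <- (t(de_raw[, , b]) - stats$min[, b]) / (stats$max[, b] - stats$min[, b])
    expect_equal(apply(nde, 1, min), rep(0, 32), ignore_attr = TRUE)
    expect_equal(apply(nde, 1, max), rep(1, 32), ignore_attr = TRUE)
  }
})

test_that("feature extraction is deterministic and errors carry provenance", {
  rec <- small_recording(n_trials = 2, trial_s = 2)
  expect_identical(build_feature_tensors(rec), build_feature_tensors(rec))

  flat <- rec
  flat$trials[[2]]$signal[5, ] <- 0  # constant channel -> zero band variance
  err <- tryCatch(build_feature_tensors(flat), error = conditionMessage)
  expect_match(err, "zero variance")
  expect_match(err, "trial 2")
  expect_match(err, flat$channel_names[5])
})

test_that("feature tables round-trip through disk", {
  rec <- small_recording(n_trials = 2, trial_s = 2)
  feat <- build_feature_tensors(rec)
  path <- withr::local_tempfile(fileext = ".rds")
  write_features(feat, path)
  expect_identical(read_features(path), feat)
})
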