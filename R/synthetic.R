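.deap_channels <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1", "P3",
  "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4", "F8", "FC6",
  "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2"
)

.dreamer_channels <- c(
  "AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2", "P8", "T8", "FC6",
  "F4", "F8", "AF4"
)

#' Specify a synthetic band-power EEG dataset
#'
#' Describes a generator for EEG-like recordings with known class structure:
#' every trial belongs to a latent emotion class, and that class elevates
#' the signal power in one frequency band. This gives the whole pipeline
#' (filtering, differential entropy, grid mapping, the classifier) a ground
#' truth to recover without downloading any real dataset.
#'
#' The defaults emulate a DEAP-shaped subject: 32 channels at 128 Hz,
#' 40 trials of 60 s, four balanced classes that elevate theta, alpha, beta
#' and gamma power respectively by a factor of 4, and ratings placed at
#' well-separated points of the 1-9 scale (1.5, 3.5, 5.5, 8.5 on all three
#' dimensions) so that both the binary threshold at 5 and the 8-bin
#' fine-grained labelling separate the classes unambiguously.
#'
#' @param n_channels Number of channels (32 and 14 get DEAP/DREAMER 10-20
#'   channel names; other counts get generic names and need a user layout).
#' @param fs Sampling rate in Hz.
#' @param n_trials Trials per subject (assigned to classes round-robin).
#' @param trial_s Trial duration in seconds.
#' @param class_map Tibble with columns `class`, `band`, `gain`: the band
#'   whose power the class elevates, and the power gain (> 1) relative to
#'   the broadband noise floor.
#' @param rating_map Tibble with columns `class`, `valence`, `arousal`,
#'   `dominance`.
#' @param noise_floor Standard deviation of the broadband Gaussian noise.
#' @param seed Integer seed; the generated data are a pure function of the
#'   spec (including this seed).
#'
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 32, fs = 128, n_trials = 40, trial_s = 60,
                       class_map = NULL, rating_map = NULL,
                       noise_floor = 1, seed = 0) {
  if (is.null(class_map)) {
    class_map <- tibble::tibble(
      class = 1:4,
      band = c("theta", "alpha", "beta", "gamma"),
      gain = 4
    )
  }
  if (is.null(rating_map)) {
    centers <- c(1.5, 3.5, 5.5, 8.5)[seq_len(nrow(class_map))]
    if (anyNA(centers)) centers <- seq(1.5, 8.5, length.out = nrow(class_map))
    rating_map <- tibble::tibble(
      class = class_map$class,
      valence = centers, arousal = centers, dominance = centers
    )
  }
  spec <- structure(
    list(n_channels = as.integer(n_channels), fs = as.integer(fs),
         n_trials = as.integer(n_trials), trial_s = as.integer(trial_s),
         class_map = class_map, rating_map = rating_map,
         noise_floor = noise_floor, seed = as.integer(seed)),
    class = "synth_spec"
  )
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$fs <= 0 || spec$n_channels <= 0 || spec$n_trials <= 0 || spec$trial_s <= 0) {
    abort("n_channels, fs, n_trials and trial_s must be positive")
  }
  if (any(spec$class_map$gain <= 1)) abort("class power gains must exceed 1")
  edges <- vapply(spec$class_map$band, function(b) resolve_band(b)["high"], numeric(1))
  if (any(edges >= spec$fs / 2)) abort("fs/2 must lie above the highest class band edge")
  if (!all(spec$class_map$class %in% spec$rating_map$class)) {
    abort("rating_map must cover every class in class_map")
  }
  invisible(spec)
}

synth_channel_names <- function(n_channels) {
  if (n_channels == 32) return(.deap_channels)
  if (n_channels == 14) return(.dreamer_channels)
  sprintf("ch%02d", seq_len(n_channels))
}

#' Trial class assignment of a synthetic spec
#'
#' Classes are assigned to trials round-robin, so counts are balanced to
#' within one trial per class.
#'
#' @param spec A [synth_spec()].
#' @return Integer vector of class labels, one per trial.
#' @export
synth_classes <- function(spec) {
  k <- nrow(spec$class_map)
  spec$class_map$class[((seq_len(spec$n_trials) - 1L) %% k) + 1L]
}

#' Generate one synthetic EEG recording
#'
#' Each trial's signal is broadband Gaussian noise plus band-limited noise
#' in the trial class's target band, independently per channel. The
#' band-limited component is white noise shaped by the same zero-phase
#' Butterworth bank used for feature extraction, scaled by
#' `sqrt(gain - 1)` so the in-band power is approximately `gain` times the
#' broadband floor's. Ratings come from the spec's `rating_map`. The output
#' is fully determined by the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @param subject_id Subject identifier.
#' @return An [eeg_recording()] with dialect `"synthetic"`.
#' @export
generate_recording <- function(spec, subject_id = "synth01") {
  validate_synth_spec(spec)
  classes <- synth_classes(spec)
  n_t <- spec$fs * spec$trial_s
  filts <- lapply(setNames(unique(spec$class_map$band), unique(spec$class_map$band)),
                  design_bandpass, fs = spec$fs)
  withr::with_seed(spec$seed, {
    trials <- lapply(seq_len(spec$n_trials), function(i) {
      cls <- classes[i]
      row <- spec$class_map[spec$class_map$class == cls, ]
      base <- matrix(rnorm(spec$n_channels * n_t), spec$n_channels, n_t)
      shaped <- zerophase_rows(filts[[row$band]],
                               matrix(rnorm(spec$n_channels * n_t), spec$n_channels, n_t))
      sig <- spec$noise_floor * (base + sqrt(row$gain - 1) * shaped)
      rr <- spec$rating_map[spec$rating_map$class == cls, ]
      eeg_trial(i, sig, c(valence = rr$valence, arousal = rr$arousal,
                          dominance = rr$dominance))
    })
    eeg_recording(subject_id, spec$fs, synth_channel_names(spec$n_channels),
                  trials, dialect = "synthetic")
  })
}

#' Generate a multi-subject synthetic dataset
#'
#' Derives an independent seed per subject from the spec's master seed, so
#' subjects share structure (class layout, ratings) but not signals.
#'
#' @param spec A [synth_spec()].
#' @param n_subjects Number of subjects.
#' @return A list with `recordings` (list of [eeg_recording()]) and
#'   `manifest` (tibble: subject_id, trial_id, class, ratings).
#' @export
generate_dataset <- function(spec, n_subjects = 1) {
  validate_synth_spec(spec)
  classes <- synth_classes(spec)
  recs <- lapply(seq_len(n_subjects), function(s) {
    sub_spec <- spec
    sub_spec$seed <- as.integer((spec$seed + s * 7919L) %% .Machine$integer.max)
    generate_recording(sub_spec, subject_id = sprintf("synth%02d", s))
  })
  manifest <- purrr::map_dfr(recs, function(rec) {
    tibble::tibble(
      subject_id = rec$subject_id,
      trial_id = vapply(rec$trials, `[[`, integer(1), "trial_id"),
      class = classes,
      valence = vapply(rec$trials, function(tr) tr$ratings[["valence"]], numeric(1)),
      arousal = vapply(rec$trials, function(tr) tr$ratings[["arousal"]], numeric(1)),
      dominance = vapply(rec$trials, function(tr) tr$ratings[["dominance"]], numeric(1))
    )
  })
  list(recordings = recs, manifest = manifest)
}
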