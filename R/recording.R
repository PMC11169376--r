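#' Construct an EEG recording
#'
#' An `eeg_recording` holds one subject's trials: a common sampling rate,
#' an ordered channel set, and per-trial signal matrices with affective
#' ratings (valence/arousal/dominance). It is the common container the
#' dataset dialect loaders, the synthetic generator and the feature
#' extractor all speak.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param fs Sampling rate in Hz (positive integer; DEAP and DREAMER
#'   distribute preprocessed signals at 128 Hz).
#' @param channel_names Character vector of unique channel labels, in the
#'   row order of every trial's signal matrix.
#' @param trials List of trials as built by [eeg_trial()].
#' @param dialect One of `"deap"`, `"dreamer"`, `"generic"`, `"synthetic"`.
#'
#' @return An object of class `eeg_recording`.
#' @seealso [eeg_trial()], [segment_trials()], [strip_baseline()]
#' @export
eeg_recording <- function(subject_id, fs, channel_names, trials,
                          dialect = c("generic", "deap", "dreamer", "synthetic")) {
  dialect <- match.arg(dialect)
  rec <- structure(
    list(
      subject_id = as.character(subject_id),
      fs = as.integer(fs),
      channel_names = as.character(channel_names),
      trials = trials,
      dialect = dialect
    ),
    class = "eeg_recording"
  )
  validate_recording(rec)
  rec
}

#' Construct a single trial
#'
#' @param trial_id Integer trial index.
#' @param signal Numeric matrix, channels x time-samples.
#' @param ratings Named numeric vector with entries among
#'   `valence`, `arousal`, `dominance`.
#'
#' @return A list of class `eeg_trial`.
#' @export
eeg_trial <- function(trial_id, signal, ratings) {
  stopifnot(is.matrix(signal), is.numeric(signal))
  ratings <- ratings[intersect(c("valence", "arousal", "dominance"), names(ratings))]
  structure(
    list(trial_id = as.integer(trial_id), signal = signal,
         ratings = setNames(as.numeric(ratings), names(ratings))),
    class = "eeg_trial"
  )
}

rating_range <- function(dialect) {
  switch(dialect,
    deap = c(1, 9),
    dreamer = c(1, 5),
    c(-Inf, Inf)
  )
}

#' Validate an EEG recording's invariants
#'
#' Checks the container invariants: positive sampling rate, unique channel
#' names, per-trial channel dimension, at least one second of signal per
#' trial, and dialect-specific rating ranges (DEAP in \[1, 9\], DREAMER
#' integers in 1..5).
#'
#' @param rec An [eeg_recording()].
#' @return `rec`, invisibly, if valid; otherwise an error.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) abort("not an eeg_recording")
  if (is.na(rec$fs) || rec$fs <= 0) abort("fs must be a positive integer")
  if (anyDuplicated(rec$channel_names)) abort("channel_names must be unique")
  nch <- length(rec$channel_names)
  rng <- rating_range(rec$dialect)
  for (tr in rec$trials) {
    if (nrow(tr$signal) != nch) {
      abort(sprintf("trial %d has %d signal rows but the recording names %d channels",
                    tr$trial_id, nrow(tr$signal), nch))
    }
    if (ncol(tr$signal) < rec$fs) {
      abort(sprintf("trial %d is shorter than one second", tr$trial_id))
    }
    r <- tr$ratings
    if (length(r) && (any(r < rng[1]) || any(r > rng[2]))) {
      abort(sprintf("trial %d has ratings outside [%g, %g] for dialect '%s'",
                    tr$trial_id, rng[1], rng[2], rec$dialect))
    }
    if (rec$dialect == "dreamer" && length(r) && any(r != round(r))) {
      abort(sprintf("trial %d: dreamer ratings must be integers 1..5", tr$trial_id))
    }
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  secs <- vapply(x$trials, function(tr) ncol(tr$signal) / x$fs, numeric(1))
  cat(sprintf("<eeg_recording> subject %s (%s): %d channels, %d trials, %.0f Hz\n",
              x$subject_id, x$dialect, length(x$channel_names), length(x$trials), x$fs))
  if (length(secs)) {
    cat(sprintf("  trial duration: %.1f-%.1f s (total %.0f s)\n",
                min(secs), max(secs), sum(secs)))
  }
  invisible(x)
}

#' Remove leading baseline samples from every trial
#'
#' DEAP trials begin with 3 s of pre-stimulus baseline followed by 60 s of
#' stimulus signal; this drops the first `baseline_s` seconds of each trial
#' and leaves ratings untouched.
#'
#' @param rec An [eeg_recording()].
#' @param baseline_s Non-negative integer number of seconds to drop.
#' @return The recording with shortened trials.
#' @export
strip_baseline <- function(rec, baseline_s) {
  validate_recording(rec)
  stopifnot(length(baseline_s) == 1, baseline_s >= 0, baseline_s == round(baseline_s))
  if (baseline_s == 0) return(rec)
  drop_n <- baseline_s * rec$fs
  rec$trials <- lapply(rec$trials, function(tr) {
    if (ncol(tr$signal) <= drop_n) {
      abort(sprintf("trial %d (%.1f s) is not longer than the %d s baseline",
                    tr$trial_id, ncol(tr$signal) / rec$fs, baseline_s))
    }
    tr$signal <- tr$signal[, (drop_n + 1L):ncol(tr$signal), drop = FALSE]
    tr
  })
  validate_recording(rec)
  rec
}

#' Cut trials into fixed non-overlapping windows
#'
#' Each trial is sliced into consecutive `window_s`-second windows in
#' temporal order; a trailing remainder shorter than one window is dropped.
#' Every segment inherits its trial's ratings.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Positive integer window length in seconds (default 1,
#'   the length at which differential entropy is computed downstream).
#'
#' @return A tibble with one row per segment: `subject_id`, `trial_id`,
#'   `second_index` (0-based offset of the window within its trial),
#'   `valence`/`arousal`/`dominance`, and a `signal` list-column of
#'   channels x (window_s * fs) matrices.
#' @export
segment_trials <- function(rec, window_s = 1L) {
  validate_recording(rec)
  stopifnot(window_s >= 1, window_s == round(window_s))
  step <- as.integer(window_s * rec$fs)
  out <- purrr::map(rec$trials, function(tr) {
    n_win <- ncol(tr$signal) %/% step
    if (n_win == 0) return(NULL)
    sigs <- purrr::map(seq_len(n_win) - 1L, function(w) {
      tr$signal[, (w * step + 1L):((w + 1L) * step), drop = FALSE]
    })
    tibble::tibble(
      subject_id = rec$subject_id,
      trial_id = tr$trial_id,
      second_index = seq_len(n_win) - 1L,
      valence = unname(tr$ratings["valence"]),
      arousal = unname(tr$ratings["arousal"]),
      dominance = unname(tr$ratings["dominance"]),
      signal = sigs
    )
  })
  segs <- dplyr::bind_rows(out)
  attr(segs, "fs") <- rec$fs
  attr(segs, "channel_names") <- rec$channel_names
  attr(segs, "dialect") <- rec$dialect
  segs
}

#' Save / load a recording
#'
#' Recordings are serialised with R's native RDS format. These round-trip
#' exactly and back the `"synthetic"` dialect of [load_recording()].
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the recording.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "eeg_recording")) abort("file does not contain an eeg_recording")
  validate_recording(rec)
  rec
}
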