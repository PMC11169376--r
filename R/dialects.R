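# ---- interchange bundle: <prefix>.json + <prefix>.bin ----------------------
# The bundle is the package's plain on-disk recording format: a JSON header
# (subject, fs, channel names, per-trial sample counts and ratings) next to a
# float64 little-endian signal file with trials concatenated, each trial
# stored channel by channel. The bundled Python converter emits the same
# format from DEAP/DREAMER source containers.

#' Write / read a recording as a plain interchange bundle
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix; `<prefix>.json` and `<prefix>.bin` are written.
#' @return The prefix, invisibly (write) or the recording (read).
#' @export
write_bundle <- function(rec, prefix) {
  validate_recording(rec)
  meta <- list(
    subject_id = rec$subject_id, fs = rec$fs, dialect = rec$dialect,
    channel_names = rec$channel_names,
    trials = lapply(rec$trials, function(tr) {
      list(trial_id = tr$trial_id, n_samples = ncol(tr$signal),
           ratings = as.list(tr$ratings))
    })
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (tr in rec$trials) {
    writeBin(as.vector(t(tr$signal)), con, size = 8, endian = "little")
  }
  invisible(prefix)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = FALSE)
  n_ch <- length(meta$channel_names)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  trials <- lapply(meta$trials, function(tr) {
    n_t <- tr$n_samples
    vals <- readBin(con, "double", n = n_ch * n_t, size = 8, endian = "little")
    if (length(vals) != n_ch * n_t) abort("bundle .bin file is truncated")
    eeg_trial(tr$trial_id, t(matrix(vals, n_t, n_ch)),
              unlist(tr$ratings))
  })
  dialect <- meta$dialect %||% "generic"
  eeg_recording(meta$subject_id, meta$fs,
                unlist(meta$channel_names), trials, dialect = dialect)
}

find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) abort("no python interpreter on PATH (needed to unpack DEAP/DREAMER containers)")
  p
}

convert_with_python <- function(path, dialect, subject) {
  script <- system.file("python", "eeg_convert.py", package = "eegemotion",
                        mustWork = TRUE)
  prefix <- tempfile("eegbundle")
  res <- suppressWarnings(system2(
    find_python(),
    c(shQuote(script), "--input", shQuote(path), "--dialect", dialect,
      "--subject", subject, "--out", shQuote(prefix)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0) {
    abort(paste0("converting ", dialect, " container failed: ",
                 paste(res, collapse = " ")))
  }
  prefix
}

#' Load an EEG recording from disk
#'
#' Dialects:
#' * `"deap"` — a preprocessed DEAP subject pickle (`sXX.dat`: 40 trials x
#'   40 channels x 8064 samples plus 40 x 4 ratings). Only the 32 EEG rows
#'   are kept; trials include the 3-s pre-stimulus baseline untouched
#'   (strip it with [strip_baseline()]); sampling rate 128 Hz.
#' * `"dreamer"` — the DREAMER MATLAB container (all 23 subjects in one
#'   file; choose one with `subject`). Only the stimulus EEG is kept —
#'   DREAMER's separate baseline recordings are discarded at load;
#'   sampling rate 128 Hz; ratings are integers 1..5.
#' * `"generic"` — an interchange bundle written by [write_bundle()] (or
#'   any tool producing the same JSON + float64 layout), `path` being the
#'   prefix without extension. An optional `<prefix>_ratings.csv`
#'   (columns `trial_id`, `valence`, `arousal`, `dominance`) overrides the
#'   bundle's ratings.
#' * `"synthetic"` — an RDS file written by [write_recording()].
#'
#' DEAP and DREAMER containers are Python/MATLAB-native formats; they are
#' unpacked by the bundled converter script through the system `python`
#' (with numpy/scipy), which must be on the PATH for those two dialects.
#'
#' @param path File path (or bundle prefix for `"generic"`).
#' @param dialect One of `"deap"`, `"dreamer"`, `"generic"`, `"synthetic"`.
#' @param subject 1-based subject index within a DREAMER container.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, dialect = c("generic", "deap", "dreamer", "synthetic"),
                           subject = 1) {
  dialect <- match.arg(dialect)
  if (dialect == "synthetic") {
    if (!file.exists(path)) abort(paste0("no such file: ", path))
    return(read_recording(path))
  }
  if (dialect == "generic") {
    if (!file.exists(paste0(path, ".json"))) {
      abort(paste0("no bundle at prefix: ", path))
    }
    rec <- read_bundle(path)
    ratings_csv <- paste0(path, "_ratings.csv")
    if (file.exists(ratings_csv)) {
      rt <- read.csv(ratings_csv)
      rec$trials <- lapply(rec$trials, function(tr) {
        row <- rt[rt$trial_id == tr$trial_id, , drop = FALSE]
        if (nrow(row) == 1) {
          tr$ratings <- c(valence = row$valence, arousal = row$arousal,
                          dominance = row$dominance)
        }
        tr
      })
      validate_recording(rec)
    }
    return(rec)
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  prefix <- convert_with_python(path, dialect, subject)
  rec <- read_bundle(prefix)
  unlink(paste0(prefix, c(".json", ".bin")))
  rec
}
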