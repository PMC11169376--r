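#' Differential entropy of a signal under a Gaussian fit
#'
#' For a band-limited EEG segment modelled as Gaussian, the differential
#' entropy has the closed form `0.5 * log(2 * pi * e * sigma^2)` with
#' `sigma` the sample standard deviation (natural logarithm). This is the
#' per-channel, per-band scalar feature the whole pipeline is built on.
#'
#' @param x Numeric vector with at least 2 samples and nonzero variance.
#' @return The differential entropy (nats).
#' @export
differential_entropy <- function(x) {
  if (length(x) < 2) abort("differential entropy needs at least 2 samples")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("zero variance: degenerate (constant) segment")
  0.5 * log(2 * pi * exp(1) * s^2)
}

#' Min-max normalise a feature sequence
#'
#' Maps a sequence to \[0, 1\] by `(x - min) / (max - min)`. A constant
#' sequence maps to all zeros (guarded division), so degenerate channels
#' never produce NaN planes.
#'
#' @param v Non-empty numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(v) {
  if (length(v) == 0) abort("cannot min-max normalise an empty sequence")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Read a channel-to-grid layout table
#'
#' A layout maps channel names injectively onto cells of a 9 x 9 scalp
#' grid (0-based `row`, `col`; row 0 is frontal) following 10-20 electrode
#' geometry. Layouts are plain CSV configuration data, not code constants;
#' the package ships reconstructed layouts for the DEAP (32-channel) and
#' DREAMER (14-channel) montages.
#'
#' @param path CSV file with columns `channel`, `row`, `col`.
#' @param grid_h,grid_w Grid dimensions (default 9 x 9).
#' @return A tibble of class `channel_layout`.
#' @export
read_layout <- function(path, grid_h = 9, grid_w = 9) {
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("channel", "row", "col") %in% names(tab))) {
    abort("layout file must have columns channel, row, col")
  }
  new_layout(tab, grid_h, grid_w)
}

new_layout <- function(tab, grid_h = 9, grid_w = 9) {
  if (anyDuplicated(tab$channel)) abort("layout maps a channel twice")
  if (anyDuplicated(tab[c("row", "col")])) abort("layout maps two channels to one cell")
  if (any(tab$row < 0 | tab$row >= grid_h | tab$col < 0 | tab$col >= grid_w)) {
    abort(sprintf("layout coordinates must lie in [0, %d) x [0, %d)", grid_h, grid_w))
  }
  structure(tibble::as_tibble(tab), grid_h = grid_h, grid_w = grid_w,
            class = c("channel_layout", class(tibble::tibble())))
}

#' Built-in channel layouts
#'
#' @param montage `"deap"` (32 channels) or `"dreamer"` (14 channels).
#' @return A `channel_layout` tibble.
#' @export
default_layout <- function(montage = c("deap", "dreamer")) {
  montage <- match.arg(montage)
  read_layout(system.file("extdata", paste0("layout_", montage, ".csv"),
                          package = "eegemotion", mustWork = TRUE))
}

# layout matched to a recording's channel set, or an informative error
layout_for <- function(channel_names, layout = NULL) {
  if (is.null(layout)) {
    for (m in c("deap", "dreamer")) {
      cand <- default_layout(m)
      if (all(channel_names %in% cand$channel)) { layout <- cand; break }
    }
    if (is.null(layout)) {
      abort("no built-in layout covers these channels; supply one via read_layout()")
    }
  }
  missing <- setdiff(channel_names, layout$channel)
  if (length(missing)) {
    abort(paste0("layout does not map channel(s): ", paste(missing, collapse = ", ")))
  }
  layout
}

#' Place per-channel values onto the scalp grid
#'
#' Builds the sparse `grid_h x grid_w` matrix with each channel's value at
#' its layout cell and exact zeros everywhere else.
#'
#' @param channel_values Named numeric vector (names are channel labels).
#' @param layout A `channel_layout` from [read_layout()] or [default_layout()].
#' @return A numeric matrix (`grid_h x grid_w`).
#' @export
spatial_map <- function(channel_values, layout) {
  gh <- attr(layout, "grid_h"); gw <- attr(layout, "grid_w")
  missing <- setdiff(names(channel_values), layout$channel)
  if (length(missing)) {
    abort(paste0("channel(s) absent from layout: ", paste(missing, collapse = ", ")))
  }
  m <- matrix(0, gh, gw)
  idx <- match(names(channel_values), layout$channel)
  m[cbind(layout$row[idx] + 1L, layout$col[idx] + 1L)] <- channel_values
  m
}

#' Logarithmic enhancement of a normalised feature matrix
#'
#' The dynamic-range transform `M1 = log(1 + coefficient * M)` applied
#' elementwise to a matrix of min-max-normalised differential entropy
#' (natural logarithm, coefficient 255 by default, so a cell at 1 maps to
#' `log(256)`). Structural zeros stay exactly zero. The alternative
#' reading with the coefficient outside the logarithm,
#' `coefficient * log(1 + M)`, is selectable via `mode = "outside"`.
#'
#' @param M Numeric matrix with entries in \[0, 1\].
#' @param coefficient Positive scale factor (default 255).
#' @param mode `"inside"` (default) or `"outside"`.
#' @return Matrix of the same shape.
#' @export
enhance <- function(M, coefficient = 255, mode = c("inside", "outside")) {
  mode <- match.arg(mode)
  if (any(M < -1e-12 | M > 1 + 1e-12)) abort("enhance() expects entries in [0, 1]")
  if (mode == "inside") log1p(coefficient * M) else coefficient * log1p(M)
}

#' Build the per-segment feature tensors for a recording
#'
#' The full feature pipeline: segment the recording into non-overlapping
#' `window_s`-second windows, band-pass filter each window into the four
#' canonical bands, compute per-channel differential entropy, min-max
#' normalise per (channel, band) across all of this subject's segments,
#' place each band's values onto the 9 x 9 grid, and optionally add the
#' logarithmically enhanced copies. With `feature_set = "both"` each
#' segment yields an 8 x 9 x 9 tensor with plane order
#' (DE theta, alpha, beta, gamma, then the enhanced four); `"de_only"` and
#' `"enhanced_only"` yield the respective 4 x 9 x 9 halves.
#'
#' @param rec An [eeg_recording()].
#' @param layout Optional `channel_layout`; by default a built-in layout
#'   matching the recording's channels is used.
#' @param feature_set `"both"`, `"de_only"`, or `"enhanced_only"`.
#' @param window_s Window length in seconds (default 1).
#' @param enhance_coefficient,enhance_mode Passed to [enhance()].
#'
#' @return A tibble with one row per segment (provenance columns
#'   `subject_id`, `trial_id`, `second_index`, the three ratings) and a
#'   `tensor` list-column of C x 9 x 9 arrays. Attributes carry the band
#'   and plane order, the layout, the normalisation statistics and the raw
#'   (unnormalised) differential entropy values, which
#'   [run_experiment()] uses for its strict leakage-free normalisation
#'   mode.
#' @export
build_feature_tensors <- function(rec, layout = NULL,
                                  feature_set = c("both", "de_only", "enhanced_only"),
                                  window_s = 1L, enhance_coefficient = 255,
                                  enhance_mode = c("inside", "outside")) {
  feature_set <- match.arg(feature_set)
  enhance_mode <- match.arg(enhance_mode)
  validate_recording(rec)
  layout <- layout_for(rec$channel_names, layout)

  segs <- segment_trials(rec, window_s)
  n_seg <- nrow(segs)
  if (n_seg == 0) abort("recording yields no segments at this window length")
  n_ch <- length(rec$channel_names)

  # stack all segments as rows (channel fastest within segment) and filter
  # every (segment, channel) row at once, one band at a time
  big <- do.call(rbind, segs$signal)
  bands <- .band_table()
  de_raw <- array(NA_real_, dim = c(n_seg, n_ch, nrow(bands)),
                  dimnames = list(NULL, rec$channel_names, bands$band))
  for (b in seq_len(nrow(bands))) {
    filt <- design_bandpass(c(bands$low_hz[b], bands$high_hz[b]), rec$fs)
    Fb <- zerophase_rows(filt, big)
    v <- rowSums((Fb - rowMeans(Fb))^2) / (ncol(Fb) - 1)
    if (any(v <= 0)) {
      i <- which(v <= 0)[1]
      seg_i <- ((i - 1) %/% n_ch) + 1
      abort(sprintf(
        "zero variance in band %s, channel %s (subject %s, trial %d, second %d)",
        bands$band[b], rec$channel_names[((i - 1) %% n_ch) + 1],
        segs$subject_id[seg_i], segs$trial_id[seg_i], segs$second_index[seg_i]))
    }
    de_raw[, , b] <- t(matrix(0.5 * log(2 * pi * exp(1) * v), n_ch, n_seg))
  }

  stats <- norm_stats(de_raw)
  tensors <- assemble_tensors(de_raw, stats, layout, feature_set,
                              enhance_coefficient, enhance_mode)

  out <- dplyr::select(segs, -"signal")
  out$tensor <- tensors
  attr(out, "fs") <- rec$fs
  attr(out, "channel_names") <- rec$channel_names
  attr(out, "dialect") <- rec$dialect
  attr(out, "band_order") <- bands$band
  attr(out, "plane_order") <- plane_order(feature_set)
  attr(out, "feature_set") <- feature_set
  attr(out, "layout") <- layout
  attr(out, "de_raw") <- de_raw
  attr(out, "norm_stats") <- stats
  attr(out, "enhance") <- list(coefficient = enhance_coefficient, mode = enhance_mode)
  out
}

plane_order <- function(feature_set) {
  bands <- .band_table()$band
  switch(feature_set,
         both = c(paste0("DE_", bands), paste0("EN_", bands)),
         de_only = paste0("DE_", bands),
         enhanced_only = paste0("EN_", bands))
}

# per (channel, band) min/max over segments
norm_stats <- function(de_raw) {
  list(min = apply(de_raw, c(2, 3), min), max = apply(de_raw, c(2, 3), max))
}

# de_raw: n_seg x n_ch x n_band; returns list of C x 9 x 9 arrays.
# clamp = TRUE applies when `stats` come from a training subset only: segments
# outside the training extrema are clipped to [0, 1], preserving the tensor
# invariant (and the domain of the log enhancement).
assemble_tensors <- function(de_raw, stats, layout, feature_set,
                             enhance_coefficient = 255, enhance_mode = "inside",
                             clamp = FALSE) {
  d <- dim(de_raw)
  n_seg <- d[1]; n_ch <- d[2]; n_band <- d[3]
  gh <- attr(layout, "grid_h"); gw <- attr(layout, "grid_w")
  ch_names <- dimnames(de_raw)[[2]]
  idx <- match(ch_names, layout$channel)
  cell <- layout$row[idx] + 1L + layout$col[idx] * gh  # linear index into gh x gw

  with_de <- feature_set %in% c("both", "de_only")
  with_en <- feature_set %in% c("both", "enhanced_only")
  n_c <- (if (with_de) n_band else 0) + (if (with_en) n_band else 0)

  # planes: (gh*gw) x n_seg per band, assembled into a (C, gh, gw, n_seg) array
  big <- array(0, dim = c(n_c, gh * gw, n_seg))
  for (b in seq_len(n_band)) {
    lo <- stats$min[, b]; hi <- stats$max[, b]
    span <- hi - lo
    span[span == 0] <- 1  # constant channel maps to 0 (guarded division)
    nde <- (t(de_raw[, , b]) - lo) / span        # n_ch x n_seg
    if (clamp) nde <- pmin(pmax(nde, 0), 1)
    plane <- matrix(0, gh * gw, n_seg)
    plane[cell, ] <- nde
    if (with_de) big[b, , ] <- plane
    if (with_en) {
      eb <- if (with_de) n_band + b else b
      big[eb, , ] <- if (enhance_mode == "inside") log1p(enhance_coefficient * plane)
                     else enhance_coefficient * log1p(plane)
    }
  }
  dim(big) <- c(n_c, gh, gw, n_seg)
  lapply(seq_len(n_seg), function(i) big[, , , i, drop = TRUE] |>
           array(dim = c(n_c, gh, gw)))
}

#' Save / load a feature table
#'
#' Feature tables (with all their attributes: layout, normalisation
#' statistics, raw differential entropy) are serialised as RDS.
#'
#' @param features A tibble from [build_feature_tensors()].
#' @param path File path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the feature tibble.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features), "tensor" %in% names(features))
  saveRDS(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  f <- readRDS(path)
  if (!is.data.frame(f) || !"tensor" %in% names(f)) {
    abort("file does not contain a feature table")
  }
  f
}
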