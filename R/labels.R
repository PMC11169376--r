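#' Binary high/low label from a rating
#'
#' `high` iff `rating >= threshold` (thresholds: 5 for 1-9 DEAP-style
#' ratings, 3 for 1-5 DREAMER-style ratings).
#'
#' @param rating Numeric vector of ratings.
#' @param threshold Decision threshold.
#' @param range Optional length-2 numeric; ratings outside it are an error.
#' @return Factor with levels `low`, `high`.
#' @export
binarize <- function(rating, threshold, range = NULL) {
  if (!is.null(range) && any(rating < range[1] | rating > range[2], na.rm = TRUE)) {
    abort(sprintf("rating outside [%g, %g]", range[1], range[2]))
  }
  factor(ifelse(rating >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Fine-grained 8-bin label for 1-9 ratings
#'
#' Bins a floating-point rating in \[1, 9\] into the eight intervals
#' \[1,2\], (2,3\], (3,4\], (4,5\], (5,6\], (6,7\], (7,8\], (8,9\].
#'
#' @param rating Numeric vector in \[1, 9\].
#' @return Integer class in 1..8.
#' @export
bin8 <- function(rating) {
  if (any(rating < 1 | rating > 9, na.rm = TRUE)) abort("rating outside [1, 9]")
  as.integer(pmax(1L, ceiling(rating - 1)))
}

#' Composite label from per-dimension binary labels
#'
#' Combines high/low labels across dimensions into a single class code,
#' read as a big-endian bit string in dimension order (valence, arousal,
#' and for VAD dominance), with high = 1. VA yields classes 0..3
#' ((low, low) is 0, (high, high) is 3); VAD yields 0..7.
#'
#' @param valence,arousal,dominance Binary labels as produced by
#'   [binarize()] (factors with levels low/high, or 0/1 vectors).
#' @param mode `"va"` or `"vad"`.
#' @return Integer class codes.
#' @export
composite_label <- function(valence, arousal, dominance = NULL,
                            mode = c("va", "vad")) {
  mode <- match.arg(mode)
  as_bit <- function(x, what) {
    if (is.null(x)) abort(sprintf("composite '%s' labels require the %s dimension", mode, what))
    if (is.factor(x)) x <- as.integer(x == "high")
    if (any(!x %in% c(0, 1))) abort("binary labels must be low/high or 0/1")
    as.integer(x)
  }
  v <- as_bit(valence, "valence")
  a <- as_bit(arousal, "arousal")
  if (mode == "va") return(2L * v + a)
  d <- as_bit(dominance, "dominance")
  4L * v + 2L * a + d
}

#' Define a label scheme
#'
#' A label scheme turns per-segment ratings into class labels. Modes:
#' `binary` (high/low on one dimension), `multiclass` (8 fine-grained bins
#' for 1-9 ratings, or the 5 integer ratings for 1-5 ratings), and the
#' composite `va` / `vad` schemes that combine the binary labels of two or
#' three dimensions into 4 or 8 classes.
#'
#' @param mode `"binary"`, `"multiclass"`, `"va"`, or `"vad"`.
#' @param dimension For `binary`/`multiclass`: `"valence"`, `"arousal"` or
#'   `"dominance"`.
#' @param dialect `"deap"` (ratings 1-9, binary threshold 5) or
#'   `"dreamer"` (ratings 1-5, threshold 3). Synthetic DEAP-range data use
#'   `"deap"`.
#' @param classes Optional explicit class set. For multiclass schemes on
#'   data known to occupy only some bins (e.g. the 4-class synthetic
#'   generator places ratings in bins 1, 3, 5, 8), pass those bins so the
#'   classifier head and the confusion matrix cover exactly the designed
#'   classes.
#' @return A list of class `label_scheme` with fields `mode`, `dimension`,
#'   `threshold`, `classes`, `n_classes`.
#' @export
label_scheme <- function(mode = c("binary", "multiclass", "va", "vad"),
                         dimension = "valence",
                         dialect = c("deap", "dreamer"),
                         classes = NULL) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  threshold <- if (dialect == "deap") 5 else 3
  if (mode %in% c("binary", "multiclass")) {
    dimension <- match.arg(dimension, c("valence", "arousal", "dominance"))
  }
  if (is.null(classes)) {
    classes <- switch(mode,
      binary = c("low", "high"),
      multiclass = if (dialect == "deap") 1:8 else 1:5,
      va = 0:3,
      vad = 0:7
    )
  }
  structure(
    list(mode = mode,
         dimension = if (mode %in% c("binary", "multiclass")) dimension else NULL,
         dialect = dialect, threshold = threshold,
         classes = classes, n_classes = length(classes)),
    class = "label_scheme"
  )
}

#' Apply a label scheme to a ratings table
#'
#' @param data Tibble with rating columns (`valence`, `arousal`,
#'   `dominance` as required by the scheme), e.g. the output of
#'   [segment_trials()] or [build_feature_tensors()].
#' @param scheme A [label_scheme()].
#' @return `data` with an added `label` factor column whose levels are the
#'   scheme's classes.
#' @export
apply_scheme <- function(data, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  rng <- rating_range(scheme$dialect)
  lab <- switch(scheme$mode,
    binary = as.character(binarize(data[[scheme$dimension]], scheme$threshold, rng)),
    multiclass = {
      r <- data[[scheme$dimension]]
      if (scheme$dialect == "deap") as.character(bin8(r))
      else {
        if (any(r < 1 | r > 5 | r != round(r))) abort("dreamer ratings must be integers 1..5")
        as.character(as.integer(r))
      }
    },
    va = as.character(composite_label(
      binarize(data$valence, scheme$threshold, rng),
      binarize(data$arousal, scheme$threshold, rng), mode = "va")),
    vad = as.character(composite_label(
      binarize(data$valence, scheme$threshold, rng),
      binarize(data$arousal, scheme$threshold, rng),
      binarize(data$dominance, scheme$threshold, rng), mode = "vad"))
  )
  bad <- setdiff(unique(lab), as.character(scheme$classes))
  if (length(bad)) {
    abort(paste0("data contain label(s) outside the scheme's class set: ",
                 paste(bad, collapse = ", ")))
  }
  data$label <- factor(lab, levels = as.character(scheme$classes))
  data
}

#' Per-class sample counts for a ratings table
#'
#' Counts segments per class for the binary and fine-grained schemes on
#' each available dimension — the bookkeeping used to describe a dataset's
#' class balance (and, on the real datasets, to reproduce their published
#' per-category sample counts).
#'
#' @param data Tibble with one row per segment and rating columns.
#' @param dialect `"deap"` or `"dreamer"`.
#' @return A tibble with columns `dimension`, `scheme`, `class`, `n`.
#' @export
sample_count_table <- function(data, dialect = c("deap", "dreamer")) {
  dialect <- match.arg(dialect)
  dims <- intersect(c("valence", "arousal", "dominance"), names(data))
  purrr::map_dfr(dims, function(dm) {
    dplyr::bind_rows(
      purrr::map_dfr(c("multiclass", "binary"), function(md) {
        sc <- label_scheme(md, dimension = dm, dialect = dialect)
        lab <- apply_scheme(data, sc)$label
        tibble::tibble(dimension = dm, scheme = md,
                       class = levels(lab), n = as.integer(table(lab)))
      })
    )
  })
}
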