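fold_indices <- function(features, train_cfg, fold_by) {
  n <- nrow(features)
  if (fold_by == "segment") {
    return(kfold_split(n, train_cfg$folds, train_cfg$seed))
  }
  trials <- sort(unique(features$trial_id))
  tf <- kfold_split(length(trials), train_cfg$folds, train_cfg$seed)
  lapply(tf, function(ix) which(features$trial_id %in% trials[ix]))
}

strict_tensors <- function(features, train_idx) {
  de_raw <- attr(features, "de_raw")
  layout <- attr(features, "layout")
  if (is.null(de_raw) || is.null(layout)) {
    abort("strict normalisation needs the raw DE attributes from build_feature_tensors()")
  }
  enh <- attr(features, "enhance")
  stats <- norm_stats(de_raw[train_idx, , , drop = FALSE])
  assemble_tensors(de_raw, stats, layout, attr(features, "feature_set"),
                   enh$coefficient, enh$mode, clamp = TRUE)
}

#' Run a subject-dependent cross-validated experiment
#'
#' For each subject: split that subject's segments into `folds` folds,
#' train a fresh model on each training split, evaluate on the held-out
#' split, and compute macro-averaged metrics from each fold's confusion
#' matrix. The report aggregates per-subject fold means and their
#' mean +/- standard deviation across subjects.
#'
#' @param features A feature table from [build_feature_tensors()] (one
#'   subject), or a list of such tables (one per subject).
#' @param scheme A [label_scheme()].
#' @param config Optional [model_config()]; by default built from the
#'   tensors and the scheme (`n_classes` must match the scheme).
#' @param train_cfg A [train_config()].
#' @param fold_by `"segment"` (shuffled segment-level folds, the default,
#'   matching the magnitude of reported subject-dependent accuracies) or
#'   `"trial"` (stricter: whole trials held out together).
#' @param strict_normalization If `TRUE`, the per-channel/band min-max
#'   normalisation is recomputed from each fold's training segments only
#'   (no statistics leakage into the test fold) instead of the default
#'   whole-subject statistics.
#' @param verbose Print fold progress.
#' @return An object of class `emotion_metrics`; see [tidy.emotion_metrics()].
#' @export
run_experiment <- function(features, scheme, config = NULL,
                           train_cfg = train_config(),
                           fold_by = c("segment", "trial"),
                           strict_normalization = FALSE, verbose = FALSE) {
  fold_by <- match.arg(fold_by)
  stopifnot(inherits(scheme, "label_scheme"))
  flist <- if (is.data.frame(features)) list(features) else features

  per_fold <- purrr::map_dfr(flist, function(feat) {
    feat <- apply_scheme(feat, scheme)
    dims <- dim(feat$tensor[[1]])
    cf <- config
    if (is.null(cf)) {
      cf <- model_config(C = dims[1], H = dims[2], W = dims[3],
                         n_classes = scheme$n_classes)
    }
    if (cf$n_classes != scheme$n_classes) {
      abort(sprintf("model head has %d classes but the scheme defines %d",
                    cf$n_classes, scheme$n_classes))
    }
    folds <- fold_indices(feat, train_cfg, fold_by)
    subject <- feat$subject_id[1]
    purrr::map_dfr(seq_along(folds), function(f) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(nrow(feat)), test_idx)
      tensors <- if (strict_normalization) strict_tensors(feat, train_idx)
                 else feat$tensor
      cf_f <- cf; cf_f$seed <- cf$seed + f
      tc_f <- train_cfg; tc_f$seed <- train_cfg$seed + f
      fit <- train_model(tensors[train_idx], feat$label[train_idx],
                         config = cf_f, train_cfg = tc_f)
      pred <- predict(fit, tensors[test_idx])
      cm <- confusion_matrix(feat$label[test_idx], pred, scheme$classes)
      mm <- macro_metrics(cm)
      if (verbose) {
        message(sprintf("subject %s fold %d: macro accuracy %.3f",
                        subject, f, mm$macro$accuracy))
      }
      dplyr::bind_cols(
        tibble::tibble(subject_id = subject, fold = f, n_test = length(test_idx)),
        mm$macro, tibble::tibble(confusion = list(cm)))
    })
  })

  metric_cols <- c("accuracy", "precision", "specificity", "recall", "f1")
  per_subject <- per_fold |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop")
  aggregate <- tidyr::pivot_longer(per_subject, dplyr::all_of(metric_cols),
                                   names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
                     .groups = "drop")
  confusion_total <- Reduce(`+`, per_fold$confusion)

  structure(list(scheme = scheme, per_fold = per_fold,
                 per_subject = per_subject, aggregate = aggregate,
                 confusion_total = confusion_total),
            class = "emotion_metrics")
}

#' @export
print.emotion_metrics <- function(x, ...) {
  cat(sprintf("<emotion_metrics> %s scheme, %d classes, %d subject(s), %d fold rows\n",
              x$scheme$mode, x$scheme$n_classes,
              nrow(x$per_subject), nrow(x$per_fold)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-11s %6.2f%%%s\n", agg$metric[i], 100 * agg$mean[i],
                if (is.na(agg$sd[i])) "" else sprintf(" +/- %.2f", 100 * agg$sd[i])))
  }
  invisible(x)
}

#' Tidy an experiment report
#'
#' `tidy()` returns one row per (subject, fold) with the five macro
#' metrics; `glance()` returns a one-row summary (mean +/- sd across
#' subjects of per-subject fold means, the reporting shape used for
#' subject-dependent EEG emotion studies).
#'
#' @param x An `emotion_metrics` object from [run_experiment()].
#' @param ... Unused.
#' @method tidy emotion_metrics
#' @export
tidy.emotion_metrics <- function(x, ...) {
  dplyr::select(x$per_fold, -"confusion")
}

#' @rdname tidy.emotion_metrics
#' @method glance emotion_metrics
#' @export
glance.emotion_metrics <- function(x, ...) {
  agg <- x$aggregate
  out <- tibble::as_tibble(setNames(as.list(agg$mean), paste0(agg$metric, "_mean")))
  out <- dplyr::bind_cols(out, tibble::as_tibble(
    setNames(as.list(agg$sd), paste0(agg$metric, "_sd"))))
  out$n_subjects <- nrow(x$per_subject)
  out$n_classes <- x$scheme$n_classes
  out$mode <- x$scheme$mode
  out
}

#' Write an experiment report to disk
#'
#' Writes a machine-readable JSON report (per-fold and aggregate metrics),
#' a CSV metric summary and the pooled confusion matrix as CSV.
#'
#' @param report An `emotion_metrics` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "emotion_metrics"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(scheme = unclass(report$scheme),
         per_fold = dplyr::select(report$per_fold, -"confusion"),
         per_subject = report$per_subject,
         aggregate = report$aggregate),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(dplyr::select(report$per_fold, -"confusion"),
            file.path(dir, "per_fold.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$confusion_total),
            file.path(dir, "confusion.csv"))
  invisible(dir)
}
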