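#' Plot the pooled confusion matrix of an experiment
#'
#' @param object An `emotion_metrics` object from [run_experiment()].
#' @param normalize Show row-normalised proportions instead of counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emotion_metrics
#' @export
autoplot.emotion_metrics <- function(object, normalize = FALSE, ...) {
  cm <- object$confusion_total
  df <- as.data.frame.table(cm, responseName = "n")
  names(df)[1:2] <- c("truth", "predicted")
  if (normalize) {
    df <- df |>
      dplyr::group_by(.data$truth) |>
      dplyr::mutate(n = .data$n / max(1, sum(.data$n))) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = if (normalize) sprintf("%.2f", .data$n)
                                    else .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = if (normalize) "prop." else "count",
                  title = sprintf("pooled confusion matrix (%s scheme)",
                                  object$scheme$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a training loss curve
#'
#' @param object An `eeg_model` from [train_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eeg_model
#' @export
autoplot.eeg_model <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_history),
                       loss = object$loss_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy",
                  title = "training loss") +
    ggplot2::theme_minimal()
}

#' Plot electrode positions on the 9 x 9 grid
#'
#' @param object A `channel_layout` from [read_layout()] or [default_layout()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot channel_layout
#' @export
autoplot.channel_layout <- function(object, ...) {
  gh <- attr(object, "grid_h")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       label = .data$channel)) +
    ggplot2::geom_tile(fill = "grey92", colour = "white") +
    ggplot2::geom_text(size = 3) +
    ggplot2::scale_y_reverse(breaks = 0:(gh - 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row (0 = frontal)",
                  title = "channel-to-grid layout") +
    ggplot2::theme_minimal()
}

#' Plot the feature planes of one segment
#'
#' Displays each plane of a segment's C x 9 x 9 tensor as a tile map —
#' useful to eyeball the sparse topographic structure and the effect of
#' the logarithmic enhancement.
#'
#' @param features Feature table from [build_feature_tensors()].
#' @param segment Row index of the segment to show.
#' @return A ggplot object.
#' @export
plot_feature_planes <- function(features, segment = 1) {
  x <- features$tensor[[segment]]
  planes <- attr(features, "plane_order") %||% paste0("plane", seq_len(dim(x)[1]))
  df <- purrr::map_dfr(seq_len(dim(x)[1]), function(i) {
    m <- x[i, , ]
    tibble::tibble(plane = planes[i],
                   row = as.vector(row(m)) - 1L,
                   col = as.vector(col(m)) - 1L,
                   value = as.vector(m))
  })
  df$plane <- factor(df$plane, levels = planes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~plane, nrow = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("feature planes, segment %d (%s, trial %d, s %d)",
                                  segment, features$subject_id[segment],
                                  features$trial_id[segment],
                                  features$second_index[segment]),
                  fill = "value") +
    ggplot2::theme_minimal()
}
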