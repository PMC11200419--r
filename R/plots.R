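#' Plot a threshold sweep / cross-validation result
#'
#' Mean Dice as a function of the candidate threshold, one line per fold,
#' with the chosen per-fold threshold marked.
#'
#' @param object a `threshold_cv` from [threshold_cv()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.threshold_cv <- function(object, ...) {
  sw <- object$sweeps
  chosen <- object$folds
  ggplot2::ggplot(sw, ggplot2::aes(x = .data$tau, y = .data$mean_dice,
                                   colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = chosen,
      ggplot2::aes(xintercept = .data$tau, colour = factor(.data$fold)),
      linetype = "dashed", show.legend = FALSE
    ) +
    ggplot2::labs(x = "threshold", y = "mean Dice (training folds)",
                  colour = "fold",
                  title = "Threshold selection by cross-validation") +
    ggplot2::theme_minimal()
}

#' Plot intensity histograms per volume and region
#'
#' The usual preprocessing QC view: one intensity histogram per volume and
#' region, log-scaled density, before/after comparison left to the caller
#' (facet on `region`).
#'
#' @param object a `histogram_report` from [histogram_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.histogram_report <- function(object, ...) {
  df <- object |>
    dplyr::mutate(
      mids = purrr::map(.data$breaks, ~ (head(.x, -1) + tail(.x, -1)) / 2)
    ) |>
    tidyr::unnest(c("mids", "counts"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mids, y = .data$counts + 1,
                                   colour = .data$volume)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ .data$region, scales = "free_x") +
    ggplot2::labs(x = "intensity", y = "count + 1",
                  title = "Intensity distribution per volume and region") +
    ggplot2::theme_minimal()
}

#' Overlay a predicted segmentation on a target slice
#'
#' Agreement overlay in the conventional colours: green where prediction
#' and reference agree (true positive), yellow where only the prediction
#' is positive (false positive), red where only the reference is positive
#' (false negative).
#'
#' @param study a `paired_study`.
#' @param pred binary 3D array of predictions.
#' @param reference binary 3D array (rater mask or truth); defaults to
#'   `study$lesion_truth`.
#' @param slice_index slice to show.
#' @return a ggplot object.
#' @export
plot_overlay <- function(study, pred, reference = study$lesion_truth,
                         slice_index = which.max(apply(reference, 1, sum))) {
  img <- study$target[slice_index, , ]
  p <- pred[slice_index, , ]
  r <- reference[slice_index, , ]
  d <- dim(img)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$intensity <- as.numeric(img[cbind(df$row, df$col)])
  df$class <- dplyr::case_when(
    p[cbind(df$row, df$col)] & r[cbind(df$row, df$col)] ~ "true positive",
    p[cbind(df$row, df$col)] ~ "false positive",
    r[cbind(df$row, df$col)] ~ "false negative",
    TRUE ~ NA_character_
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_tile(
      data = dplyr::filter(df, !is.na(.data$class)),
      ggplot2::aes(colour = .data$class), fill = NA, linewidth = 0.3
    ) +
    ggplot2::scale_colour_manual(values = c(
      "true positive" = "green3", "false positive" = "yellow2",
      "false negative" = "red2"
    )) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, slice %d", study$study_id, slice_index),
                  colour = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
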