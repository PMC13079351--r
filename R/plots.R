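#' Plot a synthetic scene with its ground-truth outlines
#'
#' Renders the image as a grayscale raster with the ground-truth instance
#' outlines overlaid, coloured by cluster-group membership.
#'
#' @param object a `"nuc_scene"` from [synthesize_scene()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nuc_scene
#' @export
autoplot.nuc_scene <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(y = seq_len(nrow(img)) - 0.5,
                           x = seq_len(ncol(img)) - 0.5)
  df$value <- as.vector(t(img))
  outlines <- purrr::imap(object$gt$annotations$segmentation, function(segs, i) {
    purrr::imap(segs, function(s, j) {
      m <- matrix(s, ncol = 2, byrow = TRUE)
      tibble::tibble(x = m[, 1], y = m[, 2], poly = paste(i, j),
                     instance = i)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Synthetic scene: %d nuclei",
                                  nrow(object$gt$annotations)))
  if (nrow(outlines) > 0) {
    gg <- gg + ggplot2::geom_polygon(
      data = outlines,
      ggplot2::aes(group = .data$poly),
      fill = NA, colour = "cyan", linewidth = 0.3)
  }
  gg
}

#' Plot per-tile prediction vs ground-truth distributions
#'
#' Side-by-side boxplots of nuclei count and relative covered area per
#' tile, prediction against ground truth — the visual check accompanying
#' the Mann-Whitney comparison.
#'
#' @param stats a `"nuc_tile_stats"` tibble from [per_tile_stats()].
#' @return a ggplot object.
#' @export
plot_tile_stats <- function(stats) {
  long <- tidyr::pivot_longer(tibble::as_tibble(stats),
                              cols = c("gt_count", "pred_count",
                                       "gt_rel_area", "pred_rel_area"),
                              names_to = c("source", "metric"),
                              names_pattern = "(gt|pred)_(.*)")
  long$metric <- ifelse(long$metric == "count", "nuclei count per tile",
                        "relative area per tile")
  ggplot2::ggplot(long, ggplot2::aes(.data$source, .data$value,
                                     fill = .data$source)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4,
                          colour = "blue", show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a precision-recall curve
#'
#' @param object a `"nuc_ap"` from [ap_at_iou()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nuc_ap
#' @export
autoplot.nuc_ap <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("AP@IoU=%.2f (%s) = %s", object$iou_threshold,
                                  object$match_on,
                                  ifelse(is.na(object$ap), "NA",
                                         sprintf("%.1f", object$ap))))
}
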