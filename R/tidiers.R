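#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-observation table of a
#' result object, `glance()` a one-row summary.
#'
#' @param x a fitted/computed result object from this package.
#' @param ... unused.
#' @return a tibble.
#' @name fibernuclei-tidiers
NULL

#' @rdname fibernuclei-tidiers
#' @method tidy nuc_mwu
#' @export
tidy.nuc_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$u, p.value = x$p_value, method = x$method,
                 n_a = x$n_a, n_b = x$n_b)
}

#' @rdname fibernuclei-tidiers
#' @method glance nuc_tile_stats
#' @export
glance.nuc_tile_stats <- function(x, ...) {
  tibble::tibble(
    n_tiles = nrow(x),
    mean_gt_count = mean(x$gt_count), median_gt_count = stats::median(x$gt_count),
    mean_pred_count = mean(x$pred_count),
    median_pred_count = stats::median(x$pred_count),
    mean_gt_rel_area = mean(x$gt_rel_area),
    median_gt_rel_area = stats::median(x$gt_rel_area),
    mean_pred_rel_area = mean(x$pred_rel_area),
    median_pred_rel_area = stats::median(x$pred_rel_area))
}

#' @rdname fibernuclei-tidiers
#' @method tidy nuc_ap
#' @export
tidy.nuc_ap <- function(x, ...) x$curve

#' @rdname fibernuclei-tidiers
#' @method glance nuc_ap
#' @export
glance.nuc_ap <- function(x, ...) {
  tibble::tibble(ap = x$ap, iou_threshold = x$iou_threshold,
                 match_on = x$match_on, n_pred = x$n_pred, n_gt = x$n_gt)
}

#' @rdname fibernuclei-tidiers
#' @method tidy nuc_analysis
#' @export
tidy.nuc_analysis <- function(x, ...) x$nuclei

#' @rdname fibernuclei-tidiers
#' @method glance nuc_analysis
#' @export
glance.nuc_analysis <- function(x, ...) x$summary

#' @rdname fibernuclei-tidiers
#' @method glance nuc_pipeline_result
#' @export
glance.nuc_pipeline_result <- function(x, ...) x$summary
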