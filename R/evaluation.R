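#' Per-tile count and area comparison against ground truth
#'
#' For every image (tile) id shared by a prediction and a ground-truth
#' dataset: nucleus counts and the relative area covered (union of masks
#' divided by tile area — overlapping instances count once) in each.
#' The companion [glance()][generics::glance] method reports the mean and
#' median of each column.
#'
#' @param pred,gt `"coco_dataset"` objects over the same tile images.
#' @return tibble of class `"nuc_tile_stats"`: `image_id`, `gt_count`,
#'   `pred_count`, `gt_rel_area`, `pred_rel_area`.
#' @export
per_tile_stats <- function(pred, gt) {
  missing <- setdiff(gt$images$id, pred$images$id)
  if (length(missing) > 0) {
    stop("prediction set lacks image id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(gt$images)), function(k) {
    im <- gt$images[k, ]
    ga <- dplyr::filter(gt$annotations, .data$image_id == im$id)
    pa <- dplyr::filter(pred$annotations, .data$image_id == im$id)
    tibble::tibble(
      image_id = im$id,
      gt_count = nrow(ga),
      pred_count = nrow(pa),
      gt_rel_area = rel_union_area(ga, im$width, im$height),
      pred_rel_area = rel_union_area(pa, im$width, im$height))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nuc_tile_stats", class(out))
  out
}

rel_union_area <- function(anns, width, height) {
  if (nrow(anns) == 0) return(0)
  canvas <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(anns))) {
    m <- polygons_to_mask(anns$segmentation[[i]], width, height)
    canvas <- paint_mask(canvas, m)
  }
  sum(canvas) / (width * height)
}

#' Mann-Whitney U test
#'
#' Rank-sum test comparing two independent samples, used to judge whether
#' predicted per-tile nuclei counts (or relative areas) are distributed like
#' the expert ground truth (p < 0.05 deemed significant). Computes the U
#' statistic with average ranks for ties. For small samples (both n <= 10)
#' the two-sided p-value is obtained by exact enumeration of all
#' assignments of the pooled values (valid under ties); otherwise by the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples, each non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default decides by sample size.
#' @return list of class `"nuc_mwu"`: `u` (U of sample `a`), `p_value`
#'   (two-sided), `method`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_a <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (is.null(exact)) exact <- max(n_a, n_b) <= 10
  if (exact) {
    us <- enumerate_u(pooled, n_a)
    p <- min(1, 2 * min(mean(us <= u_a), mean(us >= u_a)))
    method <- "exact enumeration"
  } else {
    mu <- n_a * n_b / 2
    n <- n_a + n_b
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n_a * n_b / 12 * (n + 1 - tie_term))
    z <- (u_a - mu - sign(u_a - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  structure(list(u = u_a, p_value = p, method = method, n_a = n_a, n_b = n_b),
            class = "nuc_mwu")
}

## All U values over every choice of which n_a pooled observations form
## sample a (ranks fixed by the pooled values, so ties are handled exactly).
enumerate_u <- function(pooled, n_a) {
  rk <- rank(pooled)
  combos <- utils::combn(length(pooled), n_a)
  colSums(matrix(rk[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
}

#' @export
print.nuc_mwu <- function(x, ...) {
  cat("Mann-Whitney U: U =", x$u, ", two-sided p =", signif(x$p_value, 4),
      "(", x$method, "; n =", x$n_a, "vs", x$n_b, ")\n")
  invisible(x)
}

#' Relative deviation from a reference count
#'
#' `100 * |predicted - reference| / reference`, reported to one decimal —
#' the metric used to compare automated nuclei counts against the median of
#' independent expert counts (e.g. a count of 82 against an expert median
#' of 93 deviates by 11.8%).
#'
#' @param predicted automated count.
#' @param reference reference count (e.g. expert median), `> 0`.
#' @return percent deviation, one decimal.
#' @export
relative_deviation <- function(predicted, reference) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  round(100 * abs(predicted - reference) / reference, 1)
}

#' Average precision at a fixed IoU threshold
#'
#' The COCO-style single-threshold evaluator: predictions are sorted by
#' descending score and greedily matched to the best not-yet-matched ground
#' truth with IoU >= `iou_threshold` (on boxes or on masks); precision is
#' 101-point interpolated over recall 0, 0.01, ..., 1 and averaged, on a
#' 0-100 scale.
#'
#' @param pred detections tibble with scores (global frame).
#' @param gt detections tibble of ground-truth instances.
#' @param iou_threshold match threshold (default 0.5).
#' @param match_on `"box"` or `"mask"` IoU.
#' @return list of class `"nuc_ap"`: `ap` (0-100; `NA` when there is no
#'   ground truth), `n_pred`, `n_gt`, `iou_threshold`, `match_on`, and the
#'   precision/recall `curve` tibble.
#' @export
ap_at_iou <- function(pred, gt, iou_threshold = 0.5,
                      match_on = c("box", "mask")) {
  match_on <- match.arg(match_on)
  n_gt <- nrow(gt)
  if (n_gt == 0) {
    return(structure(list(ap = NA_real_, n_pred = nrow(pred), n_gt = 0L,
                          iou_threshold = iou_threshold, match_on = match_on,
                          curve = tibble::tibble(recall = numeric(),
                                                 precision = numeric())),
                     class = "nuc_ap"))
  }
  ord <- order(-pred$score, pred$id)
  p <- pred[ord, ]
  matched_gt <- logical(n_gt)
  tp <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    ious <- vapply(seq_len(n_gt), function(j) {
      if (matched_gt[j]) return(-1)
      if (match_on == "box") {
        iou_boxes(c(x0 = p$x0[i], y0 = p$y0[i], x1 = p$x1[i], y1 = p$y1[i]),
                  c(x0 = gt$x0[j], y0 = gt$y0[j], x1 = gt$x1[j], y1 = gt$y1[j]))
      } else {
        iou_masks(det_mask(p, i), det_mask(gt, j))
      }
    }, numeric(1))
    best <- which.max(ious)
    if (length(best) == 1 && ious[best] >= iou_threshold) {
      matched_gt[best] <- TRUE
      tp[i] <- 1L
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  rec_levels <- seq(0, 1, by = 0.01)
  interp <- vapply(rec_levels, function(r) {
    sel <- recall >= r
    if (!any(sel)) 0 else max(precision[sel])
  }, numeric(1))
  structure(list(ap = 100 * mean(interp), n_pred = nrow(pred), n_gt = n_gt,
                 iou_threshold = iou_threshold, match_on = match_on,
                 curve = tibble::tibble(recall = recall, precision = precision)),
            class = "nuc_ap")
}

#' @export
print.nuc_ap <- function(x, ...) {
  cat("AP@IoU=", x$iou_threshold, " (", x$match_on, "): ",
      ifelse(is.na(x$ap), "undefined (no ground truth)",
             sprintf("%.1f", x$ap)),
      "  [", x$n_pred, " predictions, ", x$n_gt, " ground truth]\n", sep = "")
  invisible(x)
}
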