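#' Fusion configuration
#'
#' The three thresholds that turn raw per-tile detections into one global
#' instance set: the confidence cut-off (detections scoring below it are
#' discarded; 0.98 is the operating point of the trained network the
#' pipeline was built around), the per-tile NMS IoU threshold, and the
#' cross-tile non-maximum-merging IoS threshold (0.5: merge two masks when
#' their intersection covers at least half of the smaller one).
#'
#' @param score_threshold keep detections with `score >= score_threshold`
#'   (default 0.98).
#' @param nms_iou_threshold suppress a detection whose box IoU with an
#'   already-kept one exceeds this (default 0.5).
#' @param nmm_ios_threshold merge masks whose IoS reaches this (default 0.5).
#' @param nmm_single_pass if `TRUE`, each survivor collects overlapping
#'   candidates once instead of re-testing until stable (no chain merging).
#' @return a list of class `"fusion_config"`.
#' @export
fusion_config <- function(score_threshold = 0.98, nms_iou_threshold = 0.5,
                          nmm_ios_threshold = 0.5, nmm_single_pass = FALSE) {
  stopifnot(score_threshold > 0, score_threshold <= 1,
            nms_iou_threshold > 0, nms_iou_threshold <= 1,
            nmm_ios_threshold > 0, nmm_ios_threshold <= 1)
  structure(list(score_threshold = score_threshold,
                 nms_iou_threshold = nms_iou_threshold,
                 nmm_ios_threshold = nmm_ios_threshold,
                 nmm_single_pass = nmm_single_pass),
            class = "fusion_config")
}

#' Filter detections by confidence score
#'
#' Keeps detections with `score >= threshold` ("below" the threshold is
#' discarded, so a score exactly at the threshold survives); input order is
#' preserved.
#'
#' @param dets detections tibble.
#' @param threshold confidence cut-off in `(0, 1]`.
#' @return the filtered detections tibble.
#' @export
filter_by_score <- function(dets, threshold = 0.98) {
  dplyr::filter(dets, .data$score >= threshold)
}

#' Non-maximum suppression on bounding boxes
#'
#' Greedy, class-agnostic NMS: walk detections by descending score (ties by
#' lower id); suppress a detection whose box IoU with any already-kept
#' detection exceeds `iou_threshold`. Favours fewer but more reliable
#' detections within one tile.
#'
#' @param dets detections tibble in a single frame.
#' @param iou_threshold suppression threshold (default 0.5).
#' @return the surviving detections, in descending-score order.
#' @export
nms <- function(dets, iou_threshold = 0.5) {
  if (nrow(dets) <= 1) return(dets)
  ord <- order(-dets$score, dets$id)
  d <- dets[ord, ]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (iou_boxes(c(x0 = d$x0[i], y0 = d$y0[i], x1 = d$x1[i], y1 = d$y1[i]),
                    c(x0 = d$x0[j], y0 = d$y0[j], x1 = d$x1[j], y1 = d$y1[j])) >
          iou_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  d[keep, ]
}

#' Non-maximum merging of overlapping masks
#'
#' Fuses duplicate detections of the same nucleus seen from adjacent tiles.
#' Detections are visited by descending score (ties by lower id). The
#' current survivor absorbs every remaining detection whose mask IoS with
#' it reaches `ios_threshold`: the merged mask is the union, the score the
#' maximum, the box the tight box of the union. The grown survivor is
#' re-tested against the remaining candidates until stable, so chains of
#' pairwise-overlapping fragments collapse into one instance (set
#' `single_pass = TRUE` to disable the re-test). Output ids are re-indexed
#' 1..n in output order.
#'
#' The operation is idempotent, never increases the instance count, and
#' conserves the union-of-masks area.
#'
#' @param dets global-frame detections tibble.
#' @param ios_threshold merge threshold on mask IoS (default 0.5).
#' @param single_pass disable chain re-testing.
#' @return merged detections tibble.
#' @export
nmm_merge <- function(dets, ios_threshold = 0.5, single_pass = FALSE) {
  if (nrow(dets) <= 1) {
    if (nrow(dets) == 1) dets$id <- 1L
    return(dets)
  }
  ord <- order(-dets$score, dets$id)
  pool <- lapply(ord, function(i) list(
    mask = det_mask(dets, i), score = dets$score[i]))
  out <- list()
  while (length(pool) > 0) {
    cur <- pool[[1]]
    pool <- pool[-1]
    repeat {
      if (length(pool) == 0) break
      hits <- vapply(pool, function(p) {
        n <- mask_overlap_counts(cur$mask, p$mask)
        n[["inter"]] / min(n[["a"]], n[["b"]]) >= ios_threshold
      }, logical(1))
      if (!any(hits)) break
      for (p in pool[hits]) cur$mask <- union_masks(cur$mask, p$mask)
      pool <- pool[!hits]
      if (single_pass) break
    }
    out[[length(out) + 1L]] <- cur
  }
  detections(purrr::imap(out, function(o, i) {
    detection_row(o$mask, score = o$score, id = i, frame = "global")
  }))
}

## Union of two instance masks into one (tight) instance mask.
union_masks <- function(a, b) {
  x0 <- min(a$x0, b$x0); y0 <- min(a$y0, b$y0)
  x1 <- max(a$x0 + ncol(a$px), b$x0 + ncol(b$px))
  y1 <- max(a$y0 + nrow(a$px), b$y0 + nrow(b$px))
  px <- matrix(FALSE, y1 - y0, x1 - x0)
  px[(a$y0 - y0 + 1):(a$y0 - y0 + nrow(a$px)),
     (a$x0 - x0 + 1):(a$x0 - x0 + ncol(a$px))] <- a$px
  sub <- px[(b$y0 - y0 + 1):(b$y0 - y0 + nrow(b$px)),
            (b$x0 - x0 + 1):(b$x0 - x0 + ncol(b$px)), drop = FALSE]
  px[(b$y0 - y0 + 1):(b$y0 - y0 + nrow(b$px)),
     (b$x0 - x0 + 1):(b$x0 - x0 + ncol(b$px))] <- sub | b$px
  list(px = px, x0 = as.integer(x0), y0 = as.integer(y0))
}

#' Reconstruct global predictions from per-tile detections
#'
#' The full fusion chain: per tile, filter by score and apply NMS; shift
#' the survivors to the global frame; then merge duplicates across tiles
#' with [nmm_merge()]. The result is independent of tile processing order.
#'
#' @param tile_dets list of detections tibbles (tile frame), one per tile,
#'   aligned with the rows of `grid`.
#' @param grid the [tile_grid()] the tiles came from.
#' @param cfg a [fusion_config()].
#' @return global-frame detections tibble, plus a `stage_counts` attribute
#'   recording instance counts after each stage (detected, score filter,
#'   NMS, NMM).
#' @export
reconstruct_predictions <- function(tile_dets, grid, cfg = fusion_config()) {
  stopifnot(length(tile_dets) == nrow(grid))
  n_raw <- sum(vapply(tile_dets, nrow, integer(1)))
  filtered <- lapply(tile_dets, filter_by_score, threshold = cfg$score_threshold)
  n_filt <- sum(vapply(filtered, nrow, integer(1)))
  kept <- lapply(filtered, nms, iou_threshold = cfg$nms_iou_threshold)
  n_nms <- sum(vapply(kept, nrow, integer(1)))
  global <- purrr::map2(kept, seq_len(nrow(grid)),
                        function(d, t) to_global(d, grid[t, ]))
  merged <- nmm_merge(detections(global), cfg$nmm_ios_threshold,
                      cfg$nmm_single_pass)
  structure(merged, stage_counts = c(detected = n_raw, score_filter = n_filt,
                                     nms = n_nms, nmm = nrow(merged)))
}
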