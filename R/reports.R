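#' Export the three analysis report tables
#'
#' Writes `image_summary.csv`, `clusters.csv` and `nuclei.csv` into
#' `out_dir` with deterministic row order (by id), so re-exporting the same
#' analysis is bytewise identical. Empty analyses produce header-only
#' files.
#'
#' @param analysis a `"nuc_analysis"` from [analyze_detections()] (or a
#'   list with tibbles `summary`, `clusters`, `nuclei`).
#' @param out_dir output directory, created if needed.
#' @return the three file paths, invisibly.
#' @export
export_reports <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("image_summary.csv", "clusters.csv", "nuclei.csv"))
  readr::write_csv(dplyr::arrange(analysis$summary, .data$image_id), paths[1])
  readr::write_csv(dplyr::arrange(analysis$clusters, .data$cluster_id), paths[2])
  readr::write_csv(dplyr::arrange(analysis$nuclei, .data$id), paths[3])
  invisible(paths)
}

#' Export per-nucleus JPEG crops plus a COCO index
#'
#' Crops each detection (tight box plus `margin`, clipped to the image) to
#' a JPEG named `nucleus_<id>.jpg` and writes a COCO JSON indexing all
#' crops, with each mask re-expressed in its crop's frame.
#'
#' @param dets global-frame detections tibble.
#' @param image integer matrix `[y, x]`, 8-bit values.
#' @param out_dir output directory.
#' @param margin extra context around the tight box, px (default 10).
#' @return the COCO index path, invisibly.
#' @export
export_instance_crops <- function(dets, image, out_dir, margin = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- list(); anns <- list()
  for (i in seq_len(nrow(dets))) {
    x0 <- max(0L, dets$x0[i] - margin); y0 <- max(0L, dets$y0[i] - margin)
    x1 <- min(ncol(image), dets$x1[i] + margin)
    y1 <- min(nrow(image), dets$y1[i] + margin)
    crop <- image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
    fn <- sprintf("nucleus_%d.jpg", dets$id[i])
    jpeg::writeJPEG(pmax(pmin(crop / 255, 1), 0), file.path(out_dir, fn),
                    quality = 0.95)
    imgs[[i]] <- tibble::tibble(id = dets$id[i], file_name = fn,
                                width = x1 - x0, height = y1 - y0)
    m <- det_mask(dets, i)
    m$x0 <- m$x0 - x0; m$y0 <- m$y0 - y0 # crop frame
    anns[[i]] <- mask_to_annotation(m, id = dets$id[i], image_id = dets$id[i],
                                    score = dets$score[i])
  }
  ds <- coco_dataset(images = dplyr::bind_rows(imgs),
                     annotations = dplyr::bind_rows(anns))
  idx <- file.path(out_dir, "crops_coco.json")
  write_coco(ds, idx)
  invisible(idx)
}
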