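#' Pipeline configuration
#'
#' Collects every numeric constant of the processing chain in one audited,
#' serializable place: tiling (400 px tiles, 20% overlap), fusion (score
#' 0.98 for network backends, NMS IoU 0.5, NMM IoS 0.5), clustering
#' (overlap > 2%, adaptive-distance parameters, vicinity radius) and I/O
#' (channel policy, backend name, output directory, seed).
#'
#' @param tile_size,overlap_fraction see [tile_grid()].
#' @param min_visible_fraction see [slice_annotations()].
#' @param score_threshold,nms_iou_threshold,nmm_ios_threshold see
#'   [fusion_config()]; `score_threshold = NULL` uses the backend's
#'   calibrated default.
#' @param overlap_threshold,alpha,beta,vicinity_radius see
#'   [build_cluster_graph()] and [local_density()].
#' @param channel_policy see [load_image()].
#' @param backend detector backend name (default `"toy-threshold"`).
#' @param out_dir output directory.
#' @param seed integer seed recorded with the run.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(tile_size = 400, overlap_fraction = 0.2,
                            min_visible_fraction = 0.1,
                            score_threshold = NULL,
                            nms_iou_threshold = 0.5, nmm_ios_threshold = 0.5,
                            overlap_threshold = 0.02, alpha = 1.2,
                            beta = 0.05, vicinity_radius = 100,
                            channel_policy = "blue",
                            backend = "toy-threshold",
                            out_dir = "nuclei_out", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(tile_size > 0, overlap_fraction >= 0, overlap_fraction < 1,
            min_visible_fraction >= 0, min_visible_fraction <= 1,
            is.null(score_threshold) ||
              (score_threshold > 0 && score_threshold <= 1),
            nms_iou_threshold > 0, nms_iou_threshold <= 1,
            nmm_ios_threshold > 0, nmm_ios_threshold <= 1,
            overlap_threshold >= 0, overlap_threshold < 1,
            alpha > 0, beta >= 0, vicinity_radius > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' YAML (or JSON) round trip of a [pipeline_config()]: `load -> save ->
#' load` is the identity.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return `read_pipeline_config()` returns a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config key(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg a `"pipeline_config"`.
#' @export
write_pipeline_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(vals, path)
  invisible(cfg)
}

#' Run the full analysis pipeline on one or more images
#'
#' For each image: load (selecting the blue channel for RGB input, and
#' converting 16-bit data to 8 bits), slice into overlapping tiles, run the
#' configured detector backend per tile, fuse (score filter, per-tile NMS,
#' shift to global frame, cross-tile NMM), then cluster and measure every
#' nucleus. Per image the function writes the three report CSVs, a COCO
#' JSON of the fused predictions, and appends one log row per stage
#' (detected, after score filter, after NMS, after NMM) — the counts are
#' monotonically non-increasing along the chain.
#'
#' @param paths image file path(s), or a list of in-memory image matrices
#'   (named, `[y, x]`).
#' @param cfg a [pipeline_config()].
#' @return list of class `"nuc_pipeline_result"`: `summary`, `clusters`,
#'   `nuclei` (tibbles pooled over images, with `image` column), `log`
#'   (stage counts per image), `predictions` (list of detections tibbles).
#' @export
run_pipeline <- function(paths, cfg = pipeline_config()) {
  backend <- get_backend(cfg$backend)
  score_thr <- cfg$score_threshold %||% backend$default_score_threshold
  fcfg <- fusion_config(score_thr, cfg$nms_iou_threshold, cfg$nmm_ios_threshold)
  from_files <- !is.list(paths)
  if (from_files && !all(file.exists(paths))) {
    stop("unreadable image(s): ",
         paste(paths[!file.exists(paths)], collapse = ", "), call. = FALSE)
  }
  names_in <- if (from_files) basename(paths) else
    (names(paths) %||% paste0("image", seq_along(paths)))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  summaries <- list(); clusters <- list(); nuclei <- list()
  logs <- list(); preds <- list()
  for (k in seq_along(paths)) {
    img <- if (from_files) load_image(paths[[k]], cfg$channel_policy) else paths[[k]]
    if (!is.null(attr(img, "bit_depth")) && attr(img, "bit_depth") == 16L) {
      img <- convert_16_to_8(img)
    }
    grid <- tile_grid(ncol(img), nrow(img), cfg$tile_size, cfg$overlap_fraction)
    tiles <- slice_image(img, grid)
    tile_dets <- lapply(tiles$pixels, backend$detect)
    fused <- reconstruct_predictions(tile_dets, grid, fcfg)
    stage_counts <- attr(fused, "stage_counts")
    ana <- analyze_detections(fused, img, cfg$overlap_threshold, cfg$alpha,
                              cfg$beta, cfg$vicinity_radius, image_id = k)
    stem <- sub("\\.[A-Za-z]+$", "", names_in[k])
    img_dir <- file.path(cfg$out_dir, stem)
    export_reports(ana, img_dir)
    write_coco(detections_to_coco(fused, names_in[k], ncol(img), nrow(img)),
               file.path(img_dir, "predictions_coco.json"))
    summaries[[k]] <- dplyr::mutate(ana$summary, image = names_in[k])
    clusters[[k]] <- dplyr::mutate(ana$clusters, image = names_in[k])
    nuclei[[k]] <- dplyr::mutate(ana$nuclei, image = names_in[k])
    logs[[k]] <- tibble::tibble(image = names_in[k],
                                stage = names(stage_counts),
                                count = as.integer(unname(stage_counts)))
    preds[[k]] <- fused
    message(sprintf("[%s] detected %d -> score filter %d -> NMS %d -> NMM %d",
                    names_in[k], stage_counts[1], stage_counts[2],
                    stage_counts[3], stage_counts[4]))
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 clusters = dplyr::bind_rows(clusters),
                 nuclei = dplyr::bind_rows(nuclei),
                 log = dplyr::bind_rows(logs),
                 predictions = stats::setNames(preds, names_in),
                 config = cfg),
            class = "nuc_pipeline_result")
}

#' Compare prediction sets against a shared ground truth
#'
#' For each prediction dataset: per-tile count/area statistics, two-sided
#' Mann-Whitney U tests of predicted vs ground-truth per-tile counts and
#' relative areas, total-count relative deviation, and AP at IoU 0.5 on
#' boxes and on masks.
#'
#' @param pred_sets named list of `"coco_dataset"` objects (or paths to
#'   COCO JSON files).
#' @param gt ground-truth `"coco_dataset"` (or path).
#' @param out_dir optional directory; when given, writes
#'   `tile_stats_<name>.csv` and `comparison.csv`.
#' @return list of class `"nuc_comparison"`: `tile_stats` (named list),
#'   `results` (one tibble row per prediction set: U statistics, p-values,
#'   deviation, box/mask AP).
#' @export
run_compare <- function(pred_sets, gt, out_dir = NULL) {
  if (is.character(gt)) gt <- read_coco(gt)
  if (!is.list(pred_sets) || inherits(pred_sets, "coco_dataset")) {
    pred_sets <- list(pred = pred_sets)
  }
  pred_sets <- purrr::map(pred_sets, function(p) {
    if (is.character(p)) read_coco(p) else p
  })
  nm <- names(pred_sets) %||% paste0("pred", seq_along(pred_sets))
  stats_list <- list(); rows <- list()
  gt_dets_by_img <- NULL
  for (k in seq_along(pred_sets)) {
    pred <- pred_sets[[k]]
    ts <- per_tile_stats(pred, gt)
    mwu_count <- mann_whitney_u(ts$pred_count, ts$gt_count)
    mwu_area <- mann_whitney_u(ts$pred_rel_area, ts$gt_rel_area)
    ap_box <- pooled_ap(pred, gt, match_on = "box")
    ap_mask <- pooled_ap(pred, gt, match_on = "mask")
    rows[[k]] <- tibble::tibble(
      set = nm[k],
      n_tiles = nrow(ts),
      gt_total = sum(ts$gt_count), pred_total = sum(ts$pred_count),
      deviation_pct = relative_deviation(sum(ts$pred_count), sum(ts$gt_count)),
      u_count = mwu_count$u, p_count = mwu_count$p_value,
      u_area = mwu_area$u, p_area = mwu_area$p_value,
      ap_box = ap_box, ap_mask = ap_mask)
    stats_list[[nm[k]]] <- ts
  }
  results <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nmk in names(stats_list)) {
      readr::write_csv(stats_list[[nmk]],
                       file.path(out_dir, paste0("tile_stats_", nmk, ".csv")))
    }
    readr::write_csv(results, file.path(out_dir, "comparison.csv"))
  }
  structure(list(tile_stats = stats_list, results = results),
            class = "nuc_comparison")
}

## AP pooled over all shared images of two datasets (detections from each
## image offset into a private coordinate band so instances never match
## across images).
pooled_ap <- function(pred, gt, iou_threshold = 0.5, match_on = "box") {
  p_all <- list(); g_all <- list()
  offset <- 0L
  next_id <- 1L
  for (img_id in gt$images$id) {
    im <- gt$images[gt$images$id == img_id, ]
    pd <- coco_to_detections(coco_dataset(
      images = im, annotations = dplyr::filter(pred$annotations,
                                               .data$image_id == !!img_id)), img_id)
    gd <- coco_to_detections(coco_dataset(
      images = im, annotations = dplyr::filter(gt$annotations,
                                               .data$image_id == !!img_id)), img_id)
    shift <- function(d) {
      if (nrow(d) == 0) return(d)
      d$id <- seq(next_id, length.out = nrow(d))
      dplyr::mutate(d, x0 = .data$x0 + offset, x1 = .data$x1 + offset)
    }
    pd <- shift(pd); next_id <- next_id + nrow(pd)
    gd <- shift(gd)
    p_all[[length(p_all) + 1L]] <- pd
    g_all[[length(g_all) + 1L]] <- gd
    offset <- offset + im$width + 10L
  }
  res <- ap_at_iou(detections(p_all), detections(g_all),
                   iou_threshold, match_on)
  res$ap
}
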