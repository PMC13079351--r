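#' Overlapping tile grid over a full-scale image
#'
#' Computes the deterministic grid of square tiles covering an image, the
#' slicing scheme used both for training-set preparation and for sliced
#' inference: `tile_size` x `tile_size` windows with a fractional overlap
#' between neighbours (default 400 px tiles, 20% overlap = 80 px).
#'
#' Starts advance by `stride = round(tile_size * (1 - overlap_fraction))`
#' from 0; when the next window would poke past the image border, a single
#' final window is emitted flush with the border (`start = extent -
#' tile_size`) and the axis stops. Tiles are therefore always full-size and
#' fully inside the image; a 2048 px axis at (400, 0.2) yields starts
#' 0, 320, ..., 1600, 1648 — 7 per axis, 49 tiles.
#'
#' @param width,height image extent in pixels.
#' @param tile_size tile edge length in pixels (default 400).
#' @param overlap_fraction fractional overlap between neighbouring tiles,
#'   in `[0, 1)` (default 0.2).
#' @return a tibble of class `"nuc_tile_grid"` with one row per tile:
#'   `tile` (row-major index from 1), `x0`, `y0`, `x1`, `y1` (global frame),
#'   `boundary_shifted` (flag for border-flush tiles); attributes `width`,
#'   `height`, `tile_size`, `overlap_fraction`.
#' @examples
#' nrow(tile_grid(2048, 2048)) # 49
#' @export
tile_grid <- function(width, height, tile_size = 400, overlap_fraction = 0.2) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  if (tile_size > width || tile_size > height) {
    stop("tile_size exceeds the image extent", call. = FALSE)
  }
  starts <- function(extent) {
    stride <- as.integer(round(tile_size * (1 - overlap_fraction)))
    s <- seq(0L, by = stride, length.out = ceiling(extent / stride) + 1L)
    over <- which(s + tile_size > extent)[1]
    s <- unique(c(s[seq_len(over - 1L)], as.integer(extent - tile_size)))
    list(s = s, shifted = s == extent - tile_size & s %% stride != 0L)
  }
  sx <- starts(width)
  sy <- starts(height)
  g <- tidyr::expand_grid(y0 = sy$s, x0 = sx$s) # row-major: y slow? no - y outer
  out <- tibble::tibble(
    tile = seq_len(nrow(g)),
    x0 = g$x0, y0 = g$y0,
    x1 = g$x0 + as.integer(tile_size), y1 = g$y0 + as.integer(tile_size),
    boundary_shifted = rep(sy$shifted, each = length(sx$s)) |
      rep(sx$shifted, times = length(sy$s))
  )
  structure(out,
            width = as.integer(width), height = as.integer(height),
            tile_size = as.integer(tile_size),
            overlap_fraction = overlap_fraction,
            class = c("nuc_tile_grid", class(out)))
}

#' Slice an image into the tiles of a grid
#'
#' @param image numeric/integer matrix `[y, x]` whose dimensions match the
#'   grid.
#' @param grid a [tile_grid()].
#' @return the grid tibble with a `pixels` list-column holding each
#'   `tile_size` x `tile_size` crop.
#' @export
slice_image <- function(image, grid) {
  if (nrow(image) != attr(grid, "height") || ncol(image) != attr(grid, "width")) {
    stop("image dimensions do not match the tile grid", call. = FALSE)
  }
  out <- tibble::as_tibble(grid)
  out$pixels <- purrr::pmap(list(grid$x0, grid$y0, grid$x1, grid$y1),
                            function(x0, y0, x1, y1) {
                              image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
                            })
  out
}

#' Map tile-frame detections to the global frame
#'
#' Offsets all coordinates of a detections tibble by the origin of the tile
#' they were detected in; scores and mask rasters are unchanged.
#'
#' @param dets detections tibble in the tile frame.
#' @param tile a one-row tile from a [tile_grid()] (or anything with
#'   `x0`/`y0`).
#' @return the detections tibble in the global frame.
#' @export
to_global <- function(dets, tile) {
  if (nrow(dets) == 0) return(empty_detections())
  dplyr::mutate(dets,
                x0 = .data$x0 + tile$x0[1], x1 = .data$x1 + tile$x0[1],
                y0 = .data$y0 + tile$y0[1], y1 = .data$y1 + tile$y0[1],
                frame = "global")
}

#' Slice a COCO dataset into per-tile annotations
#'
#' Clips every instance of every image into each tile it intersects,
#' re-expressed in tile-frame coordinates. A clipped instance whose visible
#' area falls below `min_visible_fraction` of its original area is dropped
#' from that tile (tiny slivers at tile borders carry no context). Tile
#' images are named `<original stem>_tile<index>`.
#'
#' @param ds a COCO dataset from [read_coco()] / [coco_dataset()].
#' @param tile_size,overlap_fraction grid parameters, see [tile_grid()].
#' @param min_visible_fraction minimum clipped/original area ratio to keep
#'   an instance in a tile (default 0.1).
#' @return a COCO dataset whose images are the tiles.
#' @export
slice_annotations <- function(ds, tile_size = 400, overlap_fraction = 0.2,
                              min_visible_fraction = 0.1) {
  imgs <- list(); anns <- list(); next_img <- 1L; next_ann <- 1L
  for (k in seq_len(nrow(ds$images))) {
    im <- ds$images[k, ]
    grid <- tile_grid(im$width, im$height, tile_size, overlap_fraction)
    img_anns <- dplyr::filter(ds$annotations, .data$image_id == im$id)
    masks <- lapply(seq_len(nrow(img_anns)), function(i) {
      polygons_to_mask(img_anns$segmentation[[i]], im$width, im$height)
    })
    stem <- sub("\\.[A-Za-z]+$", "", im$file_name)
    for (t in seq_len(nrow(grid))) {
      tl <- grid[t, ]
      tile_img_id <- next_img; next_img <- next_img + 1L
      imgs[[length(imgs) + 1L]] <- tibble::tibble(
        id = tile_img_id,
        file_name = sprintf("%s_tile%d.tiff", stem, tl$tile),
        width = as.integer(tile_size), height = as.integer(tile_size))
      for (i in seq_along(masks)) {
        clip <- clip_mask(masks[[i]], tl$x0, tl$y0, tl$x1, tl$y1)
        if (is.null(clip)) next
        if (sum(clip$px) / sum(masks[[i]]$px) < min_visible_fraction) next
        anns[[length(anns) + 1L]] <- mask_to_annotation(
          clip, id = next_ann, image_id = tile_img_id)
        next_ann <- next_ann + 1L
      }
    }
  }
  coco_dataset(images = dplyr::bind_rows(imgs),
               annotations = dplyr::bind_rows(anns))
}

## Clip an instance_mask (global frame) to a tile rect; returns a tile-frame
## instance_mask or NULL when nothing is visible.
clip_mask <- function(m, x0, y0, x1, y1) {
  mx1 <- m$x0 + ncol(m$px); my1 <- m$y0 + nrow(m$px)
  cx0 <- max(m$x0, x0); cx1 <- min(mx1, x1)
  cy0 <- max(m$y0, y0); cy1 <- min(my1, y1)
  if (cx1 <= cx0 || cy1 <= cy0) return(NULL)
  sub <- m$px[(cy0 - m$y0 + 1):(cy1 - m$y0), (cx0 - m$x0 + 1):(cx1 - m$x0), drop = FALSE]
  if (!any(sub)) return(NULL)
  tighten_mask(list(px = sub, x0 = cx0 - x0, y0 = cy0 - y0))
}
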