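#' Instance masks and detection tables
#'
#' A *detection* is one predicted (or annotated) nucleus instance: a binary
#' mask over its tight bounding box, the box itself, and a confidence score.
#' Detections are kept in an ordinary tibble with one row per instance, so
#' they compose with dplyr verbs; the mask travels in a list-column.
#'
#' Coordinates are 0-based and half-open: a box `[x0, x1) x [y0, y1)` covers
#' pixel columns `x0 .. x1-1` and rows `y0 .. y1-1`, with `x` = column and
#' `y` = row, origin at the top-left (the COCO convention). The `frame`
#' column says whether coordinates are relative to a tile or to the full
#' image ("tile" or "global").
#'
#' @param mask logical (or 0/1) matrix, rows indexed by `y`, columns by `x`.
#' @param x0,y0 integer offset of the mask's top-left corner in its frame.
#' @param score detection confidence in `[0, 1]`.
#' @param id integer instance id.
#' @param frame `"tile"` or `"global"`.
#' @return `instance_mask()` returns a list with elements `px`, `x0`, `y0`;
#'   `detection_row()` a one-row detections tibble; `detections()` binds rows
#'   into a detections tibble with columns `id`, `x0`, `y0`, `x1`, `y1`,
#'   `score`, `frame`, `mask`.
#' @examples
#' m <- matrix(TRUE, 4, 6) # 6 px wide, 4 px tall
#' d <- detection_row(instance_mask(m, 10, 20), score = 0.99, id = 1L)
#' d$x1 - d$x0 # 6
#' @export
instance_mask <- function(mask, x0 = 0L, y0 = 0L) {
  px <- mask
  storage.mode(px) <- "logical"
  if (!is.matrix(px) || !any(px)) {
    stop("instance mask must be a non-empty logical matrix", call. = FALSE)
  }
  list(px = px, x0 = as.integer(x0), y0 = as.integer(y0))
}

#' @rdname instance_mask
#' @export
detection_row <- function(mask, score = 1, id = 1L, frame = "global") {
  m <- tighten_mask(mask)
  stopifnot(score >= 0, score <= 1, frame %in% c("tile", "global"))
  tibble::tibble(
    id = as.integer(id),
    x0 = m$x0, y0 = m$y0,
    x1 = m$x0 + ncol(m$px), y1 = m$y0 + nrow(m$px),
    score = as.numeric(score),
    frame = frame,
    mask = list(m$px)
  )
}

#' @rdname instance_mask
#' @param ... one-row tibbles from [detection_row()], or detections tibbles.
#' @export
detections <- function(...) {
  out <- dplyr::bind_rows(...)
  if (nrow(out) == 0) empty_detections() else out
}

empty_detections <- function(frame = "global") {
  tibble::tibble(
    id = integer(), x0 = integer(), y0 = integer(),
    x1 = integer(), y1 = integer(), score = numeric(),
    frame = character(), mask = list()
  )
}

#' Drop all-empty margins so the box is the tight box of the raster.
#' @noRd
tighten_mask <- function(m) {
  px <- m$px
  rows <- which(rowSums(px) > 0)
  cols <- which(colSums(px) > 0)
  list(
    px = px[rows[1]:rows[length(rows)], cols[1]:cols[length(cols)], drop = FALSE],
    x0 = m$x0 + cols[1] - 1L,
    y0 = m$y0 + rows[1] - 1L
  )
}

## Extract the instance_mask of row i of a detections tibble.
det_mask <- function(dets, i) {
  list(px = dets$mask[[i]], x0 = dets$x0[i], y0 = dets$y0[i])
}

## Paint row i of a detections tibble into a full-frame logical canvas
## (width x height pixels); returns the updated canvas matrix [y, x].
paint_mask <- function(canvas, m) {
  h <- nrow(m$px); w <- ncol(m$px)
  ys <- (m$y0 + 1):(m$y0 + h)
  xs <- (m$x0 + 1):(m$x0 + w)
  canvas[ys, xs] <- canvas[ys, xs] | m$px
  canvas
}

#' Union coverage of a set of detections
#'
#' Rasterizes all masks of a detections tibble onto one frame-sized canvas
#' and returns the union pixel count. Overlapping pixels count once, so the
#' result is the area actually covered by nuclei.
#'
#' @param dets detections tibble.
#' @param width,height frame extent in pixels.
#' @return integer pixel count of the union of all masks.
#' @export
union_area <- function(dets, width, height) {
  if (nrow(dets) == 0) return(0L)
  canvas <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(dets))) canvas <- paint_mask(canvas, det_mask(dets, i))
  sum(canvas)
}
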