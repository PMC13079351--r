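#' Bounding boxes
#'
#' Boxes are 0-based half-open pixel rectangles `[x0, x1) x [y0, y1)` tagged
#' with the frame ("tile" or "global") they live in. Overlap measures refuse
#' to compare boxes from different frames, which catches the classic bug of
#' mixing tile-local and global coordinates.
#'
#' @param x0,y0,x1,y1 box corners in pixels, `x1 > x0`, `y1 > y0`.
#' @param frame `"tile"` or `"global"`.
#' @return a named numeric vector of class `"nuc_bbox"`.
#' @export
bbox <- function(x0, y0, x1, y1, frame = "global") {
  stopifnot(x1 > x0, y1 > y0, x0 >= 0, y0 >= 0,
            frame %in% c("tile", "global"))
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            frame = frame, class = "nuc_bbox")
}

as_box4 <- function(b) {
  if (is.data.frame(b)) {
    stopifnot(nrow(b) == 1)
    structure(c(x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1),
              frame = b$frame)
  } else {
    unclass(b)
  }
}

check_same_frame <- function(a, b) {
  fa <- attr(a, "frame"); fb <- attr(b, "frame")
  if (!is.null(fa) && !is.null(fb) && !identical(fa, fb)) {
    stop("cannot compare boxes/masks from different frames ('",
         fa, "' vs '", fb, "')", call. = FALSE)
  }
}

box_intersection_area <- function(a, b) {
  w <- min(a["x1"], b["x1"]) - max(a["x0"], b["x0"])
  h <- min(a["y1"], b["y1"]) - max(a["y0"], b["y0"])
  if (w <= 0 || h <= 0) 0 else w * h
}

#' Intersection over union of two bounding boxes
#'
#' `|A n B| / |A u B|` on pixel areas; 0 for disjoint boxes. Both boxes must
#' be in the same coordinate frame.
#'
#' @param a,b boxes from [bbox()] or one-row detections tibbles.
#' @return a fraction in `[0, 1]`.
#' @examples
#' iou_boxes(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10)) # 1/3
#' @export
iou_boxes <- function(a, b) {
  check_same_frame(if (is.data.frame(a)) structure(0, frame = a$frame) else a,
                   if (is.data.frame(b)) structure(0, frame = b$frame) else b)
  a <- as_box4(a); b <- as_box4(b)
  inter <- box_intersection_area(a, b)
  if (inter == 0) return(0)
  area_a <- (a["x1"] - a["x0"]) * (a["y1"] - a["y0"])
  area_b <- (b["x1"] - b["x0"]) * (b["y1"] - b["y0"])
  unname(inter / (area_a + area_b - inter))
}

as_imask <- function(m) {
  if (is.data.frame(m)) det_mask(m, 1) else m
}

## Pixel counts of intersection and of each mask, via the overlapping
## sub-rectangle only (masks can sit anywhere in a shared frame).
mask_overlap_counts <- function(a, b) {
  ax1 <- a$x0 + ncol(a$px); ay1 <- a$y0 + nrow(a$px)
  bx1 <- b$x0 + ncol(b$px); by1 <- b$y0 + nrow(b$px)
  x0 <- max(a$x0, b$x0); x1 <- min(ax1, bx1)
  y0 <- max(a$y0, b$y0); y1 <- min(ay1, by1)
  inter <- 0L
  if (x1 > x0 && y1 > y0) {
    sa <- a$px[(y0 - a$y0 + 1):(y1 - a$y0), (x0 - a$x0 + 1):(x1 - a$x0), drop = FALSE]
    sb <- b$px[(y0 - b$y0 + 1):(y1 - b$y0), (x0 - b$x0 + 1):(x1 - b$x0), drop = FALSE]
    inter <- sum(sa & sb)
  }
  c(inter = inter, a = sum(a$px), b = sum(b$px))
}

#' Intersection over smaller area (IoS) of two masks
#'
#' `|A n B| / min(|A|, |B|)` on mask pixel counts. This is the merge
#' criterion used when fusing duplicate detections from adjacent tiles
#' (threshold 0.5) and, at a 0.02 threshold, the "relevant mask overlap"
#' criterion of the clustering rule.
#'
#' @param a,b instance masks from [instance_mask()] or one-row detections
#'   tibbles, in the same frame.
#' @return a fraction in `[0, 1]`.
#' @export
ios_masks <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) check_same_frame(
    structure(0, frame = a$frame), structure(0, frame = b$frame))
  a <- as_imask(a); b <- as_imask(b)
  n <- mask_overlap_counts(a, b)
  if (n[["a"]] == 0 || n[["b"]] == 0) {
    stop("ios_masks: empty mask", call. = FALSE)
  }
  unname(n[["inter"]] / min(n[["a"]], n[["b"]]))
}

#' Mask intersection over union
#'
#' Pixel-count IoU of two instance masks; the matching criterion of the
#' average-precision evaluator in mask mode.
#'
#' @inheritParams ios_masks
#' @return a fraction in `[0, 1]`.
#' @export
iou_masks <- function(a, b) {
  a <- as_imask(a); b <- as_imask(b)
  n <- mask_overlap_counts(a, b)
  unname(n[["inter"]] / (n[["a"]] + n[["b"]] - n[["inter"]]))
}

#' Convert a binary mask to COCO-style polygons
#'
#' Traces the boundary of the pixel region along pixel edges, so vertices
#' lie on the pixel-corner lattice and re-rasterizing the polygons
#' reproduces the mask exactly for simply-connected shapes. Interior holes
#' are filled before tracing (nuclei masks are effectively simply
#' connected); a component pinched at a diagonal corner yields one polygon
#' per 4-connected part. Collinear vertices are pruned, so an axis-aligned
#' rectangle comes back as its 4 corners.
#'
#' @param mask an [instance_mask()] or one-row detections tibble.
#' @return list of polygons; each is an `n x 2` matrix of `(x, y)` vertices
#'   in the mask's (global) frame, implicitly closed.
#' @export
mask_to_polygons <- function(mask) {
  m <- as_imask(mask)
  px <- fill_holes(m$px)
  h <- nrow(px); w <- ncol(px)
  p <- matrix(FALSE, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- px
  core <- p[2:(h + 1), 2:(w + 1), drop = FALSE]
  up    <- p[1:h, 2:(w + 1), drop = FALSE]
  down  <- p[3:(h + 2), 2:(w + 1), drop = FALSE]
  left  <- p[2:(h + 1), 1:w, drop = FALSE]
  right <- p[2:(h + 1), 3:(w + 2), drop = FALSE]

  edge_set <- function(sel, fx0, fy0, tx0, ty0) {
    idx <- which(sel, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    x <- idx[, 2] - 1L; y <- idx[, 1] - 1L # 0-based pixel coords
    cbind(fx = x + fx0, fy = y + fy0, tx = x + tx0, ty = y + ty0)
  }
  # directed so the interior is on the left of the walking direction
  edges <- rbind(
    edge_set(core & !up,    0L, 0L, 1L, 0L),  # top:    (x,y)   -> (x+1,y)
    edge_set(core & !right, 1L, 0L, 1L, 1L),  # right:  (x+1,y) -> (x+1,y+1)
    edge_set(core & !down,  1L, 1L, 0L, 1L),  # bottom: (x+1,y+1)->(x,y+1)
    edge_set(core & !left,  0L, 1L, 0L, 0L)   # left:   (x,y+1) -> (x,y)
  )
  K <- max(h, w) + 2L
  from_key <- edges[, "fx"] * K + edges[, "fy"]
  out_by_vertex <- split(seq_len(nrow(edges)), from_key)
  used <- logical(nrow(edges))

  polys <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    verts <- matrix(NA_integer_, nrow(edges) + 1L, 2L)
    nv <- 0L
    cur <- e0
    repeat {
      used[cur] <- TRUE
      nv <- nv + 1L
      verts[nv, ] <- edges[cur, c("fx", "fy")]
      vkey <- as.character(edges[cur, "tx"] * K + edges[cur, "ty"])
      cand <- out_by_vertex[[vkey]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      if (length(cand) == 1) {
        cur <- cand
      } else {
        # pinch vertex: take the turn that closes tightest around the
        # current pixel (positive cross product with the incoming direction)
        din <- edges[cur, c("tx", "ty")] - edges[cur, c("fx", "fy")]
        crosses <- vapply(cand, function(e) {
          d <- edges[e, c("tx", "ty")] - edges[e, c("fx", "fy")]
          din[1] * d[2] - din[2] * d[1]
        }, numeric(1))
        cur <- cand[which.max(crosses)]
      }
    }
    v <- verts[seq_len(nv), , drop = FALSE]
    v <- prune_collinear(v)
    v[, 1] <- v[, 1] + m$x0
    v[, 2] <- v[, 2] + m$y0
    colnames(v) <- c("x", "y")
    polys[[length(polys) + 1L]] <- v
  }
  polys
}

prune_collinear <- function(v) {
  n <- nrow(v)
  if (n < 3) return(v)
  keep <- logical(n)
  for (i in seq_len(n)) {
    a <- v[if (i == 1) n else i - 1, ]
    b <- v[i, ]
    c <- v[if (i == n) 1 else i + 1, ]
    keep[i] <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]) != 0
  }
  v[keep, , drop = FALSE]
}

fill_holes <- function(px) {
  filled <- EBImage::fillHull(EBImage::Image(px * 1))
  matrix(as.numeric(filled) > 0.5, nrow(px), ncol(px))
}

shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

## TRUE if any two non-adjacent polygon edges properly cross.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in 1:(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent around the wrap
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      o1 <- orient(a[1], a[2], b[1], b[2], c[1], c[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c[1], c[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c[1], c[2], d[1], d[2], b[1], b[2])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize COCO-style polygons into an instance mask
#'
#' Fills the union of the given closed polygons by testing pixel centers
#' (`x + 0.5`, `y + 0.5`); the inverse of [mask_to_polygons()] for polygons
#' produced there. Interior holes are not supported (outer contours only).
#'
#' @param polygons list of `n x 2` `(x, y)` vertex matrices, or a single
#'   matrix, or flat COCO `[x1, y1, x2, y2, ...]` vectors.
#' @param width,height frame extent in pixels; polygons must fit inside.
#' @return an [instance_mask()] (tight box plus offset).
#' @export
polygons_to_mask <- function(polygons, width, height) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  polys <- lapply(polygons, function(p) {
    if (!is.matrix(p)) p <- matrix(p, ncol = 2, byrow = TRUE)
    # drop an explicitly repeated closing vertex
    n <- nrow(p)
    if (n > 1 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    p
  })
  for (p in polys) {
    if (nrow(p) < 3 || shoelace_area(p) < 0.5) {
      stop("degenerate polygon (fewer than 3 vertices or zero area)", call. = FALSE)
    }
    if (polygon_self_intersects(p)) {
      stop("self-intersecting polygon", call. = FALSE)
    }
    if (any(p[, 1] < 0 | p[, 1] > width | p[, 2] < 0 | p[, 2] > height)) {
      stop("polygon vertices outside the frame extent", call. = FALSE)
    }
  }
  canvas <- matrix(FALSE, height, width)
  for (p in polys) {
    xr <- c(max(0L, floor(min(p[, 1]))), min(width, ceiling(max(p[, 1]))))
    yr <- c(max(0L, floor(min(p[, 2]))), min(height, ceiling(max(p[, 2]))))
    xs <- seq(xr[1], xr[2] - 1L)
    ys <- seq(yr[1], yr[2] - 1L)
    grid <- expand.grid(x = xs + 0.5, y = ys + 0.5)
    inside <- pracma::inpolygon(grid$x, grid$y, p[, 1], p[, 2], boundary = TRUE)
    if (any(inside)) {
      canvas[cbind(grid$y[inside] + 0.5, grid$x[inside] + 0.5)] <- TRUE
    }
  }
  if (!any(canvas)) stop("polygon rasterization produced an empty mask", call. = FALSE)
  tighten_mask(list(px = canvas, x0 = 0L, y0 = 0L))
}

#' Area-equivalent circle radius
#'
#' Radius of the circle with the same pixel area, `sqrt(area / pi)`; the
#' notion of "nucleus radius" used by the adaptive clustering distance,
#' well defined for arbitrarily shaped nuclei.
#'
#' @param area pixel count(s), `>= 1`.
#' @return radius in pixels (vectorized).
#' @export
equivalent_radius <- function(area) {
  if (any(area < 1)) stop("area must be >= 1 pixel", call. = FALSE)
  sqrt(area / pi)
}
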