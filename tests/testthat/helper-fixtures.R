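# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written as direct brute force over pixels /
# orderings / enumerations, independent of the package's code paths.

# logical raster of a disk, on an n x n canvas, matrix [y, x]
disk_raster <- function(r, n = 2 * r + 11, cx = n / 2, cy = n / 2) {
  xs <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - 0.5, n, n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# rotated ellipse raster with semi-axes a (x) and b (y)
ellipse_raster <- function(a, b, theta = 0, n = 2 * ceiling(max(a, b)) + 11,
                           cx = n / 2, cy = n / 2) {
  xs <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE) - cx
  ys <- matrix(seq_len(n) - 0.5, n, n) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# random 4/8-connected-ish blob: union of a few random disks
blob_raster <- function(n = 40, n_seeds = 3, rmax = 8) {
  canvas <- matrix(FALSE, n, n)
  cx0 <- runif(1, rmax + 2, n - rmax - 2)
  cy0 <- runif(1, rmax + 2, n - rmax - 2)
  for (k in seq_len(n_seeds)) {
    r <- runif(1, 3, rmax)
    cx <- cx0 + runif(1, -4, 4)
    cy <- cy0 + runif(1, -4, 4)
    canvas <- canvas | disk_raster(r, n, cx, cy)
  }
  canvas
}

# paint an instance mask onto a w x h canvas (brute-force frame raster)
rasterize_full <- function(m, width, height) {
  canvas <- matrix(FALSE, height, width)
  canvas[(m$y0 + 1):(m$y0 + nrow(m$px)), (m$x0 + 1):(m$x0 + ncol(m$px))] <-
    canvas[(m$y0 + 1):(m$y0 + nrow(m$px)),
           (m$x0 + 1):(m$x0 + ncol(m$px))] | m$px
  canvas
}

# per-pixel overlap oracles on full-frame rasters
pixel_iou <- function(ra, rb) sum(ra & rb) / sum(ra | rb)
pixel_ios <- function(ra, rb) sum(ra & rb) / min(sum(ra), sum(rb))

# brute-force transitive closure of a pairwise link matrix (n x n logical)
closure_components <- function(link) {
  n <- nrow(link)
  reach <- link | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# independent AP evaluator: same definition, independent code path --
# exhaustive best-unmatched-GT search per prediction, right-to-left
# precision envelope sampled on the 101-point recall grid
oracle_ap <- function(pred_boxes, pred_scores, gt_boxes, iou_thr = 0.5) {
  n_gt <- nrow(gt_boxes)
  ord <- order(-pred_scores)
  used <- rep(FALSE, n_gt)
  tp <- numeric(length(ord))
  box_iou <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  for (i in ord) {
    best <- 0; best_j <- 0
    for (j in seq_len(n_gt)) {
      if (used[j]) next
      v <- box_iou(pred_boxes[i, ], gt_boxes[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0 && best >= iou_thr) { used[best_j] <- TRUE; tp[which(ord == i)] <- 1 }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / n_gt
  # precision envelope from the right, then sample the recall grid
  env <- rev(cummax(rev(prec)))
  mean(vapply(seq(0, 1, 0.01), function(r) {
    k <- which(rec >= r)
    if (length(k) == 0) 0 else env[k[1]]
  }, numeric(1))) * 100
}

# exact two-sided Mann-Whitney p by enumeration, written independently
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  n_a <- length(a)
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(length(pooled), n_a)
  us <- apply(sets, 2, function(ix) sum(rk[ix]) - n_a * (n_a + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# small noise-free, non-touching scene used by several suites; nuclei are
# kept in the bright band so they sit inside the reference threshold
# detector's operating range (a global Otsu split cannot recover nuclei
# much dimmer than their tile-mates -- the classic low-DNA-density failure
# mode the pipeline's trained backends exist to fix)
clean_scene <- function(n = 8, seed = 5, wh = 512) {
  synthesize_scene(scene_spec(
    width = wh, height = wh, n_nuclei = n, cluster_fraction = 0,
    intensity_range = c(150, 240),
    noise_sd = 0, blur_sigma = 1, seed = seed))
}
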