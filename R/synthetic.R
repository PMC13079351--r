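#' Specification of a synthetic fluorescence scene
#'
#' Parameters of a DAPI-like scene: bright nuclei of varying size, shape
#' (circular, elliptical, or u-shaped crescents — the shape that splits
#' naive detectors) and brightness (emulating high- versus low-DNA-density
#' nuclei) on a darker fiber background, optionally placed in overlapping
#' groups. Defaults emulate a 2048 x 2048 px field at 40x with nucleus
#' radii of 8–20 px.
#'
#' @param width,height image extent in pixels (default 2048).
#' @param n_nuclei number of nuclei to place.
#' @param radius_range min/max equivalent radius in pixels.
#' @param intensity_range dim-to-bright nucleus intensity (8-bit units).
#' @param shape_mix named fractions `circular`, `elliptical`, `u_shaped`
#'   summing to <= 1 (remainder circular).
#' @param cluster_fraction fraction of nuclei placed in overlapping groups.
#' @param cluster_spread centre-to-centre distance of clustered neighbours,
#'   as a fraction of the sum of their radii (< 1 forces mask overlap).
#' @param background,noise_sd background level and Gaussian noise sd
#'   (8-bit units).
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param halo_amplitude intensity of a faint ring around bright nuclei
#'   (0 = none).
#' @param seed integer RNG seed; the whole scene is a pure function of the
#'   spec.
#' @return list of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 2048, height = 2048, n_nuclei = 100,
                       radius_range = c(8, 20),
                       intensity_range = c(90, 240),
                       shape_mix = c(circular = 0.6, elliptical = 0.3,
                                     u_shaped = 0.1),
                       cluster_fraction = 0.3, cluster_spread = 0.8,
                       background = 20, noise_sd = 4, blur_sigma = 1,
                       halo_amplitude = 0, seed = 1L) {
  stopifnot(n_nuclei >= 0, diff(radius_range) >= 0, diff(intensity_range) >= 0,
            sum(shape_mix) <= 1 + 1e-9, cluster_fraction >= 0,
            cluster_fraction <= 1, seed < 2^31)
  structure(as.list(environment()), class = "scene_spec")
}

#' Render a synthetic scene with exact ground truth
#'
#' Deterministically (per seed) places and renders the nuclei of a
#' [scene_spec()]: filled rotated ellipses, u-shapes as crescents (an
#' ellipse minus a shifted copy), clustered nuclei with centre distances
#' below the sum of their radii so masks genuinely overlap, then background,
#' additive Gaussian noise, optional halo rings and Gaussian blur. Ground
#' truth is recorded pre-blur, one annotation per rendered nucleus.
#'
#' @param spec a [scene_spec()].
#' @return list of class `"nuc_scene"`: `image` (8-bit integer matrix),
#'   `gt` (a `coco_dataset` of the true instances), `params` (tibble of
#'   per-nucleus generative parameters incl. `group` membership), `spec`.
#' @export
synthesize_scene <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  w <- spec$width; h <- spec$height
  n <- spec$n_nuclei
  params <- place_nuclei(spec)
  img <- matrix(spec$background, h, w)
  masks <- vector("list", n)
  if (n > 0) {
    for (i in seq_len(n)) {
      m <- render_nucleus(params[i, ], w, h)
      masks[[i]] <- m
      sub <- img[(m$y0 + 1):(m$y0 + nrow(m$px)),
                 (m$x0 + 1):(m$x0 + ncol(m$px)), drop = FALSE]
      sub[m$px] <- pmax(sub[m$px], params$intensity[i])
      img[(m$y0 + 1):(m$y0 + nrow(m$px)),
          (m$x0 + 1):(m$x0 + ncol(m$px))] <- sub
      if (spec$halo_amplitude > 0) {
        img <- add_halo(img, m, spec$halo_amplitude, spec$background)
      }
    }
  }
  if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(w * h, 0, spec$noise_sd), h, w)
  if (spec$blur_sigma > 0) {
    img <- EBImage::gblur(EBImage::Image(img / 255), sigma = spec$blur_sigma)
    img <- as.matrix(img) * 255
  }
  img <- matrix(as.integer(pmax(pmin(round(img), 255), 0)), h, w)
  attr(img, "bit_depth") <- 8L

  anns <- purrr::imap(masks[lengths(masks) > 0],
                      function(m, i) mask_to_annotation(m, id = i, image_id = 1L))
  gt <- coco_dataset(
    images = tibble::tibble(id = 1L, file_name = "synthetic.tiff",
                            width = as.integer(w), height = as.integer(h)),
    annotations = dplyr::bind_rows(anns))
  structure(list(image = img, gt = gt, params = params, spec = spec),
            class = "nuc_scene")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Sample per-nucleus generative parameters with feasible placement:
## isolated nuclei keep >= 3 px clearance to every other nucleus; clustered
## nuclei are chained with centre distance cluster_spread * (r_i + r_j).
place_nuclei <- function(spec) {
  n <- spec$n_nuclei
  cols <- tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                         r = numeric(), aspect = numeric(), angle = numeric(),
                         shape = character(), intensity = numeric(),
                         group = integer())
  if (n == 0) return(cols)
  mix <- spec$shape_mix
  shapes <- sample(c("circular", "elliptical", "u_shaped"), n, replace = TRUE,
                   prob = c(1 - sum(mix[c("elliptical", "u_shaped")]),
                            mix[["elliptical"]], mix[["u_shaped"]]))
  r <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
  margin <- max(spec$radius_range) * 2 + 4
  if (2 * margin >= min(spec$width, spec$height)) {
    stop("scene too small for the requested nucleus radii", call. = FALSE)
  }
  n_clustered <- round(spec$cluster_fraction * n)
  group <- integer(n)
  xs <- ys <- numeric(n)
  placed <- 0
  gid <- 0L
  i <- 1L
  while (i <= n) {
    gsize <- if (n_clustered - sum(group > 0) >= 2 &&
                 i <= n - 1) min(sample(2:4, 1), n - i + 1L) else 1L
    if (gsize > 1 && sum(group > 0) + gsize > n_clustered + 2) gsize <- 1L
    ok <- FALSE
    for (try in 1:200) {
      cx <- stats::runif(1, margin, spec$width - margin)
      cy <- stats::runif(1, margin, spec$height - margin)
      clear <- if (i == 1) TRUE else all(
        sqrt((xs[seq_len(i - 1)] - cx)^2 + (ys[seq_len(i - 1)] - cy)^2) >
          r[seq_len(i - 1)] + r[i] + gsize * 2 * max(r) + 3)
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place nuclei: scene too crowded", call. = FALSE)
    xs[i] <- cx; ys[i] <- cy
    if (gsize > 1) {
      gid <- gid + 1L
      group[i] <- gid
      ang <- stats::runif(1, 0, 2 * pi)
      for (k in seq_len(gsize - 1L)) {
        j <- i + k
        d <- spec$cluster_spread * (r[j - 1] + r[j])
        ang <- ang + stats::runif(1, -0.8, 0.8)
        xs[j] <- xs[j - 1] + d * cos(ang)
        ys[j] <- ys[j - 1] + d * sin(ang)
        group[j] <- gid
      }
      i <- i + gsize
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(
    id = seq_len(n), x = xs, y = ys, r = r,
    aspect = ifelse(shapes == "elliptical", stats::runif(n, 1.5, 2.5), 1),
    angle = stats::runif(n, 0, pi),
    shape = shapes,
    intensity = stats::runif(n, spec$intensity_range[1], spec$intensity_range[2]),
    group = group)
}

## Rasterize one nucleus from its generative parameters.
render_nucleus <- function(p, width, height) {
  a <- p$r * sqrt(p$aspect) # semi-axes with area ~ pi r^2
  b <- p$r / sqrt(p$aspect)
  ext <- ceiling(max(a, b)) + 2L
  x0 <- max(0L, floor(p$x) - ext); x1 <- min(width, ceiling(p$x) + ext)
  y0 <- max(0L, floor(p$y) - ext); y1 <- min(height, ceiling(p$y) + ext)
  gx <- seq(x0, x1 - 1L) + 0.5
  gy <- seq(y0, y1 - 1L) + 0.5
  gridx <- matrix(gx, length(gy), length(gx), byrow = TRUE) - p$x
  gridy <- matrix(gy, length(gy), length(gx)) - p$y
  u <- gridx * cos(p$angle) + gridy * sin(p$angle)
  v <- -gridx * sin(p$angle) + gridy * cos(p$angle)
  px <- (u / a)^2 + (v / b)^2 <= 1
  if (p$shape == "u_shaped") {
    # crescent: subtract an ellipse shifted along the major axis
    u2 <- u - 0.7 * a
    cut <- (u2 / (0.9 * a))^2 + (v / (0.75 * b))^2 <= 1
    px <- px & !cut
    if (!any(px)) px <- (u / a)^2 + (v / b)^2 <= 1
  }
  tighten_mask(list(px = px, x0 = as.integer(x0), y0 = as.integer(y0)))
}

add_halo <- function(img, m, amplitude, background) {
  grow <- 3L
  y0 <- max(0L, m$y0 - grow); x0 <- max(0L, m$x0 - grow)
  y1 <- min(nrow(img), m$y0 + nrow(m$px) + grow)
  x1 <- min(ncol(img), m$x0 + ncol(m$px) + grow)
  big <- matrix(FALSE, y1 - y0, x1 - x0)
  big[(m$y0 - y0 + 1):(m$y0 - y0 + nrow(m$px)),
      (m$x0 - x0 + 1):(m$x0 - x0 + ncol(m$px))] <- m$px
  dil <- EBImage::dilate(EBImage::Image(big * 1),
                         EBImage::makeBrush(2 * grow + 1, "disc"))
  ring <- (as.matrix(dil) > 0.5) & !big
  sub <- img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  sub[ring] <- pmax(sub[ring], background + amplitude)
  img[(y0 + 1):y1, (x0 + 1):x1] <- sub
  img
}
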