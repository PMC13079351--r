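#' Per-nucleus morphometrics
#'
#' Computes the geometric and intensity descriptors of every detected
#' nucleus: area (pixel count), centroid (mask centre of mass), perimeter
#' (length of the sub-pixel 0.5-level iso-contour of the mask, or the count
#' of exposed pixel edges with `perimeter = "pixel_edges"`), eccentricity of
#' the moment-fit ellipse (`sqrt(1 - lambda2/lambda1)` from the eigenvalues
#' of the pixel-coordinate covariance; 0 = circular, near 1 = elongated),
#' and mean image intensity inside the mask, in the original image units.
#'
#' @param dets global-frame detections tibble.
#' @param image integer/numeric matrix `[y, x]` the detections live on.
#' @param perimeter `"contour"` (marching-squares 0.5-level, sub-pixel) or
#'   `"pixel_edges"`.
#' @return a tibble with one row per nucleus: `id`, `x`, `y` (centroid),
#'   `area`, `perimeter`, `eccentricity`, `mean_intensity`.
#' @export
nucleus_morphometrics <- function(dets, image,
                                  perimeter = c("contour", "pixel_edges")) {
  perimeter <- match.arg(perimeter)
  rows <- purrr::map(seq_len(nrow(dets)), function(i) {
    m <- det_mask(dets, i)
    idx <- which(m$px, arr.ind = TRUE)
    # pixel-centre coordinates, global frame
    xs <- m$x0 + idx[, 2] - 0.5
    ys <- m$y0 + idx[, 1] - 0.5
    area <- nrow(idx)
    mu <- mask_ellipse_moments(xs, ys)
    sub <- image[(m$y0 + 1):(m$y0 + nrow(m$px)),
                 (m$x0 + 1):(m$x0 + ncol(m$px)), drop = FALSE]
    tibble::tibble(
      id = dets$id[i],
      x = mean(xs), y = mean(ys),
      area = area,
      perimeter = if (perimeter == "contour") contour_perimeter(m$px)
                  else pixel_edge_perimeter(m$px),
      eccentricity = mu$ecc,
      mean_intensity = mean(sub[m$px]))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                          area = integer(), perimeter = numeric(),
                          eccentricity = numeric(), mean_intensity = numeric()))
  }
  dplyr::bind_rows(rows)
}

mask_ellipse_moments <- function(xs, ys) {
  n <- length(xs)
  if (n < 2) return(list(ecc = 0))
  mu20 <- sum((xs - mean(xs))^2) / n
  mu02 <- sum((ys - mean(ys))^2) / n
  mu11 <- sum((xs - mean(xs)) * (ys - mean(ys))) / n
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(list(ecc = 0))
  list(ecc = sqrt(max(1 - l2 / l1, 0)))
}

## Perimeter as the total length of the marching-squares 0.5-level contour
## of the zero-padded mask (pixel-centre sample grid).
contour_perimeter <- function(px) {
  h <- nrow(px); w <- ncol(px)
  z <- matrix(0, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- px * 1
  # contourLines expects z[i, j] at (x[i], y[j]): feed the transpose
  cl <- grDevices::contourLines(x = 0:(h + 1), y = 0:(w + 1), z = z, levels = 0.5)
  sum(vapply(cl, function(seg) {
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
  }, numeric(1)))
}

pixel_edge_perimeter <- function(px) {
  h <- nrow(px); w <- ncol(px)
  p <- matrix(FALSE, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- px
  core <- p[2:(h + 1), 2:(w + 1)]
  sum(core & !p[1:h, 2:(w + 1)]) + sum(core & !p[3:(h + 2), 2:(w + 1)]) +
    sum(core & !p[2:(h + 1), 1:w]) + sum(core & !p[2:(h + 1), 3:(w + 2)])
}

#' Local nuclei density
#'
#' Number of neighbouring nuclei whose centroid lies within
#' `vicinity_radius` of each nucleus (the nucleus itself excluded). The
#' default radius of 100 px is about five typical nucleus diameters at the
#' 40x magnification the pipeline targets.
#'
#' @param records morphometrics tibble with `x`, `y` columns.
#' @param vicinity_radius neighbourhood radius in pixels (default 100).
#' @return the tibble with a `local_density` integer column added.
#' @export
local_density <- function(records, vicinity_radius = 100) {
  n <- nrow(records)
  if (n == 0) return(dplyr::mutate(records, local_density = integer()))
  d <- as.matrix(stats::dist(cbind(records$x, records$y)))
  records$local_density <- as.integer(colSums(d <= vicinity_radius) - 1L)
  records
}

#' Nearest-neighbour distance
#'
#' Centroid-to-centroid distance to the closest other nucleus; `NA` for a
#' lone nucleus.
#'
#' @param records morphometrics tibble with `x`, `y` columns.
#' @return the tibble with an `nn_distance` column added.
#' @export
nearest_neighbor_distance <- function(records) {
  n <- nrow(records)
  if (n == 0) return(dplyr::mutate(records, nn_distance = numeric()))
  if (n == 1) return(dplyr::mutate(records, nn_distance = NA_real_))
  d <- as.matrix(stats::dist(cbind(records$x, records$y)))
  diag(d) <- Inf
  records$nn_distance <- unname(apply(d, 1, min))
  records
}

#' Adaptive centre-distance threshold for the clustering rule
#'
#' Two nuclei can be linked without mask overlap when their centroids are
#' closer than a threshold that adapts to nucleus size and crowding:
#' `T = alpha * (r_i + r_j) / (1 + beta * rho)`, with `r` the
#' area-equivalent radii and `rho` the mean local density of the pair.
#' Larger nuclei may link from further apart; in dense fields the threshold
#' tightens so incidental proximity is not over-linked. With the defaults
#' (`alpha = 1.2`, `beta = 0.05`) two touching average nuclei (r about
#' 10 px) link. Symmetric in `r_i`, `r_j`; increasing in each radius;
#' decreasing in `rho`.
#'
#' @param r_i,r_j area-equivalent radii in pixels, `> 0`.
#' @param rho mean local density of the pair, `>= 0`.
#' @param alpha,beta scale and crowding-damping parameters.
#' @return threshold distance in pixels (vectorized).
#' @export
adaptive_distance_threshold <- function(r_i, r_j, rho = 0,
                                        alpha = 1.2, beta = 0.05) {
  stopifnot(all(r_i > 0), all(r_j > 0), all(rho >= 0))
  alpha * (r_i + r_j) / (1 + beta * rho)
}

#' Build the nuclei adjacency graph
#'
#' Inserts an undirected edge between two nuclei when they either share a
#' relevant mask overlap (IoS above `overlap_threshold`, default 2%) or
#' their centroids fall within the [adaptive_distance_threshold()] computed
#' from their radii and the mean of their local densities.
#'
#' @param dets global-frame detections tibble.
#' @param records morphometrics tibble aligned with `dets` (needs
#'   `local_density`; computed at radius `vicinity_radius` if absent).
#' @param overlap_threshold IoS above which two masks count as overlapping
#'   (default 0.02, i.e. the ">2%" rule).
#' @param alpha,beta adaptive-threshold parameters.
#' @param vicinity_radius radius for `local_density` if it must be computed.
#' @return a two-column `edges` tibble (`from`, `to` nucleus ids).
#' @export
build_cluster_graph <- function(dets, records, overlap_threshold = 0.02,
                                alpha = 1.2, beta = 0.05,
                                vicinity_radius = 100) {
  stopifnot(nrow(dets) == nrow(records), all(dets$id == records$id))
  if (!"local_density" %in% names(records)) {
    records <- local_density(records, vicinity_radius)
  }
  n <- nrow(dets)
  edges <- list()
  if (n >= 2) {
    r <- equivalent_radius(records$area)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        dist_ij <- sqrt((records$x[i] - records$x[j])^2 +
                          (records$y[i] - records$y[j])^2)
        thr <- adaptive_distance_threshold(
          r[i], r[j], mean(c(records$local_density[i],
                             records$local_density[j])), alpha, beta)
        linked <- dist_ij <= thr
        if (!linked) {
          n_ov <- mask_overlap_counts(det_mask(dets, i), det_mask(dets, j))
          linked <- n_ov[["inter"]] / min(n_ov[["a"]], n_ov[["b"]]) >
            overlap_threshold
        }
        if (linked) {
          edges[[length(edges) + 1L]] <- c(records$id[i], records$id[j])
        }
      }
    }
  }
  if (length(edges) == 0) {
    tibble::tibble(from = integer(), to = integer())
  } else {
    e <- do.call(rbind, edges)
    tibble::tibble(from = as.integer(e[, 1]), to = as.integer(e[, 2]))
  }
}

#' Assign cluster ids from the nuclei graph
#'
#' Connected components of size >= 2 become clusters, numbered 1, 2, ... in
#' the order of their topmost-then-leftmost member centroid; isolated nuclei
#' receive the reserved cluster id 0.
#'
#' @param edges edge tibble from [build_cluster_graph()].
#' @param records morphometrics tibble (provides ids and centroids).
#' @return `records` with a `cluster_id` column added.
#' @export
assign_cluster_ids <- function(edges, records) {
  ids <- records$id
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  member <- comp$membership[as.character(ids)]
  records$cluster_id <- 0L
  real <- which(comp$csize >= 2)
  if (length(real) > 0) {
    # order clusters by topmost, then leftmost member centroid
    anchor <- vapply(real, function(cc) {
      in_cc <- which(member == cc)
      top <- min(records$y[in_cc])
      left <- min(records$x[in_cc][records$y[in_cc] == top])
      top * 1e9 + left
    }, numeric(1))
    for (k in seq_along(real[order(anchor)])) {
      records$cluster_id[member == real[order(anchor)][k]] <- k
    }
  }
  records
}

#' Aggregate statistics per cluster
#'
#' For each cluster: member count, union area of member masks (overlapping
#' pixels counted once), the ratio of member count to all detected nuclei
#' in the image, and union area relative to the full image.
#'
#' @param records tibble with `cluster_id` from [assign_cluster_ids()].
#' @param dets the detections the records describe.
#' @param width,height image extent in pixels.
#' @return a tibble with one row per cluster: `cluster_id`, `n_nuclei`,
#'   `total_area`, `count_ratio`, `area_ratio`.
#' @export
cluster_aggregates <- function(records, dets, width, height) {
  cl_ids <- sort(unique(records$cluster_id[records$cluster_id > 0]))
  rows <- purrr::map(cl_ids, function(cid) {
    members <- records$id[records$cluster_id == cid]
    sub <- dets[dets$id %in% members, ]
    tibble::tibble(
      cluster_id = as.integer(cid),
      n_nuclei = length(members),
      total_area = union_area(sub, width, height),
      count_ratio = length(members) / nrow(records),
      area_ratio = union_area(sub, width, height) / (width * height))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(cluster_id = integer(), n_nuclei = integer(),
                          total_area = integer(), count_ratio = numeric(),
                          area_ratio = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Per-image summary
#'
#' Totals of the analysis: nuclei count, number of clusters, number of
#' isolated nuclei, union area covered by all masks, and that area relative
#' to the image. Isolated plus clustered counts always equal the total.
#'
#' @param records tibble with `cluster_id`.
#' @param dets detections tibble.
#' @param width,height image extent in pixels.
#' @param image_id identifier to carry through (default 1).
#' @return a one-row tibble: `image_id`, `n_nuclei`, `n_clusters`,
#'   `n_isolated`, `covered_area`, `relative_area`.
#' @export
image_summary <- function(records, dets, width, height, image_id = 1L) {
  cov <- union_area(dets, width, height)
  tibble::tibble(
    image_id = as.integer(image_id),
    n_nuclei = nrow(records),
    n_clusters = length(unique(records$cluster_id[records$cluster_id > 0])),
    n_isolated = sum(records$cluster_id == 0),
    covered_area = cov,
    relative_area = cov / (width * height))
}

#' Full analysis of one image's detections
#'
#' Convenience wrapper chaining morphometrics, density, nearest-neighbour
#' distance, graph clustering and aggregation.
#'
#' @inheritParams nucleus_morphometrics
#' @inheritParams build_cluster_graph
#' @param image_id identifier for the summary row.
#' @return list of class `"nuc_analysis"` with tibbles `nuclei`, `clusters`,
#'   `summary`.
#' @export
analyze_detections <- function(dets, image, overlap_threshold = 0.02,
                               alpha = 1.2, beta = 0.05,
                               vicinity_radius = 100, image_id = 1L) {
  rec <- nucleus_morphometrics(dets, image)
  rec <- local_density(rec, vicinity_radius)
  rec <- nearest_neighbor_distance(rec)
  edges <- build_cluster_graph(dets, rec, overlap_threshold, alpha, beta)
  rec <- assign_cluster_ids(edges, rec)
  w <- ncol(image); h <- nrow(image)
  structure(list(
    nuclei = rec,
    clusters = cluster_aggregates(rec, dets, w, h),
    summary = image_summary(rec, dets, w, h, image_id)),
    class = "nuc_analysis")
}
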