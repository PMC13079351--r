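test_that("morphometrics of a disk: near-zero eccentricity, correct area/intensity", {
  ra <- disk_raster(20)
  d <- detection_row(instance_mask(ra))
  rec <- nucleus_morphometrics(d, matrix(100, nrow(ra), ncol(ra)))
  expect_lte(rec$eccentricity, 0.05)
  expect_equal(rec$area, pi * 400, tolerance = 0.02)
  expect_equal(rec$mean_intensity, 100)
  # the 0.5-level contour of a binary disk runs slightly outside the ideal
  # circle (stair-step cuts), so its length sits a few percent above 2*pi*r
  expect_gte(rec$perimeter, 2 * pi * 20)
  expect_lte(rec$perimeter, 1.1 * 2 * pi * 20)
  expect_equal(nucleus_morphometrics(d, matrix(100, nrow(ra), ncol(ra)),
                                     perimeter = "pixel_edges")$perimeter,
               fibernuclei:::pixel_edge_perimeter(ra))
})

test_that("moment eccentricity matches the analytic ellipse value within 0.02", {
  cases <- list(c(20, 10), c(15, 12), c(30, 8), c(10, 10))
  for (ab in cases) {
    for (theta in c(0, pi / 7, pi / 3)) {
      ra <- ellipse_raster(ab[1], ab[2], theta)
      rec <- nucleus_morphometrics(detection_row(instance_mask(ra)),
                                   matrix(0, nrow(ra), ncol(ra)))
      expect_equal(rec$eccentricity, sqrt(1 - (ab[2] / ab[1])^2),
                   tolerance = 0.021)
    }
  }
})

test_that("local density counts neighbours within the vicinity radius", {
  rec1 <- tibble::tibble(id = 1L, x = 0, y = 0, area = 100)
  expect_equal(local_density(rec1, 100)$local_density, 0L)
  rec2 <- tibble::tibble(id = 1:2, x = c(0, 50), y = c(0, 0), area = 100)
  expect_equal(local_density(rec2, 100)$local_density, c(1L, 1L))
  # 3x3 grid, spacing 60, radius 100: centre sees all 8; a corner sees the
  # two at 60, one at 60*sqrt(2) = 84.9 -- wait, and the opposite-edge mids
  g <- tidyr::expand_grid(gx = 0:2, gy = 0:2)
  recs <- tibble::tibble(id = 1:9, x = g$gx * 60, y = g$gy * 60, area = 100)
  ld <- local_density(recs, 100)$local_density
  centre <- which(recs$x == 60 & recs$y == 60)
  corners <- which(recs$x %in% c(0, 120) & recs$y %in% c(0, 120))
  # brute-force oracle
  dmat <- as.matrix(dist(cbind(recs$x, recs$y)))
  expect_equal(ld, as.integer(colSums(dmat <= 100) - 1L))
  expect_equal(ld[centre], 8L)
  # a corner sees its two orthogonal neighbours at 60 and the diagonal at 84.9
  expect_equal(ld[corners], rep(3L, 4))
})

test_that("nearest-neighbour distance matches brute force; lone nucleus is NA", {
  lone <- tibble::tibble(id = 1L, x = 5, y = 5)
  expect_true(is.na(nearest_neighbor_distance(lone)$nn_distance))
  two <- tibble::tibble(id = 1:2, x = c(0, 42), y = c(0, 0))
  expect_equal(nearest_neighbor_distance(two)$nn_distance, c(42, 42))
  set.seed(9)
  recs <- tibble::tibble(id = 1:5, x = runif(5, 0, 200), y = runif(5, 0, 200))
  nn <- nearest_neighbor_distance(recs)$nn_distance
  dmat <- as.matrix(dist(cbind(recs$x, recs$y))); diag(dmat) <- Inf
  expect_equal(nn, unname(apply(dmat, 1, min)))
})

test_that("the adaptive distance threshold follows its closed form", {
  expect_equal(adaptive_distance_threshold(10, 10, 0), 24)
  expect_equal(adaptive_distance_threshold(10, 14, 3),
               adaptive_distance_threshold(14, 10, 3))
  rho <- c(0, 1, 5, 20)
  expect_true(all(diff(adaptive_distance_threshold(10, 10, rho)) < 0))
  expect_true(all(diff(adaptive_distance_threshold(seq(5, 20, 5), 10, 2)) > 0))
})

test_that("the edge rule links by overlap OR adaptive distance, as specified", {
  # two long bars overlapping ~5% at their tips: far centroids, IoS > 2%
  bar1 <- detection_row(instance_mask(matrix(TRUE, 4, 100), 0, 0), id = 1)
  bar2 <- detection_row(instance_mask(matrix(TRUE, 4, 100), 95, 0), id = 2)
  dets <- detections(bar1, bar2)
  rec <- local_density(nucleus_morphometrics(dets, matrix(0, 10, 200)), 100)
  expect_equal(ios_masks(bar1, bar2), 0.05)
  e <- build_cluster_graph(dets, rec)
  expect_equal(nrow(e), 1) # centroids 95 px apart > T = 27.1, overlap decides
  # shrink the overlap below 2% and push the bars apart: no edge
  bar2b <- detection_row(instance_mask(matrix(TRUE, 4, 100), 99, 0), id = 2)
  dets2 <- detections(bar1, bar2b)
  rec2 <- local_density(nucleus_morphometrics(dets2, matrix(0, 10, 200)), 100)
  expect_equal(ios_masks(bar1, bar2b), 0.01)
  expect_equal(nrow(build_cluster_graph(dets2, rec2)), 0)
})

test_that("overlap and distance links chain but do not shortcut", {
  # collinear r=10 disks at x = 20, 32, 53: A-B masks overlap (d = 12);
  # B-C sit 21 px apart, inside the adaptive threshold 24/1.1 = 21.8 but
  # with disjoint masks; A-C are 33 px apart, beyond both criteria
  a <- detection_row(instance_mask(disk_raster(10, 80, 20, 20)), id = 1)
  b <- detection_row(instance_mask(disk_raster(10, 80, 32, 20)), id = 2)
  c <- detection_row(instance_mask(disk_raster(10, 80, 53, 20)), id = 3)
  dets <- detections(a, b, c)
  rec <- local_density(nucleus_morphometrics(dets, matrix(0, 80, 80)), 100)
  expect_equal(ios_masks(b, c), 0)
  e <- build_cluster_graph(dets, rec)
  pairs <- paste(e$from, e$to)
  expect_true("1 2" %in% pairs)
  expect_true("2 3" %in% pairs)
  expect_false("1 3" %in% pairs)
})

test_that("cluster ids are connected components; isolated nuclei get id 0", {
  recs <- tibble::tibble(id = 1:5, x = c(10, 20, 30, 200, 300),
                         y = c(10, 10, 10, 10, 10), area = 100)
  none <- tibble::tibble(from = integer(), to = integer())
  expect_equal(assign_cluster_ids(none, recs)$cluster_id, rep(0L, 5))
  chain <- tibble::tibble(from = c(1L, 2L), to = c(2L, 3L))
  out <- assign_cluster_ids(chain, recs)
  expect_equal(out$cluster_id, c(1L, 1L, 1L, 0L, 0L))
  # random graphs match the brute-force transitive closure
  set.seed(17)
  for (rep in 1:10) {
    n <- 20
    link <- matrix(FALSE, n, n)
    picks <- which(upper.tri(link))[sample(n * (n - 1) / 2, 15)]
    link[picks] <- TRUE
    link <- link | t(link)
    ij <- which(link & upper.tri(link), arr.ind = TRUE)
    edges <- tibble::tibble(from = as.integer(ij[, 1]), to = as.integer(ij[, 2]))
    recs_n <- tibble::tibble(id = 1:n, x = runif(n, 0, 100), y = runif(n, 0, 100),
                             area = 50)
    got <- assign_cluster_ids(edges, recs_n)$cluster_id
    want <- closure_components(link)
    # same partition: ids 0 for singletons, matching groups otherwise
    for (cc in unique(want)) {
      members <- which(want == cc)
      if (length(members) == 1) expect_equal(got[members], 0L)
      else expect_length(unique(got[members]), 1)
    }
    # distinct components get distinct nonzero ids
    nonzero <- got[got > 0]
    expect_equal(length(unique(nonzero)),
                 sum(table(want) >= 2))
  }
})

test_that("cluster numbering follows the topmost-then-leftmost member", {
  recs <- tibble::tibble(id = 1:4, x = c(100, 110, 10, 20),
                         y = c(50, 55, 80, 85), area = 100)
  edges <- tibble::tibble(from = c(1L, 3L), to = c(2L, 4L))
  out <- assign_cluster_ids(edges, recs)
  expect_equal(out$cluster_id, c(1L, 1L, 2L, 2L)) # y=50 group first
})

test_that("cluster aggregates: counts, union areas, ratios", {
  sq <- function(x0, id) detection_row(instance_mask(matrix(TRUE, 10, 10), x0, 0),
                                       id = id)
  dets <- detections(sq(0, 1), sq(20, 2), sq(25, 3), sq(200, 4))
  recs <- tibble::tibble(id = 1:4, cluster_id = c(1L, 1L, 1L, 0L),
                         x = c(5, 25, 30, 205), y = 5, area = 100)
  agg <- cluster_aggregates(recs, dets, 400, 400)
  expect_equal(agg$n_nuclei, 3L)
  # members at x0 0, 20, 25: squares 2 and 3 overlap by 5 px -> union 250
  expect_equal(agg$total_area, 100 + 150)
  expect_equal(agg$count_ratio, 0.75)
  expect_equal(agg$area_ratio, 250 / 160000)
  empty <- cluster_aggregates(recs[recs$cluster_id == 99, ], dets[0, ], 400, 400)
  expect_equal(nrow(empty), 0)
})

test_that("image summary conserves counts and measures union coverage", {
  none <- image_summary(tibble::tibble(id = integer(), cluster_id = integer()),
                        detections(), 400, 400)
  expect_equal(none$n_nuclei, 0)
  expect_equal(none$relative_area, 0)
  one <- detection_row(instance_mask(matrix(TRUE, 10, 10), 5, 5))
  s <- image_summary(tibble::tibble(id = 1L, cluster_id = 0L), one, 400, 400)
  expect_equal(s$relative_area, 100 / 160000)
  expect_equal(s$n_isolated, 1)
})

test_that("full clustering equals the brute-force pairwise rule on random scenes", {
  for (seed in c(3, 21)) {
    sc <- synthesize_scene(scene_spec(width = 640, height = 640, n_nuclei = 24,
                                      cluster_fraction = 0.5, noise_sd = 0,
                                      blur_sigma = 0, seed = seed))
    dets <- coco_to_detections(sc$gt)
    ana <- analyze_detections(dets, sc$image)
    n <- nrow(dets)
    # brute-force link matrix from the published rule
    rec <- ana$nuclei
    r <- equivalent_radius(rec$area)
    link <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ov <- ios_masks(dets[i, ], dets[j, ]) > 0.02
        d <- sqrt((rec$x[i] - rec$x[j])^2 + (rec$y[i] - rec$y[j])^2)
        t_ij <- adaptive_distance_threshold(
          r[i], r[j], mean(c(rec$local_density[i], rec$local_density[j])))
        link[i, j] <- link[j, i] <- ov || d <= t_ij
      }
    }
    want <- closure_components(link)
    got <- rec$cluster_id
    for (cc in unique(want)) {
      members <- which(want == cc)
      if (length(members) == 1) expect_equal(got[members], 0L)
      else expect_length(unique(got[members]), 1)
    }
    # partition property: isolated + clustered = total
    expect_equal(sum(ana$clusters$n_nuclei) + ana$summary$n_isolated,
                 ana$summary$n_nuclei)
    expect_true(all(ana$clusters$count_ratio > 0 & ana$clusters$count_ratio <= 1))
    expect_true(all(ana$clusters$n_nuclei >= 2))
  }
})
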