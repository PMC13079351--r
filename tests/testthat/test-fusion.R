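square_det <- function(x0, y0, side = 10, score = 0.99, id = 1L,
                       frame = "global") {
  detection_row(instance_mask(matrix(TRUE, side, side), x0, y0),
                score = score, id = id, frame = frame)
}

test_that("score filtering keeps the boundary and preserves order", {
  d <- detections(square_det(0, 0, score = 0.99, id = 1),
                  square_det(20, 0, score = 0.97, id = 2),
                  square_det(40, 0, score = 0.98, id = 3))
  kept <- filter_by_score(d, 0.98)
  expect_equal(kept$id, c(1L, 3L)) # 0.98 itself survives ("below" is dropped)
  expect_equal(nrow(filter_by_score(detections(), 0.98)), 0)
})

test_that("NMS keeps the top-scoring of overlapping boxes and all disjoint ones", {
  dup <- detections(square_det(0, 0, score = 0.985, id = 1),
                    square_det(0, 0, score = 0.99, id = 2))
  expect_equal(nms(dup, 0.5)$id, 2L)
  disj <- detections(square_det(0, 0, id = 1), square_det(50, 0, id = 2),
                     square_det(100, 0, id = 3))
  expect_equal(sort(nms(disj, 0.5)$id), 1:3)
})

test_that("greedy NMS resolves suppression chains as hand-simulated", {
  # A-B IoU 0.6, B-C IoU 0.6, A-C 0: A suppresses B; C survives
  a <- square_det(0, 0, side = 20, score = 0.99, id = 1)
  b <- square_det(5, 0, side = 20, score = 0.98, id = 2)   # IoU 15/25 = 0.6
  c <- square_det(10, 0, side = 20, score = 0.97, id = 3)  # b-c 0.6, a-c 10/30 = 1/3
  expect_equal(sort(nms(detections(a, b, c), 0.5)$id), c(1L, 3L))
})

test_that("NMM merges duplicates, respects the threshold, and collapses chains", {
  # exact duplicate from two tiles
  two <- detections(square_det(100, 100, score = 0.99, id = 1),
                    square_det(100, 100, score = 0.995, id = 2))
  m <- nmm_merge(two, 0.5)
  expect_equal(nrow(m), 1)
  expect_equal(sum(m$mask[[1]]), 100)
  expect_equal(m$score, 0.995)
  # IoS 0.4 stays separate
  low <- detections(square_det(0, 0, id = 1), square_det(6, 0, id = 2))
  expect_equal(nrow(nmm_merge(low, 0.5)), 2)
  # chain: A covers 50% of B, (A u B) covers 50% of C but A alone does not
  a <- square_det(0, 0, side = 10, score = 0.99, id = 1)
  b <- square_det(5, 0, side = 10, score = 0.98, id = 2)   # IoS(a,b) = 0.5
  c <- square_det(10, 0, side = 10, score = 0.97, id = 3)  # IoS(a u b, c) = 0.5
  merged <- nmm_merge(detections(a, b, c), 0.5)
  expect_equal(nrow(merged), 1)
  expect_equal(sum(merged$mask[[1]]), 200) # union of [0,20) x [0,10)
  # single-pass mode does not re-test the grown survivor
  expect_equal(nrow(nmm_merge(detections(a, b, c), 0.5, single_pass = TRUE)), 2)
})

test_that("NMM is idempotent, never increases counts, and conserves union area", {
  set.seed(31)
  for (rep in 1:5) {
    dets <- detections(purrr::map(1:12, function(i) {
      square_det(sample(0:80, 1), sample(0:80, 1), side = sample(6:14, 1),
                 score = runif(1, 0.5, 1), id = i)
    }))
    m1 <- nmm_merge(dets, 0.5)
    m2 <- nmm_merge(m1, 0.5)
    expect_lte(nrow(m1), nrow(dets))
    expect_equal(nrow(m2), nrow(m1))
    expect_equal(union_area(m1, 120, 120), union_area(dets, 120, 120))
    expect_equal(union_area(m2, 120, 120), union_area(m1, 120, 120))
    # merged output does not depend on input row order
    m3 <- nmm_merge(dets[sample(nrow(dets)), ], 0.5)
    expect_equal(dplyr::arrange(m3, x0, y0)[c("x0", "y0", "x1", "y1")],
                 dplyr::arrange(m1, x0, y0)[c("x0", "y0", "x1", "y1")])
  }
})

test_that("reconstruction fuses a border-straddling nucleus into one instance", {
  sc <- clean_scene(n = 6, seed = 13, wh = 512)
  grid <- tile_grid(512, 512, 200, 0.2)
  tiles <- slice_image(sc$image, grid)
  fused <- reconstruct_predictions(lapply(tiles$pixels, toy_detector), grid,
                                   fusion_config(score_threshold = 0.5))
  expect_equal(nrow(fused), nrow(sc$gt$annotations))
  stages <- attr(fused, "stage_counts")
  expect_true(all(diff(unname(stages)) <= 0)) # monotone along the chain
  # running the merge again changes nothing
  expect_equal(nrow(nmm_merge(fused, 0.5)), nrow(fused))
})

test_that("detections wholly inside non-overlap regions pass through unchanged", {
  grid <- tile_grid(512, 512, 200, 0.2)
  # one detection in the interior of the first tile, none elsewhere
  tile_dets <- c(list(detections(square_det(50, 50, score = 0.99, frame = "tile"))),
                 rep(list(detections()), nrow(grid) - 1))
  out <- reconstruct_predictions(tile_dets, grid, fusion_config())
  expect_equal(nrow(out), 1)
  expect_equal(c(out$x0, out$y0), c(50, 50))
  expect_equal(sum(out$mask[[1]]), 100)
})

test_that("the backend registry resolves names and rejects unknown ones", {
  b <- get_backend("toy-threshold")
  expect_true(is.function(b$detect))
  expect_equal(b$default_score_threshold, 0.5)
  expect_error(get_backend("resnet-101-dc5"), "unknown detector backend")
})
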