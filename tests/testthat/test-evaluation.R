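test_that("per-tile statistics count and measure as specified", {
  gt <- slice_annotations(clean_scene(n = 10, seed = 43, wh = 512)$gt,
                          tile_size = 256, overlap_fraction = 0.2)
  ts <- per_tile_stats(gt, gt)
  expect_true(all(ts$pred_count == ts$gt_count))
  expect_true(all(ts$pred_rel_area == ts$gt_rel_area))
  expect_true(all(ts$gt_rel_area >= 0 & ts$gt_rel_area <= 1))
  # conservation: per-tile counts sum to the sliced dataset's annotations
  expect_equal(sum(ts$gt_count), nrow(gt$annotations))
  g <- glance(ts)
  expect_equal(g$mean_gt_count, mean(ts$gt_count))
  expect_equal(g$median_gt_count, stats::median(ts$gt_count))
})

test_that("relative area uses the mask union over the tile area", {
  # one 40x40 = 1600 px^2 square on a 400x400 tile -> 0.01
  m <- instance_mask(matrix(TRUE, 40, 40), 100, 100)
  ds <- coco_dataset(
    images = tibble::tibble(id = 1L, file_name = "t.tiff",
                            width = 400L, height = 400L),
    annotations = fibernuclei:::mask_to_annotation(m, 1, 1))
  ts <- per_tile_stats(ds, ds)
  expect_equal(ts$gt_rel_area, 0.01)
  # mean/median arithmetic on counts {7, 9}
  expect_equal(mean(c(7, 9)), 8)
  two <- tibble::tibble(gt_count = c(7L, 9L))
  expect_equal(stats::median(two$gt_count), 8)
})

test_that("Mann-Whitney U: exact enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1) # 2/20 orderings as extreme
  # identical samples: p = 1
  expect_equal(mann_whitney_u(c(5, 5, 7), c(5, 5, 7))$p_value, 1)
  # symmetry under swapping samples
  a <- c(3, 9, 1, 7); b <- c(2, 8, 8)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("exact mode matches full enumeration for n <= 7, including ties", {
  set.seed(53)
  for (rep in 1:12) {
    n_a <- sample(2:7, 1); n_b <- sample(2:7, 1)
    # integer draws force ties regularly
    a <- sample(1:6, n_a, replace = TRUE)
    b <- sample(1:6, n_b, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_mwu_p(a, b))
  }
  # and matches wilcox.test exactly when there are no ties
  for (rep in 1:6) {
    a <- sample(1:100, 6); b <- setdiff(sample(1:100, 12), a)[1:6]
    w <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value, w$p.value)
    expect_equal(mann_whitney_u(a, b)$u, unname(w$statistic))
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(59)
  a <- round(rnorm(40, 10, 2)); b <- round(rnorm(35, 11, 2))
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(got$u, unname(ref$statistic))
  expect_match(got$method, "normal approximation")
})

test_that("relative deviation reproduces the expert-comparison values", {
  expect_equal(relative_deviation(82, 93), 11.8)
  expect_equal(relative_deviation(39, 43), 9.3)
  expect_equal(relative_deviation(15, 43), 65.1)
  expect_equal(relative_deviation(72, 43), 67.4)
  expect_equal(relative_deviation(57, 57), 0)
  expect_error(relative_deviation(10, 0), "> 0")
})

test_that("AP at IoU 0.5 handles the canonical cases", {
  sq <- function(x0, score, id) detection_row(
    instance_mask(matrix(TRUE, 10, 10), x0, 0), score = score, id = id)
  gt <- detections(sq(0, 1, 1))
  # a perfect prediction set scores 100 regardless of scores
  expect_equal(ap_at_iou(detections(sq(0, 0.3, 1)), gt)$ap, 100)
  # no predictions at all: AP 0
  expect_equal(ap_at_iou(detections(), gt)$ap, 0)
  # non-matching at 0.9 then matching at 0.8: hand-computed AP = 50
  preds <- detections(sq(500, 0.9, 1), sq(0, 0.8, 2))
  expect_equal(ap_at_iou(preds, gt)$ap, 50)
  # no ground truth: undefined
  expect_true(is.na(ap_at_iou(preds, detections())$ap))
  # mask mode on identical instances
  expect_equal(ap_at_iou(detections(sq(0, 0.9, 1)), gt, match_on = "mask")$ap, 100)
})

test_that("AP matches an independent evaluator on random instance sets", {
  set.seed(61)
  for (rep in 1:15) {
    n_gt <- sample(1:6, 1); n_pred <- sample(1:10, 1)
    gt_rows <- purrr::map(seq_len(n_gt), function(i) {
      x0 <- sample(0:90, 1); y0 <- sample(0:90, 1); s <- sample(8:14, 1)
      detection_row(instance_mask(matrix(TRUE, s, s), x0, y0), score = 1, id = i)
    })
    pred_rows <- purrr::map(seq_len(n_pred), function(i) {
      x0 <- sample(0:90, 1); y0 <- sample(0:90, 1); s <- sample(8:14, 1)
      detection_row(instance_mask(matrix(TRUE, s, s), x0, y0),
                    score = runif(1), id = i)
    })
    gt <- detections(gt_rows); pred <- detections(pred_rows)
    got <- ap_at_iou(pred, gt)$ap
    want <- oracle_ap(as.matrix(pred[, c("x0", "y0", "x1", "y1")]), pred$score,
                      as.matrix(gt[, c("x0", "y0", "x1", "y1")]))
    expect_equal(got, want)
  }
})
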