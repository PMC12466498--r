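# Evaluation stack: IoU, matching, P/R/F1, AP, mAP, radar normalisation, plus
# equivalence with the independent brute-force evaluator.

test_that("iou handles identity, disjoint and partial overlap", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching follows the confidence order with one-to-one gts", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  p1 <- cbind(0, 0, 10, 8, 0.9)         # IoU 0.8
  expect_identical(match_detections(p1, gt, 0.5)[c("TP", "FP", "FN")],
                   list(TP = 1L, FP = 0L, FN = 0L))
  p2 <- cbind(0, 0, 10, 4, 0.9)         # IoU 0.4
  expect_identical(match_detections(p2, gt, 0.5)[c("TP", "FP", "FN")],
                   list(TP = 0L, FP = 1L, FN = 1L))
  # two predictions on one gt: the higher-confidence one wins regardless of
  # input row order (exhaustive over both orders)
  for (ord in list(1:2, 2:1)) {
    p <- rbind(c(0, 0, 10, 10, 0.6), c(0, 0, 10, 9, 0.8))[ord, ]
    mc <- match_detections(p, gt, 0.5)
    expect_identical(mc$TP, 1L)
    expect_identical(mc$FP, 1L)
    expect_true(mc$hits[which(p[, 5] == 0.8)])
  }
})

test_that("precision/recall and F1 reproduce the worked fraction arithmetic", {
  expect_equal(precision_recall(list(TP = 1, FP = 0, FN = 0)), c(P = 100, R = 100))
  expect_equal(precision_recall(list(TP = 0, FP = 5, FN = 5)), c(P = 0, R = 0))
  expect_equal(precision_recall(list(TP = 3, FP = 1, FN = 2)), c(P = 75, R = 60))
  expect_equal(f1_score(75, 60), 2 * 75 * 60 / 135)
  expect_equal(f1_score(42.5, 42.5), 42.5)   # harmonic-mean fixed point
  expect_equal(f1_score(0, 0), 0)
})

test_that("average precision matches the hand-built staircase", {
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 2), 0)
  expect_error(average_precision(TRUE, 0), "undefined")
  # 1 TP then 1 FP with 2 gts: precision envelope is 1 up to recall 0.5, then
  # the curve ends; 101-point mean = 51/101
  expect_equal(average_precision(c(TRUE, FALSE), 2), 51 / 101)
  # all-point integration of the same curve: 0.5 * 1
  expect_equal(average_precision(c(TRUE, FALSE), 2, interpolation = "all"), 0.5)
})

test_that("map_metrics: perfect predictions, empty predictions, threshold grid", {
  gts <- list(matrix(c(0, 0, 10, 10, 20, 20, 30, 30), 2, 4, byrow = TRUE))
  perfect <- list(cbind(gts[[1]], conf = c(0.9, 0.8)))
  m <- map_metrics(perfect, gts)
  expect_equal(m$mAP50, 100)
  expect_equal(m$mAP50_95, 100)
  expect_length(m$ap_per_threshold, 10)

  none <- list(matrix(numeric(0), 0, 5))
  m0 <- map_metrics(none, gts)
  expect_equal(m0$R, 0)
  expect_equal(m0$mAP50, 0)

  # jittered boxes: high-threshold APs fall away
  jit <- list(cbind(gts[[1]] + c(1.2, 1.2, -0.6, -0.6), conf = c(0.9, 0.8)))
  mj <- map_metrics(jit, gts)
  expect_lt(mj$mAP50_95, mj$mAP50)
})

test_that("the pipeline agrees with an independent evaluator on random instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    ours <- cd("ap_at_threshold")(inst$preds, inst$gts, 0.5, interpolation = "all")
    ref <- oracle_ap(inst$preds, inst$gts, 0.5)
    if (is.na(ref)) {
      expect_true(is.na(ours))
    } else {
      expect_equal(ours, ref, tolerance = 1e-10, info = paste("seed", seed))
    }
    # 101-point interpolation within interpolation tolerance of all-point
    ours101 <- cd("ap_at_threshold")(inst$preds, inst$gts, 0.5, interpolation = "101")
    if (!is.na(ref)) expect_lt(abs(ours101 - ref), 0.05)
  }
})

test_that("mAP is non-increasing in the IoU threshold", {
  inst <- random_instance(99)
  aps <- sapply(seq(0.5, 0.95, 0.05), function(t) {
    cd("ap_at_threshold")(inst$preds, inst$gts, t)
  })
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("radar normalisation and polygon area follow the published scheme", {
  expect_equal(max(normalize_metric(c(85, 90, 88), "positive")), 1)
  expect_equal(normalize_metric(c(85, 90, 88), "positive")[2], 1)
  v <- normalize_metric(c(6.3, 9.0, 21.3), "negative")
  expect_equal(v[1], 1)                       # minimum is best
  expect_equal(v[2], (log10(21.3) - log10(9)) / (log10(21.3) - log10(6.3)),
               tolerance = 1e-12)
  expect_equal(normalize_metric(c(5, 5, 5), "positive"), c(1, 1, 1))
  expect_error(normalize_metric(c(-1, 2), "negative"), "positive")

  expect_equal(radar_polygon_area(rep(0, 5)), 0)
  expect_equal(radar_polygon_area(rep(1, 5)), 2.5 * sin(2 * pi / 5))
  v5 <- runif(5)
  expect_equal(radar_polygon_area(0.5 * v5), 0.25 * radar_polygon_area(v5))
  expect_error(radar_polygon_area(c(1, 1)), "at least 3")
})
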