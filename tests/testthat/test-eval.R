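test_that("size classes split on equivalent-square area with medium-inclusive bounds", {
  b <- function(side) boundingBoxes(0, 0, side, side)
  expect_equal(as.character(classifySize(b(20))), "small")    # 400 px^2
  expect_equal(as.character(classifySize(b(30))), "medium")   # 900 px^2
  expect_equal(as.character(classifySize(b(22))), "medium")   # boundary
  expect_equal(as.character(classifySize(b(34))), "medium")   # boundary
  expect_equal(as.character(classifySize(b(35))), "large")
  rect <- boundingBoxes(0, 0, 44, 11)            # 484 px^2 but elongated
  expect_equal(as.character(classifySize(rect)), "medium")
})

test_that("greedy matching claims each ground truth once, best IoU first", {
  gt <- boundingBoxes(0, 0, 10, 10)
  det <- gt; det$score <- 0.9
  m <- matchDetections(det, gt, 0.99)
  expect_equal(sum(m$tp), 1)
  expect_equal(m$fn_count, 0)

  two <- rbind(det, det); two$score <- c(0.7, 0.9)
  m2 <- matchDetections(two, gt, 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))            # higher score claims first
  expect_equal(m2$order, c(2L, 1L))
})

test_that("matching agrees with the exhaustive reference on random instances", {
  set.seed(41)
  for (rep in 1:25) {
    det <- randomBoxes(20, W = 80, H = 80)
    gt <- randomBoxes(15, W = 80, H = 80, scored = FALSE)
    thr <- sample(c(0.3, 0.5, 0.75), 1)
    m <- matchDetections(det, gt, thr)
    ref <- refMatch(det, gt, thr)
    expect_equal(m$tp, ref$tp)
    expect_equal(m$fn_count, ref$fn)
    expect_equal(sum(m$tp) + m$fn_count, nrow(gt))  # TP + FN = GT
  }
})

test_that("PR curves accumulate Precision = TP/(TP+FP) and Recall = TP/(TP+FN) prefix-wise", {
  pr <- prCurve(c(TRUE, TRUE, TRUE), 3)
  expect_equal(pr$precision, c(1, 1, 1))
  expect_equal(pr$recall, c(1 / 3, 2 / 3, 1))

  pr2 <- prCurve(c(FALSE, TRUE), 1)              # FP at 0.9 then TP at 0.8
  expect_equal(pr2$recall, c(0, 1))
  expect_equal(pr2$precision, c(0, 0.5))
  expect_equal(averagePrecision(pr2), 0.5)
  expect_equal(averagePrecision(pr2, "pascal_continuous"), 0.5)

  expect_error(prCurve(logical(), 0), "undefined")
  expect_equal(averagePrecision(prCurve(logical(), 5)), 0)

  set.seed(13)
  for (rep in 1:10) {                             # Eqs hold on every prefix
    tp <- runif(12) > 0.5
    pr <- prCurve(tp, 12)
    k <- seq_along(tp)
    expect_equal(pr$precision, cumsum(tp) / k)
    expect_equal(pr$recall, cumsum(tp) / 12)
  }
})

test_that("AP is score-scale invariant and 1 for a perfect detector", {
  gt <- randomBoxes(6, scored = FALSE)
  det <- gt; det$score <- seq(0.9, 0.4, length.out = 6)
  e <- evaluateDetections(det, gt, iouThresholds = 0.5, sizeBreaks = NULL)
  expect_equal(e$ap, 1.0)
  det2 <- det; det2$score <- det$score / 2       # same order, halved scores
  e2 <- evaluateDetections(det2, gt, iouThresholds = 0.5, sizeBreaks = NULL)
  expect_equal(e2$ap, e$ap)
})

test_that("AP agrees with the independent reference within 1e-6", {
  set.seed(57)
  for (rep in 1:20) {
    det <- randomBoxes(15, W = 70, H = 70)
    gt <- randomBoxes(10, W = 70, H = 70, scored = FALSE)
    thr <- sample(c(0.5, 0.75), 1)
    e <- evaluateDetections(det, gt, iouThresholds = thr, sizeBreaks = NULL)
    expect_equal(e$ap, refAP(det, gt, thr), tolerance = 1e-6)
  }
})

test_that("tighter IoU thresholds never increase AP", {
  set.seed(71)
  for (rep in 1:100) {
    det <- randomBoxes(12, W = 60, H = 60)
    gt <- randomBoxes(8, W = 60, H = 60, scored = FALSE)
    e <- evaluateDetections(det, gt, iouThresholds = c(0.5, 0.75),
                            sizeBreaks = NULL)
    expect_lte(e$ap[e$iou_threshold == 0.75], e$ap[e$iou_threshold == 0.5])
  }
})

test_that("removing a false positive never decreases AP", {
  set.seed(83)
  for (rep in 1:10) {
    det <- randomBoxes(12, W = 60, H = 60)
    gt <- randomBoxes(8, W = 60, H = 60, scored = FALSE)
    m <- matchDetections(det, gt, 0.5)
    fpRows <- m$order[!m$tp]
    if (!length(fpRows)) next
    apFull <- evaluateDetections(det, gt, 0.5, NULL)$ap
    apLess <- evaluateDetections(det[-fpRows[1], ], gt, 0.5, NULL)$ap
    expect_gte(apLess, apFull)
  }
})

test_that("stratified evaluation ignores out-of-class objects instead of penalising them", {
  # small GT (10x10 = 100 px^2) and large GT (50x50)
  gt <- boundingBoxes(c(0, 100), c(0, 100), c(10, 150), c(10, 150))
  det <- gt; det$score <- c(0.9, 0.8)
  e <- evaluateDetections(det, gt)
  expect_equal(e$ap[e$size_class == "small"], 1)
  expect_equal(e$ap[e$size_class == "large"], 1)
  expect_true(is.na(e$ap[e$size_class == "medium"]))  # no medium objects
  expect_equal(e$n_gt[e$size_class == "small"], 1)

  # a large FP must not hurt the small stratum
  det2 <- rbind(det, boundingBoxes(300, 300, 360, 360, score = 0.95))
  e2 <- evaluateDetections(det2, gt)
  expect_equal(e2$ap[e2$size_class == "small"], 1)
  expect_lt(e2$ap[e2$iou_threshold == 0.5 & e2$size_class == "all"], 1)
})

test_that("detection rate reflects controlled ground-truth dropout exactly", {
  set.seed(97)
  gt <- randomBoxes(20, W = 300, H = 300, scored = FALSE)
  det <- gt[1:16, ]                              # drop 20% of objects
  det$score <- runif(16, 0.5, 1)
  e <- evaluateDetections(det, gt, iouThresholds = 0.5, sizeBreaks = NULL)
  expect_equal(e$detection_rate, 0.8)
})

test_that("multi-image evaluation routes boxes by image id and rejects unknown ids", {
  gt <- boundingBoxes(c(0, 0), c(0, 0), c(20, 20), c(20, 20),
                      image_id = c("a", "b"))
  det <- gt; det$score <- 0.9
  e <- evaluateDetections(det, gt, iouThresholds = 0.5, sizeBreaks = NULL)
  expect_equal(e$ap, 1)
  det$image_id <- c("a", "zzz")
  expect_error(evaluateDetections(det, gt), "zzz")
})
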