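test_that("corner tiling anchors one tile at each image vertex", {
  s <- cornerTiles(c(1280, 720), c(640, 360))
  expect_equal(tileOffsets(s),
               rbind(c(0, 0), c(640, 0), c(0, 360), c(640, 360)),
               ignore_attr = TRUE)
  expect_true(s@coverage)

  s2 <- cornerTiles(c(1280, 720), c(960, 540))
  expect_equal(tileOffsets(s2),
               rbind(c(0, 0), c(320, 0), c(0, 180), c(320, 180)),
               ignore_attr = TRUE)

  expect_warning(s3 <- cornerTiles(c(1280, 720), c(320, 180)), "not cover")
  expect_false(s3@coverage)
  expect_equal(nTiles(s3), 4)
  expect_error(cornerTiles(c(100, 100), c(200, 50)), "exceeds")
})

pixelCoverage <- function(spec) {
  W <- spec@imageSize[1]; H <- spec@imageSize[2]
  hit <- matrix(FALSE, H, W)
  off <- tileOffsets(spec); w <- spec@tileSize
  for (i in seq_len(nrow(off)))
    hit[(off[i, 2] + 1):(off[i, 2] + w[2]),
        (off[i, 1] + 1):(off[i, 1] + w[1])] <- TRUE
  all(hit)
}

test_that("half-size corner tiles partition the image exactly", {
  s <- cornerTiles(c(64, 48), c(32, 24))
  hit <- matrix(0L, 48, 64)
  off <- tileOffsets(s)
  for (i in 1:4)
    hit[(off[i, 2] + 1):(off[i, 2] + 24), (off[i, 1] + 1):(off[i, 1] + 32)] <-
      hit[(off[i, 2] + 1):(off[i, 2] + 24), (off[i, 1] + 1):(off[i, 1] + 32)] + 1L
  expect_true(all(hit == 1L))                    # every pixel in exactly one tile
})

test_that("grid tiling covers every pixel for any valid overlap", {
  expect_equal(tileOffsets(gridTiles(c(1280, 720), c(640, 360), c(0, 0))),
               tileOffsets(cornerTiles(c(1280, 720), c(640, 360))),
               ignore_attr = TRUE)
  g <- gridTiles(c(1280, 720), c(320, 180), c(40, 40))
  expect_true(pixelCoverage(g))
  set.seed(19)
  for (rep in 1:15) {
    ts <- c(sample(8:30, 1), sample(8:30, 1))
    ov <- c(sample(0:(ts[1] - 1), 1), sample(0:(ts[2] - 1), 1))
    expect_true(pixelCoverage(gridTiles(c(97, 61), ts, ov)))
  }
  expect_error(gridTiles(c(100, 100), c(20, 20), c(20, 5)), "stride")
})

test_that("overlap at least the object extent keeps every box whole in some tile", {
  set.seed(23)
  for (rep in 1:5) {
    gt <- randomBoxes(12, W = 200, H = 150, minSide = 5, maxSide = 18,
                      scored = FALSE)
    maxExt <- ceiling(max(boxWidth(gt), boxHeight(gt)))
    g <- gridTiles(c(200, 150), c(50, 50), c(maxExt, maxExt))
    off <- tileOffsets(g)
    inside <- vapply(seq_len(nrow(gt)), function(i) {
      any(vapply(seq_len(nrow(off)), function(t)
        gt$x_min[i] >= off[t, 1] & gt$x_max[i] <= off[t, 1] + 50 &
        gt$y_min[i] >= off[t, 2] & gt$y_max[i] <= off[t, 2] + 50,
        logical(1)))
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("ground-truth transfer clips, filters by retained area, and translates", {
  gt <- boundingBoxes(c(10, 28, 50), c(10, 10, 50), c(20, 38, 60),
                      c(20, 20, 60))
  # tile [0,32) x [0,32): box2 has 4/10 of width inside -> 40% retained
  out <- transferGroundTruth(gt, c(0, 0), c(32, 32), 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$x_min, 10)                    # fully inside: shifted by -0
  all3 <- transferGroundTruth(gt, c(0, 0), c(32, 32), 1e-9)
  expect_equal(nrow(all3), 2)                    # box3 misses the tile entirely
  sh <- transferGroundTruth(gt[1, ], c(5, 8), c(32, 32), 0.5)
  expect_equal(c(sh$x_min, sh$y_min), c(5, 2))
})

test_that("mapping tile detections back is the inverse of transfer for interior boxes", {
  s <- cornerTiles(c(1280, 720), c(640, 360))
  d <- boundingBoxes(10, 10, 20, 20, score = 0.9)
  mapped <- mapToOriginal(list(NULL, NULL, NULL, d), s)
  expect_equal(c(mapped$x_min, mapped$y_min, mapped$x_max, mapped$y_max),
               c(650, 370, 660, 380))
  expect_equal(nrow(mapToOriginal(list(NULL, NULL, NULL, NULL), s)), 0)

  gt <- boundingBoxes(660, 400, 700, 430, score = 0.5)
  tile4 <- transferGroundTruth(gt, c(640, 360), c(640, 360), 0.5)
  back <- mapToOriginal(list(NULL, NULL, NULL, tile4), s)
  expect_equal(back[c("x_min", "y_min", "x_max", "y_max")],
               gt[c("x_min", "y_min", "x_max", "y_max")])
})

test_that("NMS keeps the top-scored of duplicates and all disjoint boxes", {
  dup <- boundingBoxes(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                       score = c(0.9, 0.8))
  expect_equal(mergeDetections(dup, 0.5)$score, 0.9)
  far <- boundingBoxes(c(0, 50), c(0, 50), c(10, 60), c(10, 60),
                       score = c(0.3, 0.9))
  expect_equal(nrow(mergeDetections(far, 0.5)), 2)
})

test_that("NMS equals the reference oracle on randomised 50-box sets and is idempotent", {
  set.seed(31)
  for (rep in 1:8) {
    b <- randomBoxes(50, W = 120, H = 90)
    thr <- runif(1, 0.2, 0.7)
    got <- mergeDetections(b, thr)
    want <- refNms(b, thr)
    expect_equal(got[c("x_min", "y_min", "x_max", "y_max", "score")],
                 want[c("x_min", "y_min", "x_max", "y_max", "score")])
    expect_equal(mergeDetections(got, thr), got)   # idempotent
    m <- iouMatrix(got, got); diag(m) <- 0
    expect_true(all(m < thr))                      # antichain under IoU
  }
})
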