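test_that("per-object error and error rate follow the printed-table arithmetic", {
  expect_equal(unlist(scoreObject(33.64, 31.57)),
               c(error_mm = 2.07, error_rate_pct = 6.15))
  expect_equal(unlist(scoreObject(34.55, 27.03)),
               c(error_mm = 7.52, error_rate_pct = 21.77))
  expect_equal(unlist(scoreObject(30, 30)), c(error_mm = 0, error_rate_pct = 0))
  expect_error(scoreObject(0, 10), "positive")
})

test_that("bundled verification tables reconstruct their printed error columns", {
  for (setting in c("indoor", "outdoor")) {
    tab <- verificationTable(setting)
    sc <- scoreObject(tab$measured_mm, tab$predicted_mm)
    expect_true(all(abs(sc$error_mm - tab$error_mm) <= 0.01))
    expect_true(all(abs(sc$error_rate_pct - tab$error_rate_pct) <= 0.01))
  }
})

test_that("class summaries reproduce the printed average rows to within 0.01", {
  indoor <- verificationTable("indoor")
  outdoor <- verificationTable("outdoor")
  avg <- function(tab, cls) summarizeClass(tab[tab$size_class == cls, ])
  chk <- function(s, meas, pred, err, rate) {
    expect_equal(s$mean_measured_mm, meas, tolerance = 0.011)
    expect_equal(s$mean_predicted_mm, pred, tolerance = 0.011)
    expect_equal(s$mean_error_mm, err, tolerance = 0.011)
    expect_equal(s$mean_error_rate_pct, rate, tolerance = 0.011)
  }
  chk(avg(indoor, "medium"), 34.94, 34.47, 2.05, 5.90)
  chk(avg(indoor, "large"), 35.08, 36.22, 1.97, 5.66)
  chk(avg(outdoor, "small"), 28.06, 24.96, 3.10, 11.26)
  chk(avg(outdoor, "medium"), 26.80, 25.28, 2.01, 7.44)
  chk(avg(outdoor, "large"), 29.74, 28.20, 1.92, 6.27)
})

test_that("the error rate is the mean of per-object rates, not the ratio of means", {
  rec <- data.frame(measured_mm = c(10, 40), predicted_mm = c(8, 36))
  s <- summarizeClass(rec)
  expect_equal(s$mean_error_rate_pct, mean(c(20, 10)))       # 15
  wrong <- 100 * abs(mean(rec$measured_mm) - mean(rec$predicted_mm)) /
    mean(rec$measured_mm)                                    # 12
  expect_false(isTRUE(all.equal(s$mean_error_rate_pct, wrong)))
})

test_that("a single detected record summarises to itself; undetected rows only count in rates", {
  one <- data.frame(measured_mm = 34.5, predicted_mm = 33.1)
  s <- summarizeClass(one)
  expect_equal(s$mean_measured_mm, 34.5)
  expect_equal(s$mean_error_mm, 1.4)
  expect_equal(s$detection_rate_pct, 100)

  mix <- data.frame(measured_mm = c(30, 31), predicted_mm = c(29, NA))
  s2 <- summarizeClass(mix)
  expect_equal(s2$n_detected, 1L)
  expect_equal(s2$detection_rate_pct, 50)
  expect_equal(s2$mean_error_mm, 1)              # undetected row excluded
})

test_that("estimates link to caliper references by IoU with score priority", {
  ref <- data.frame(object_id = 1:3,
                    x_min = c(0, 40, 80), y_min = 0,
                    x_max = c(20, 60, 100), y_max = 20,
                    measured_mm = c(30, 32, 34))
  est <- data.frame(x_min = c(1, 41), y_min = 0, x_max = c(21, 61),
                    y_max = 20, score = c(0.9, 0.8),
                    long_axis_mm = c(29.5, 33.0), valid = TRUE)
  rec <- verificationRecords(est, ref)
  expect_equal(rec$predicted_mm, c(29.5, 33.0, NA))
  expect_equal(rec$detected, c(TRUE, TRUE, FALSE))
  expect_equal(rec$error_mm[1:2], c(0.5, 1.0))

  none <- verificationRecords(est[0, ], ref)
  expect_true(all(!none$detected))
})

test_that("duplicate estimate claims resolve by score, like the reference assignment", {
  set.seed(101)
  for (rep in 1:10) {
    ref <- randomBoxes(8, W = 200, H = 200, scored = FALSE)
    ref$object_id <- 1:8
    ref$measured_mm <- runif(8, 20, 40)
    est <- ref
    # jitter boxes, duplicate some, random scores
    est <- rbind(est, est[sample(8, 3), ])
    est$x_min <- est$x_min + runif(nrow(est), -2, 2)
    est$x_max <- est$x_max + runif(nrow(est), -2, 2)
    est$score <- runif(nrow(est), 0.5, 1)
    est$long_axis_mm <- runif(nrow(est), 20, 40)
    est$valid <- TRUE
    rec <- verificationRecords(est, ref, iouThreshold = 0.5)
    m <- refMatch(est, ref, 0.5)
    expect_equal(sum(rec$detected), sum(m$tp))
  }
})

test_that("split bookkeeping turns counts into the printed percentages", {
  img <- splitBookkeeping(c(train = 431, validation = 144, test = 144))
  expect_equal(img$pct, c(59.94, 20.03, 20.03))
  obj <- splitBookkeeping(c(7940, 2391, 2442))
  expect_equal(obj$pct, c(62.16, 18.72, 19.12))
  expect_equal(splitBookkeeping(c(1, 0, 0))$pct, c(100, 0, 0))
})
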