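test_that("fruit projection follows the pinhole model in both modes", {
  cam <- cameraModel(1280, 720, focalPx = 600)
  pc <- projectFruit(c(0, 0, 600), 17, cam, "consistent")
  expect_equal(pc$radius_px, c(17, 17))
  expect_equal(pc$center_depth_mm, 600)
  expect_equal(pc$center_px, c(640, 360))

  pp <- projectFruit(c(0, 0, 600), 17, cam, "perspective")
  expect_equal(pp$radius_px[1], 600 * 17 / sqrt(600^2 - 17^2))
  expect_equal(round(pp$radius_px[1], 4), 17.0068)
  expect_equal(pp$center_depth_mm, 583)

  far <- projectFruit(c(0, 0, 1200), 17, cam, "consistent")
  expect_equal(far$radius_px, pc$radius_px / 2)  # doubling z halves the disk
  expect_error(projectFruit(c(0, 0, 10), 17, cam), "front")
})

test_that("an empty scene renders background only and rendering is seed-deterministic", {
  spec <- randomScene(nFruits = 0, camera = tinyCam(), seed = 5)
  scene <- renderScene(spec)
  expect_equal(nrow(scene$truth), 0)
  expect_true(all(depthValues(scene$depth) == spec@backgroundDepth))

  spec2 <- gridScene(4, seed = 9, noiseSigma = 4, dropout = 0.02)
  a <- renderScene(spec2); b <- renderScene(spec2)
  expect_identical(a$rgb, b$rgb)
  expect_identical(depthValues(a$depth), depthValues(b$depth))
  expect_identical(a$truth, b$truth)
})

test_that("truth conserves diameters and reports occlusion-aware visibility", {
  spec <- gridScene(4, seed = 2)
  scene <- renderScene(spec)
  expect_equal(scene$truth$true_diameter_mm, 2 * spec@fruits$radius_mm)
  expect_true(all(scene$truth$visible_fraction == 1))
  expect_true(all(scene$truth$annotated))
  # truth boxes lie inside the image
  res <- cameraResolution(spec@camera)
  expect_true(all(scene$truth$x_min >= 0 & scene$truth$x_max <= res[1]))

  # nearer fruit occludes a farther one placed on the same line of sight
  cam <- tinyCam()
  fruits <- data.frame(x_mm = c(0, 12), y_mm = 0, z_mm = c(300, 500),
                       radius_mm = 10)
  sp <- sceneSpec(fruits, camera = cam, seed = 3)
  sc <- renderScene(sp)
  expect_equal(sc$truth$visible_fraction[1], 1)
  expect_lt(sc$truth$visible_fraction[2], 1)
  expect_gt(sc$truth$visible_fraction[2], 0)
})

test_that("the annotated flag flips at half visibility", {
  cam <- tinyCam()
  fruit <- data.frame(x_mm = 0, y_mm = 0, z_mm = 400, radius_mm = 12)
  pr <- focalPx(cam)[1] * 12 / 400               # 3.6 px silhouette radius
  u <- principalPoint(cam)[1]
  occl <- function(frac) data.frame(
    shape = "rect", x_min = u - pr - 1 + 2 * (pr + 1) * (1 - frac),
    y_min = 0, x_max = u + pr + 1, y_max = cameraResolution(cam)[2],
    z_mm = 200, hue = 0.08, sat = 0.3, val = 0.4)
  mostly <- renderScene(sceneSpec(fruit, cam, occluders = occl(0.9), seed = 1))
  barely <- renderScene(sceneSpec(fruit, cam, occluders = occl(0.15), seed = 1))
  expect_false(mostly$truth$annotated)
  expect_lt(mostly$truth$visible_fraction, 0.5)
  expect_true(barely$truth$annotated)
  expect_gt(barely$truth$visible_fraction, 0.5)
})

test_that("the colour-threshold detector finds separated fruits and nothing else", {
  spec <- gridScene(6, seed = 12)
  scene <- renderScene(spec)
  det <- baselineDetect(scene$rgb)
  expect_equal(nrow(det), 6)
  ious <- iouMatrix(det, scene$truth[, c("x_min", "y_min", "x_max", "y_max")])
  expect_true(all(apply(ious, 2, max) > 0.9))

  empty <- renderScene(randomScene(nFruits = 0, camera = tinyCam(), seed = 4))
  expect_equal(nrow(baselineDetect(empty$rgb)), 0)

  # fully hidden fruit yields no detection
  cam <- tinyCam()
  fruit <- data.frame(x_mm = 0, y_mm = 0, z_mm = 400, radius_mm = 10)
  wall <- data.frame(shape = "rect", x_min = 0, y_min = 0, x_max = 128,
                     y_max = 96, z_mm = 150, hue = 0.08, sat = 0.3, val = 0.4)
  hidden <- renderScene(sceneSpec(fruit, cam, occluders = wall, seed = 6))
  expect_equal(hidden$truth$visible_px, 0L)
  expect_equal(nrow(baselineDetect(hidden$rgb)), 0)
})

test_that("consistent noiseless scenes invert to the true diameter within a pixel-equivalent", {
  cam <- cameraModel(320, 240, focalPx = 300)
  spec <- randomScene(nFruits = 8, diameterRange = c(32, 37),
                      depthRange = c(400, 700), camera = cam, seed = 21)
  rec <- endToEndRecovery(spec)
  expect_true(all(rec$detected))
  bound <- 700 / 300 + 0.5
  expect_true(all(abs(rec$predicted_mm - rec$true_diameter_mm) <= bound))
})

test_that("perspective rendering biases the linear sizing model; depth noise degrades it", {
  cam <- cameraModel(320, 240, focalPx = 300)
  args <- list(nFruits = 8, diameterRange = c(32, 37),
               depthRange = c(400, 700), camera = cam)
  err <- function(mode, sigma, seed) {
    spec <- do.call(randomScene, c(args, list(projectionMode = mode,
                                              noiseSigma = sigma,
                                              seed = seed)))
    rec <- endToEndRecovery(spec)
    mean(abs(rec$predicted_mm - rec$true_diameter_mm), na.rm = TRUE)
  }
  seeds <- 31:36
  clean <- vapply(seeds, function(s) err("consistent", 0, s), numeric(1))
  noisy <- vapply(seeds, function(s) err("consistent", 8, s), numeric(1))
  expect_gt(mean(noisy), mean(clean))            # error grows with sigma
  persp <- vapply(seeds[1:3], function(s) err("perspective", 0, s), numeric(1))
  expect_gt(mean(persp), mean(clean[1:3]))       # model bias on real spheres
})
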