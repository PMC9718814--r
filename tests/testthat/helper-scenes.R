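# small cameras and scenes shared by the tests; tiny frames keep the suite
# fast while exercising the same code paths as full-resolution sensors

tinyCam <- function(w = 128, h = 96, f = 120) cameraModel(w, h, focalPx = f)

# n fruits on a regular grid, guaranteed unoccluded, consistent mode
gridScene <- function(n = 6, cam = tinyCam(), diameter = 24, z = 300,
                      seed = 1, ...) {
  res <- cameraResolution(cam); f <- focalPx(cam); pp <- principalPoint(cam)
  cols <- ceiling(sqrt(n)); rows <- ceiling(n / cols)
  us <- seq(0.15, 0.85, length.out = cols) * res[1]
  vs <- seq(0.15, 0.85, length.out = rows) * res[2]
  pos <- expand.grid(u = us, v = vs)[seq_len(n), ]
  fruits <- data.frame(
    x_mm = (pos$u - pp[1]) * z / f[1],
    y_mm = (pos$v - pp[2]) * z / f[2],
    z_mm = z, radius_mm = diameter / 2)
  sceneSpec(fruits, camera = cam, seed = seed, ...)
}
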