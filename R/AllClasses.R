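#' @import methods
NULL

#' Pinhole camera model
#'
#' An idealised pinhole camera: focal length expressed on the pixel grid,
#' principal point, sensor resolution and (optionally) the nominal field of
#' view. The focal length in pixels relates pixel extent to physical extent
#' through `extent_mm = extent_px * depth_mm / focal_px`.
#'
#' @slot focal numeric of length 1 or 2; focal length in pixels. When length
#'   2, the components are the horizontal (fx) and vertical (fy) focal
#'   lengths.
#' @slot principalPoint numeric of length 2, `(cx, cy)` in pixels
#'   (0-based continuous coordinates, origin at the top-left image corner).
#' @slot resolution integer of length 2, `(width, height)` in pixels.
#' @slot fov numeric of length 2, nominal `(horizontal, vertical)` field of
#'   view in degrees; may be `NA` when unknown.
#'
#' @seealso [cameraModel()], [focalFromFov()], [depthCameraD435()]
#' @export
setClass("CameraModel",
  representation(
    focal = "numeric",
    principalPoint = "numeric",
    resolution = "integer",
    fov = "numeric"
  )
)

setValidity("CameraModel", function(object) {
  msg <- character()
  f <- object@focal
  if (!length(f) %in% 1:2 || any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "focal must be 1 or 2 positive finite values (pixels)")
  if (length(object@principalPoint) != 2 ||
      any(!is.finite(object@principalPoint)))
    msg <- c(msg, "principalPoint must be 2 finite values (cx, cy)")
  res <- object@resolution
  if (length(res) != 2 || any(is.na(res)) || any(res < 1))
    msg <- c(msg, "resolution must be 2 positive integers (width, height)")
  if (length(object@fov) != 2)
    msg <- c(msg, "fov must have 2 components (horizontal, vertical) degrees")
  # consistency between stated horizontal FOV and focal length (1% slack)
  if (!length(msg) && is.finite(object@fov[1])) {
    fh <- focalFromFov(res[1], object@fov[1])
    if (abs(f[1] - fh) / fh > 0.01)
      msg <- c(msg, sprintf(
        "focal %.2f px inconsistent with horizontal FOV %.2f deg (implies %.2f px)",
        f[1], object@fov[1], fh))
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("CameraModelOrNULL", c("CameraModel", "NULL"))

#' Depth map aligned to a camera frame
#'
#' Per-pixel range in millimetres on the pixel grid of a [CameraModel].
#' The value 0 marks invalid pixels (no sensor return), matching the
#' convention of 16-bit PNG depth files.
#'
#' @slot values numeric matrix of depth in mm, `nrow = height`,
#'   `ncol = width`; non-negative and finite; 0 = invalid.
#' @slot camera the [CameraModel] whose pixel grid the values live on, or
#'   `NULL` when the intrinsics are unknown (sizing operations then refuse
#'   to run).
#'
#' @seealso [depthMap()], [alignDepthToRgb()], [readDepthPng()]
#' @export
setClass("DepthMap",
  representation(values = "matrix", camera = "CameraModelOrNULL")
)

setValidity("DepthMap", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || length(v) == 0)
    msg <- c(msg, "values must be a non-empty numeric matrix")
  else if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "depth values must be finite and >= 0 (0 = invalid)")
  if (!is.null(object@camera)) {
    res <- object@camera@resolution
    if (!is.null(dim(v)) && (nrow(v) != res[2] || ncol(v) != res[1]))
      msg <- c(msg, sprintf(
        "depth grid %d x %d does not match camera resolution %d x %d (w x h)",
        ncol(v), nrow(v), res[1], res[2]))
  }
  if (length(msg)) msg else TRUE
})

#' Tiling specification
#'
#' Describes how an image is cut into tiles: the common tile size and the
#' offset of each tile's top-left corner in the original image. Produced by
#' [cornerTiles()] (the four vertex-anchored crops) or [gridTiles()] (a
#' full-coverage overlapping grid).
#'
#' @slot imageSize integer `(W, H)` of the original image.
#' @slot tileSize integer `(w, h)` of every tile.
#' @slot offsets numeric matrix with one `(dx, dy)` row per tile.
#' @slot overlap numeric `(ox, oy)` requested overlap (grid mode; `NA` for
#'   corner mode).
#' @slot mode `"corner"` or `"grid"`.
#' @slot coverage logical; `TRUE` when every pixel of the original image is
#'   inside at least one tile.
#' @export
setClass("TileSpec",
  representation(
    imageSize = "integer",
    tileSize = "integer",
    offsets = "matrix",
    overlap = "numeric",
    mode = "character",
    coverage = "logical"
  )
)

setValidity("TileSpec", function(object) {
  msg <- character()
  w <- object@tileSize; W <- object@imageSize
  if (any(w < 1)) msg <- c(msg, "tile size must be positive")
  if (any(w > W)) msg <- c(msg, "tile must not exceed the image")
  off <- object@offsets
  if (ncol(off) != 2) msg <- c(msg, "offsets must have 2 columns")
  else if (nrow(off) &&
           (any(off < 0) || any(off[, 1] + w[1] > W[1]) ||
            any(off[, 2] + w[2] > W[2])))
    msg <- c(msg, "every tile must lie fully inside the original image")
  if (length(msg)) msg else TRUE
})

#' Synthetic RGB-D scene specification
#'
#' A complete, seeded description of a synthetic orchard scene: camera,
#' spherical fruits (camera-frame coordinates in mm), opaque occluders,
#' background depth, depth-noise parameters and the projection mode.
#' Rendering a spec with [renderScene()] is deterministic given `seed`.
#'
#' Projection modes: `"consistent"` renders each fruit as a flat disk of
#' pixel radius `focal * r / z` at uniform depth `z`, so the linear sizing
#' model inverts the rendering exactly (up to rasterisation); `"perspective"`
#' renders the physically exact sphere silhouette (pixel radius
#' `focal * r / sqrt(z^2 - r^2)`) with true per-pixel surface range, which
#' quantifies the bias the linear model incurs on real spheres.
#'
#' @slot camera the rendering [CameraModel].
#' @slot fruits data.frame with columns `x_mm`, `y_mm`, `z_mm` (camera
#'   frame: x right, y down, z forward), `radius_mm`, `hue`, `sat`, `val`.
#' @slot occluders data.frame (possibly empty) with columns `shape`
#'   (`"rect"` or `"ellipse"`), `x_min`, `y_min`, `x_max`, `y_max` (pixels),
#'   `z_mm`, `hue`, `sat`, `val`.
#' @slot backgroundDepth numeric, background plane range in mm.
#' @slot noiseSigma numeric, Gaussian depth-noise standard deviation in mm.
#' @slot dropout numeric in `[0,1)`, probability a depth pixel returns 0.
#' @slot projectionMode `"consistent"` or `"perspective"`.
#' @slot seed integer; fixes every stochastic choice of the renderer.
#'
#' @seealso [sceneSpec()], [randomScene()], [renderScene()]
#' @export
setClass("SceneSpec",
  representation(
    camera = "CameraModel",
    fruits = "data.frame",
    occluders = "data.frame",
    backgroundDepth = "numeric",
    noiseSigma = "numeric",
    dropout = "numeric",
    projectionMode = "character",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  fr <- object@fruits
  need <- c("x_mm", "y_mm", "z_mm", "radius_mm", "hue", "sat", "val")
  if (!all(need %in% names(fr)))
    msg <- c(msg, paste("fruits needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(fr) && any(fr$radius_mm <= 0))
      msg <- c(msg, "fruit radii must be positive")
    if (nrow(fr) && any(fr$z_mm <= fr$radius_mm))
      msg <- c(msg, "every fruit must lie fully in front of the camera (z > radius)")
  }
  if (!object@projectionMode %in% c("consistent", "perspective"))
    msg <- c(msg, "projectionMode must be 'consistent' or 'perspective'")
  if (object@backgroundDepth <= 0)
    msg <- c(msg, "backgroundDepth must be positive")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})
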