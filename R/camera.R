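#' Focal length in pixels from a field of view
#'
#' `focal_px = (extent_px / 2) / tan(fov / 2)` for a pinhole camera.
#'
#' @param extentPx sensor extent along the axis, in pixels.
#' @param fovDeg field of view along the same axis, in degrees.
#' @return focal length in pixels.
#' @examples
#' focalFromFov(1280, 86)   # depth sensor horizontal focal, ~686 px
#' @export
focalFromFov <- function(extentPx, fovDeg) {
  stopifnot(extentPx > 0, fovDeg > 0, fovDeg < 180)
  (extentPx / 2) / tan(fovDeg * pi / 360)
}

#' Field of view (degrees) implied by a focal length
#' @param extentPx sensor extent in pixels.
#' @param focalPx focal length in pixels.
#' @return field of view in degrees.
#' @export
fovFromFocal <- function(extentPx, focalPx) {
  stopifnot(extentPx > 0, focalPx > 0)
  2 * atan((extentPx / 2) / focalPx) * 180 / pi
}

#' Construct a pinhole camera model
#'
#' Either `focalPx` or `fovDeg` (or both) must be given; a missing focal
#' length is derived per axis from the field of view, and a missing
#' principal point defaults to the image centre.
#'
#' @param width,height sensor resolution in pixels.
#' @param focalPx focal length in pixels; a scalar, or `c(fx, fy)`.
#' @param cx,cy principal point (default: image centre).
#' @param fovDeg nominal field of view `c(horizontal, vertical)` in degrees.
#' @return a [CameraModel].
#' @examples
#' cameraModel(1280, 720, fovDeg = c(86, 57))
#' cameraModel(640, 360, focalPx = 600)
#' @export
cameraModel <- function(width, height, focalPx = NULL, cx = NULL, cy = NULL,
                        fovDeg = c(NA_real_, NA_real_)) {
  fovDeg <- rep_len(as.numeric(fovDeg), 2)
  if (is.null(focalPx)) {
    if (!is.finite(fovDeg[1]))
      stop("either focalPx or a horizontal fovDeg must be given")
    fx <- focalFromFov(width, fovDeg[1])
    focalPx <- if (is.finite(fovDeg[2])) c(fx, focalFromFov(height, fovDeg[2])) else fx
  }
  if (is.null(cx)) cx <- width / 2
  if (is.null(cy)) cy <- height / 2
  new("CameraModel",
      focal = as.numeric(focalPx),
      principalPoint = c(cx, cy),
      resolution = as.integer(c(width, height)),
      fov = fovDeg)
}

#' Stock RealSense D435i intrinsics
#'
#' Convenience constructors for the RGB sensor (1920 x 1080, 69.4 x 42.5
#' degrees) and the depth sensor (1280 x 720, 86 x 57 degrees) of the Intel
#' RealSense D435i, the sensor the sizing model is designed around. The
#' focal lengths are derived per axis from the nominal fields of view; no
#' factory calibration is assumed.
#'
#' @return a [CameraModel].
#' @export
rgbCameraD435 <- function()
  cameraModel(1920, 1080, fovDeg = c(69.4, 42.5))

#' @rdname rgbCameraD435
#' @export
depthCameraD435 <- function()
  cameraModel(1280, 720, fovDeg = c(86, 57))

#' @describeIn cameraAccessors focal length in pixels, always length 2
#'   `(fx, fy)` (a scalar focal is recycled).
#' @export
setGeneric("focalPx", function(x) standardGeneric("focalPx"))

#' Camera accessors
#'
#' @param x a [CameraModel] (or, for `camera()`, a [DepthMap]).
#' @name cameraAccessors
NULL

#' @export
setMethod("focalPx", "CameraModel", function(x) rep_len(x@focal, 2))

#' @describeIn cameraAccessors principal point `(cx, cy)`.
#' @export
setGeneric("principalPoint", function(x) standardGeneric("principalPoint"))

#' @export
setMethod("principalPoint", "CameraModel", function(x) x@principalPoint)

#' @describeIn cameraAccessors resolution `(width, height)` in pixels.
#' @export
setGeneric("cameraResolution", function(x) standardGeneric("cameraResolution"))

#' @export
setMethod("cameraResolution", "CameraModel", function(x) x@resolution)

#' @describeIn cameraAccessors nominal field of view in degrees.
#' @export
setGeneric("fieldOfView", function(x) standardGeneric("fieldOfView"))

#' @export
setMethod("fieldOfView", "CameraModel", function(x) x@fov)

setMethod("show", "CameraModel", function(object) {
  f <- focalPx(object)
  cat(sprintf("CameraModel %d x %d px, focal (%.1f, %.1f) px, pp (%.1f, %.1f)",
              object@resolution[1], object@resolution[2], f[1], f[2],
              object@principalPoint[1], object@principalPoint[2]))
  if (any(is.finite(object@fov)))
    cat(sprintf(", FOV %.1f x %.1f deg", object@fov[1], object@fov[2]))
  cat("\n")
})
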