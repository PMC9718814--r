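#' Construct a depth map
#'
#' @param values numeric matrix of ranges in mm, `nrow = height`,
#'   `ncol = width`; 0 marks invalid pixels.
#' @param camera the [CameraModel] the grid is aligned to, or `NULL`.
#' @return a [DepthMap].
#' @export
depthMap <- function(values, camera = NULL) {
  new("DepthMap", values = values, camera = camera)
}

#' @describeIn depthMap the raw value matrix (mm).
#' @param x a [DepthMap].
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))

#' @export
setMethod("depthValues", "DepthMap", function(x) x@values)

#' @describeIn depthMap the camera the map is aligned to (may be `NULL`).
#' @export
setGeneric("camera", function(x) standardGeneric("camera"))

#' @export
setMethod("camera", "DepthMap", function(x) x@camera)

setMethod("show", "DepthMap", function(object) {
  v <- object@values
  nz <- v[v > 0]
  cat(sprintf("DepthMap %d x %d px, %.1f%% valid", ncol(v), nrow(v),
              100 * length(nz) / length(v)))
  if (length(nz))
    cat(sprintf(", range %.0f-%.0f mm", min(nz), max(nz)))
  cat(if (is.null(object@camera)) ", no camera\n" else ", with camera\n")
})

#' Resample a depth map onto an RGB camera's pixel grid
#'
#' RGB and depth sensors of an RGB-D rig see different fields of view, so a
#' detector box in RGB coordinates cannot index the depth grid directly.
#' This alignment models the two sensors as co-located pinholes that differ
#' only in FOV and resolution (no stereo baseline): each output pixel's
#' viewing ray, defined by the RGB intrinsics, is looked up in the source
#' grid via the depth intrinsics and filled by nearest-neighbour sampling.
#' Depth is never interpolated — interpolation across an object edge would
#' blend foreground and background ranges and corrupt sizing. Output pixels
#' whose ray falls outside the source FOV are set to 0 (invalid).
#'
#' When the two frames are identical the input is returned verbatim, so
#' the operation is idempotent.
#'
#' @param depth a [DepthMap] with a non-`NULL` camera.
#' @param rgbCam the target [CameraModel].
#' @return a [DepthMap] on `rgbCam`'s grid, with `camera = rgbCam`.
#' @export
alignDepthToRgb <- function(depth, rgbCam) {
  stopifnot(is(depth, "DepthMap"), is(rgbCam, "CameraModel"))
  src <- camera(depth)
  if (is.null(src))
    stop("depth map carries no camera model; cannot align")
  if (identical(src@focal, rgbCam@focal) &&
      identical(src@principalPoint, rgbCam@principalPoint) &&
      identical(src@resolution, rgbCam@resolution))
    return(depthMap(depthValues(depth), rgbCam))

  fs <- focalPx(src);  ps <- principalPoint(src);  rs <- cameraResolution(src)
  ft <- focalPx(rgbCam); pt <- principalPoint(rgbCam); rt <- cameraResolution(rgbCam)

  # pixel centres sit at i + 0.5; map target viewing angle to source column/row
  mapAxis <- function(nTo, cTo, fTo, nFrom, cFrom, fFrom) {
    centres <- seq_len(nTo) - 0.5
    u <- cFrom + fFrom * (centres - cTo) / fTo
    j <- floor(u)                      # nearest-neighbour: containing pixel
    j[j < 0 | j >= nFrom] <- NA
    j + 1L                             # 1-based matrix index
  }
  cols <- mapAxis(rt[1], pt[1], ft[1], rs[1], ps[1], fs[1])
  rows <- mapAxis(rt[2], pt[2], ft[2], rs[2], ps[2], fs[2])

  v <- depthValues(depth)
  out <- matrix(0, nrow = rt[2], ncol = rt[1])
  okR <- !is.na(rows); okC <- !is.na(cols)
  out[okR, okC] <- v[rows[okR], cols[okC]]
  depthMap(out, rgbCam)
}

# depth value at a continuous (x, y) pixel coordinate; 0-based, half-open
depthAtPoint <- function(depth, x, y) {
  v <- depthValues(depth)
  ix <- floor(x) + 1L; iy <- floor(y) + 1L
  ok <- ix >= 1 & ix <= ncol(v) & iy >= 1 & iy <= nrow(v)
  out <- rep(NA_real_, length(x))
  out[ok] <- v[cbind(iy[ok], ix[ok])]
  out
}
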