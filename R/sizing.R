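#' Gate detections by confidence score
#'
#' Keeps boxes with `score >= threshold` (inclusive gate; the default 0.75
#' mirrors the high-confidence cut used when sizing fruit from detector
#' output), preserving the original order. Boxes without a score are an
#' error: ground truth must not be fed through a score gate.
#'
#' @param detections scored box data.frame.
#' @param threshold confidence cut in `[0, 1]`.
#' @return the surviving rows.
#' @export
filterByScore <- function(detections, threshold = 0.75) {
  checkBoxes(detections)
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(detections) == 0) return(detections)
  if (!"score" %in% names(detections) || anyNA(detections$score)) {
    bad <- if ("score" %in% names(detections)) which(is.na(detections$score))[1] else 1L
    stop("detection row ", bad, " carries no score; cannot gate by score")
  }
  detections[detections$score >= threshold, , drop = FALSE]
}

#' Sample depth for a detection box
#'
#' Reads the depth used for sizing from the aligned depth map. The default
#' `"center"` mode takes the median of the non-zero depths in a
#' `window x window` neighbourhood of the box centre (zeros are sensor
#' dropouts, never data, so the median ignores them). The `"edges"` mode
#' instead samples the midpoints of the two vertical box edges the same way
#' and averages whichever of the two windows returned a valid value —
#' reading the object's range at both horizontal extremes of the box rather
#' than at its centre.
#'
#' @param boxes box data.frame (one row per detection).
#' @param depth a [DepthMap] aligned to the boxes' pixel grid.
#' @param window odd window side in pixels (default 3).
#' @param mode `"center"` or `"edges"`.
#' @return data.frame with `depth_mm`, `valid`, `reason` per box.
#' @export
sampleDepth <- function(boxes, depth, window = 3L, mode = c("center", "edges")) {
  checkBoxes(boxes)
  mode <- match.arg(mode)
  stopifnot(window >= 1, window %% 2 == 1)
  v <- depthValues(depth)
  h <- nrow(v); w <- ncol(v)
  half <- (window - 1L) / 2L

  windowMedian <- function(x, y) {
    ix <- floor(x); iy <- floor(y)
    if (is.na(ix) || ix < 0 || ix >= w || iy < 0 || iy >= h)
      return(NA_real_)  # point outside grid
    xs <- max(ix - half, 0):min(ix + half, w - 1L)
    ys <- max(iy - half, 0):min(iy + half, h - 1L)
    vals <- v[ys + 1L, xs + 1L]
    vals <- vals[vals > 0]
    if (length(vals)) stats::median(vals) else NA_real_
  }

  n <- nrow(boxes)
  depth_mm <- rep(NA_real_, n); reason <- rep(NA_character_, n)
  ctr <- boxCenter(boxes)
  for (i in seq_len(n)) {
    if (mode == "center") {
      d <- windowMedian(ctr[i, 1], ctr[i, 2])
      if (is.na(d))
        reason[i] <- if (ctr[i, 1] < 0 || ctr[i, 1] >= w ||
                         ctr[i, 2] < 0 || ctr[i, 2] >= h)
          "center outside depth grid" else "no valid depth in window"
    } else {
      dl <- windowMedian(boxes$x_min[i], ctr[i, 2])
      dr <- windowMedian(min(boxes$x_max[i] - 1e-9, w - 1e-9), ctr[i, 2])
      both <- c(dl, dr)
      d <- if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE)
      if (is.na(d)) reason[i] <- "no valid depth at either box edge"
    }
    depth_mm[i] <- d
  }
  data.frame(depth_mm = depth_mm, valid = !is.na(depth_mm), reason = reason)
}

#' Estimate physical diameters from boxes and depth
#'
#' The trigonometric-ratio (similar-triangles) sizing model of the pinhole
#' camera: `horizontal_mm = width_px * depth / focal_x`,
#' `vertical_mm = height_px * depth / focal_y`; the long axis is the larger
#' of the two and the short axis the smaller. Depth comes from
#' [sampleDepth()]; estimates with no usable depth are returned with
#' `valid = FALSE` and `NA` diameters rather than dropped, so row counts
#' are preserved.
#'
#' @inheritParams sampleDepth
#' @param cam the [CameraModel] supplying the focal length.
#' @return data.frame: the box columns plus `depth_mm`, `horizontal_mm`,
#'   `vertical_mm`, `long_axis_mm`, `short_axis_mm`, `valid`.
#' @examples
#' cam <- cameraModel(200, 200, focalPx = 600)
#' dm <- depthMap(matrix(900, 200, 200), cam)
#' b <- boundingBoxes(80, 80, 120, 110, score = 0.9)  # 40 x 30 px
#' estimateSize(b, dm, cam)  # horizontal 60 mm, vertical 45 mm
#' @export
estimateSize <- function(boxes, depth, cam, window = 3L,
                         mode = c("center", "edges")) {
  checkBoxes(boxes)
  f <- focalPx(cam)
  samp <- sampleDepth(boxes, depth, window = window, mode = mode)
  horizontal <- boxWidth(boxes) * samp$depth_mm / f[1]
  vertical <- boxHeight(boxes) * samp$depth_mm / f[2]
  out <- boxes
  out$depth_mm <- samp$depth_mm
  out$horizontal_mm <- horizontal
  out$vertical_mm <- vertical
  out$long_axis_mm <- pmax(horizontal, vertical)
  out$short_axis_mm <- pmin(horizontal, vertical)
  out$valid <- samp$valid
  out
}

#' Score-gated sizing report
#'
#' The composed sizing pipeline for one image: gate detections by score,
#' sample depth, convert to physical diameters. Rows are ordered by
#' descending score, ties by `x_min`, and numbered in `object_id`.
#'
#' @inheritParams estimateSize
#' @param detections scored box data.frame.
#' @param scoreThreshold confidence gate (default 0.75).
#' @return a size-report data.frame (columns of [estimateSize()] plus
#'   `object_id`).
#' @export
sizeReport <- function(detections, depth, cam, scoreThreshold = 0.75,
                       window = 3L, mode = c("center", "edges")) {
  kept <- filterByScore(detections, scoreThreshold)
  if (nrow(kept)) kept <- kept[order(-kept$score, kept$x_min), , drop = FALSE]
  est <- estimateSize(kept, depth, cam, window = window, mode = mode)
  est <- cbind(object_id = seq_len(nrow(est)), est)
  rownames(est) <- NULL
  est
}

#' Write a size report as CSV
#'
#' Millimetre columns are reported at 2 decimals (half away from zero);
#' full precision is a property of the in-memory report, not the file.
#'
#' @param report output of [sizeReport()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
writeSizeReport <- function(report, path) {
  out <- report
  for (col in intersect(c("depth_mm", "horizontal_mm", "vertical_mm",
                          "long_axis_mm", "short_axis_mm"), names(out)))
    out[[col]] <- roundHalfUp(out[[col]], 2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# round half away from zero (the convention of printed verification tables);
# base round() is banker's rounding
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
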