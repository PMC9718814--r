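#' Corner-anchored tiles
#'
#' Crops an image into exactly four tiles, one anchored at each vertex of
#' the original: offsets `(0,0)`, `(W-w,0)`, `(0,H-h)`, `(W-w,H-h)`. With
#' `w = W/2, h = H/2` the four tiles partition the image exactly; larger
#' tiles overlap; smaller tiles leave the image centre uncovered, in which
#' case the returned spec's `coverage` flag is `FALSE` and a warning is
#' raised (use [gridTiles()] when full coverage matters).
#'
#' @param imageSize `(W, H)` of the original image in pixels.
#' @param tileSize `(w, h)` of each tile; must not exceed the image.
#' @return a [TileSpec] with four offsets.
#' @examples
#' cornerTiles(c(1280, 720), c(640, 360))  # exact partition
#' @export
cornerTiles <- function(imageSize, tileSize) {
  W <- as.integer(imageSize); w <- as.integer(tileSize)
  if (any(w > W)) stop("tile size exceeds image size")
  off <- rbind(c(0, 0), c(W[1] - w[1], 0), c(0, W[2] - w[2]),
               c(W[1] - w[1], W[2] - w[2]))
  colnames(off) <- c("dx", "dy")
  covered <- 2 * w[1] >= W[1] && 2 * w[2] >= W[2]
  if (!covered)
    warning("corner tiles of ", w[1], "x", w[2], " do not cover a ",
            W[1], "x", W[2], " image; interior pixels fall in no tile")
  new("TileSpec", imageSize = W, tileSize = w, offsets = off,
      overlap = c(NA_real_, NA_real_), mode = "corner", coverage = covered)
}

#' Overlapping-grid tiles
#'
#' Row-major grid of tiles with stride `tileSize - overlap`; the final row
#' and column are shifted inward so every tile lies inside the image, which
#' guarantees full pixel coverage for any valid overlap. Choosing an
#' overlap at least as large as the largest annotated object guarantees
#' every ground-truth box lies fully inside at least one tile, avoiding the
#' detection errors that plain cropping causes for objects cut by a tile
#' boundary.
#'
#' @inheritParams cornerTiles
#' @param overlap `(ox, oy)` overlap between adjacent tiles in pixels;
#'   must be smaller than the tile.
#' @return a [TileSpec]; `coverage` is always `TRUE`.
#' @export
gridTiles <- function(imageSize, tileSize, overlap = c(0, 0)) {
  W <- as.integer(imageSize); w <- as.integer(tileSize)
  o <- rep_len(as.integer(overlap), 2)
  if (any(w > W)) stop("tile size exceeds image size")
  stride <- w - o
  if (any(stride <= 0)) stop("overlap must be smaller than the tile (stride > 0)")
  axisStarts <- function(extent, tile, step) {
    s <- seq.int(0L, max(extent - tile, 0L), by = step)
    if (s[length(s)] != extent - tile) s <- c(s, extent - tile)
    s
  }
  xs <- axisStarts(W[1], w[1], stride[1])
  ys <- axisStarts(W[2], w[2], stride[2])
  off <- as.matrix(expand.grid(dx = xs, dy = ys))[, c("dx", "dy"), drop = FALSE]
  new("TileSpec", imageSize = W, tileSize = w, offsets = off,
      overlap = as.numeric(o), mode = "grid", coverage = TRUE)
}

#' @describeIn cornerTiles offsets matrix, one `(dx, dy)` row per tile.
#' @param spec a [TileSpec].
#' @export
tileOffsets <- function(spec) spec@offsets

#' @describeIn cornerTiles number of tiles.
#' @export
nTiles <- function(spec) nrow(spec@offsets)

setMethod("show", "TileSpec", function(object) {
  cat(sprintf("TileSpec (%s): %d tiles of %d x %d in %d x %d, coverage %s\n",
              object@mode, nrow(object@offsets), object@tileSize[1],
              object@tileSize[2], object@imageSize[1], object@imageSize[2],
              if (object@coverage) "full" else "PARTIAL"))
})

#' Transfer ground truth into tile coordinates
#'
#' Boxes intersecting the tile are clipped to it and re-expressed in tile
#' coordinates. A clipped box is kept only when the retained fraction of
#' its area is at least `minInsideFraction`; the default 0.5 mirrors the
#' annotation rule that objects more than half hidden are not labelled.
#'
#' @param gt box data.frame in original-image coordinates.
#' @param offset `(dx, dy)` of the tile's top-left corner.
#' @param tileSize `(w, h)` of the tile.
#' @param minInsideFraction minimum clipped-area/original-area in `(0, 1]`.
#' @return boxes in tile coordinates.
#' @export
transferGroundTruth <- function(gt, offset, tileSize,
                                minInsideFraction = 0.5) {
  checkBoxes(gt)
  stopifnot(minInsideFraction > 0, minInsideFraction <= 1)
  if (nrow(gt) == 0) return(gt)
  x0 <- offset[1]; y0 <- offset[2]
  x1 <- x0 + tileSize[1]; y1 <- y0 + tileSize[2]
  cl <- gt
  cl$x_min <- pmax(gt$x_min, x0); cl$x_max <- pmin(gt$x_max, x1)
  cl$y_min <- pmax(gt$y_min, y0); cl$y_max <- pmin(gt$y_max, y1)
  w <- cl$x_max - cl$x_min; h <- cl$y_max - cl$y_min
  frac <- ifelse(w > 0 & h > 0, (w * h) / boxArea(gt), 0)
  keep <- frac >= minInsideFraction
  shiftBoxes(cl[keep, , drop = FALSE], -x0, -y0)
}

#' Map per-tile detections back to original-image coordinates
#'
#' @param detectionsPerTile list of box data.frames, one per tile, in the
#'   order of `tileOffsets(spec)`.
#' @param spec the [TileSpec] the tiles came from.
#' @return one box data.frame in original coordinates, with a `tile`
#'   column recording provenance.
#' @export
mapToOriginal <- function(detectionsPerTile, spec) {
  stopifnot(length(detectionsPerTile) == nTiles(spec))
  off <- tileOffsets(spec)
  parts <- lapply(seq_along(detectionsPerTile), function(i) {
    d <- detectionsPerTile[[i]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    checkBoxes(d)
    d <- shiftBoxes(d, off[i, 1], off[i, 2])
    d$tile <- i
    d
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    out <- emptyBoxes(); out$tile <- integer()
    return(out)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Merge duplicate detections by non-maximum suppression
#'
#' Tiling with overlap detects boundary objects in more than one tile;
#' mapping back to the original frame then yields near-duplicate boxes.
#' Greedy score-ordered NMS resolves them: boxes are visited by descending
#' score (ties by smaller `x_min`, then `y_min`) and kept only when their
#' IoU with every already-kept box is below `iouThreshold`. The output is
#' idempotent under re-merging.
#'
#' @param boxes scored box data.frame.
#' @param iouThreshold suppression threshold (default 0.5).
#' @return the surviving boxes, in score order.
#' @export
mergeDetections <- function(boxes, iouThreshold = 0.5) {
  checkBoxes(boxes)
  if (nrow(boxes) <= 1) return(boxes)
  if (!"score" %in% names(boxes) || anyNA(boxes$score))
    stop("NMS merging needs a score on every box")
  ord <- order(-boxes$score, boxes$x_min, boxes$y_min)
  b <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    ki <- which(keep)
    keep[i] <- !length(ki) ||
      all(boxIoU(b[i, , drop = FALSE], b[ki, , drop = FALSE]) < iouThreshold)
  }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop an image into the tiles of a spec
#'
#' @param image matrix (grayscale/depth) or H x W x C array.
#' @param spec a [TileSpec] whose `imageSize` matches the image.
#' @return list of cropped arrays, in offset order.
#' @export
cropToTiles <- function(image, spec) {
  d <- dim(image)
  if (d[2] != spec@imageSize[1] || d[1] != spec@imageSize[2])
    stop("image is ", d[2], "x", d[1], " but spec expects ",
         spec@imageSize[1], "x", spec@imageSize[2])
  off <- tileOffsets(spec); w <- spec@tileSize
  lapply(seq_len(nrow(off)), function(i) {
    rows <- (off[i, 2] + 1L):(off[i, 2] + w[2])
    cols <- (off[i, 1] + 1L):(off[i, 1] + w[1])
    if (length(d) == 2) image[rows, cols, drop = FALSE]
    else image[rows, cols, , drop = FALSE]
  })
}
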