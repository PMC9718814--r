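#' Build a bounding-box table
#'
#' Bounding boxes are ordinary data.frames with columns `x_min`, `y_min`,
#' `x_max`, `y_max` (0-based continuous pixel coordinates, origin top-left,
#' x rightward, y downward, half-open `[min, max)` extents) plus optional
#' `score` (detection confidence in `[0, 1]`; `NA` for ground truth),
#' `label` and `image_id`. All box operations in the package accept and
#' return this layout, so the result of one stage feeds the next directly.
#'
#' @param x_min,y_min,x_max,y_max numeric vectors; `x_max > x_min` and
#'   `y_max > y_min` (degenerate boxes are rejected).
#' @param score optional confidence in `[0, 1]`.
#' @param label class tag, default `"fruit"`.
#' @param image_id optional image identifier.
#' @param ... further columns carried along unchanged.
#' @return a data.frame of validated boxes.
#' @examples
#' boundingBoxes(0, 0, 10, 20, score = 0.9)
#' @export
boundingBoxes <- function(x_min, y_min, x_max, y_max, score = NA_real_,
                          label = "fruit", image_id = NA, ...) {
  df <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                   score = as.numeric(score), label = label,
                   image_id = image_id, ...)
  checkBoxes(df)
  df
}

#' Validate a bounding-box table
#'
#' Stops with an informative message on the first malformed row: missing
#' columns, non-finite corners, non-positive width/height, or a score
#' outside `[0, 1]`.
#'
#' @param boxes a box data.frame (see [boundingBoxes()]).
#' @return `boxes`, invisibly.
#' @export
checkBoxes <- function(boxes) {
  need <- c("x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(boxes))
  if (length(miss))
    stop("box table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(boxes) == 0) return(invisible(boxes))
  corners <- as.matrix(boxes[need])
  bad <- which(!is.finite(corners), arr.ind = TRUE)
  if (nrow(bad))
    stop("box row ", bad[1, 1], ": non-finite coordinate")
  deg <- which(boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min)
  if (length(deg))
    stop("box row ", deg[1], ": degenerate (width and height must be > 0)")
  if ("score" %in% names(boxes)) {
    s <- boxes$score
    bad <- which(!is.na(s) & (s < 0 | s > 1))
    if (length(bad))
      stop("box row ", bad[1], ": score outside [0, 1]")
  }
  invisible(boxes)
}

#' Box geometry helpers
#'
#' @param boxes a box data.frame.
#' @return `boxWidth`/`boxHeight`/`boxArea`: numeric vectors. `boxCenter`:
#'   a two-column matrix of `(x, y)` centres.
#' @name boxGeometry
NULL

#' @rdname boxGeometry
#' @export
boxWidth <- function(boxes) boxes$x_max - boxes$x_min

#' @rdname boxGeometry
#' @export
boxHeight <- function(boxes) boxes$y_max - boxes$y_min

#' @rdname boxGeometry
#' @export
boxArea <- function(boxes) boxWidth(boxes) * boxHeight(boxes)

#' @rdname boxGeometry
#' @export
boxCenter <- function(boxes) {
  cbind(x = (boxes$x_min + boxes$x_max) / 2,
        y = (boxes$y_min + boxes$y_max) / 2)
}

#' Intersection over union
#'
#' `boxIoU()` compares boxes elementwise (recycling a single row);
#' `iouMatrix()` returns the full `nrow(a) x nrow(b)` matrix. Disjoint
#' boxes score 0; identical boxes score 1.
#'
#' @param a,b box data.frames.
#' @return numeric vector (`boxIoU`) or matrix (`iouMatrix`) of values in
#'   `[0, 1]`.
#' @examples
#' a <- boundingBoxes(0, 0, 10, 10)
#' b <- boundingBoxes(5, 0, 15, 10)
#' boxIoU(a, b)  # 50 / 150
#' @export
boxIoU <- function(a, b) {
  checkBoxes(a); checkBoxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1 && nrow(b) != 1)
    stop("boxIoU: incompatible row counts ", nrow(a), " and ", nrow(b))
  ix <- function(v, n) rep_len(v, n)
  iw <- pmin(ix(a$x_max, n), ix(b$x_max, n)) - pmax(ix(a$x_min, n), ix(b$x_min, n))
  ih <- pmin(ix(a$y_max, n), ix(b$y_max, n)) - pmax(ix(a$y_min, n), ix(b$y_min, n))
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- ix(boxArea(a), n) + ix(boxArea(b), n) - inter
  inter / union
}

#' @rdname boxIoU
#' @export
iouMatrix <- function(a, b) {
  checkBoxes(a); checkBoxes(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  iw <- pmax(outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax), 0)
  ih <- pmax(outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax), 0)
  inter <- iw * ih
  inter / (outer(boxArea(a), boxArea(b), `+`) - inter)
}

#' Translate boxes
#'
#' @param boxes a box data.frame.
#' @param dx,dy pixel offsets added to all four corners.
#' @return the translated box data.frame.
#' @export
shiftBoxes <- function(boxes, dx, dy) {
  boxes$x_min <- boxes$x_min + dx; boxes$x_max <- boxes$x_max + dx
  boxes$y_min <- boxes$y_min + dy; boxes$y_max <- boxes$y_max + dy
  boxes
}

# empty box table with the canonical columns
emptyBoxes <- function() {
  data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
             y_max = numeric(), score = numeric(), label = character(),
             image_id = character())
}
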