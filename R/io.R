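# level-tagged logging; threshold via option rgbdsizer.logLevel
.logLevels <- c(debug = 1, info = 2, warn = 3, error = 4)
logMsg <- function(level, ...) {
  thr <- getOption("rgbdsizer.logLevel", "info")
  if (.logLevels[[level]] >= .logLevels[[thr]])
    message("[", toupper(level), "] ", ...)
  invisible(NULL)
}

#' Read ground-truth annotations
#'
#' Supports the two annotation formats common in detection work and
#' normalises both to the package's half-open 0-based corner convention at
#' the boundary, so no other code ever sees `x,y,w,h` or 1-based
#' coordinates.
#'
#' * `"coco"`: a JSON file with `images` and `annotations`; each
#'   annotation's `bbox` is `[x, y, w, h]`, mapped to corners
#'   `(x, y, x + w, y + h)`.
#' * `"voc"`: one Pascal VOC XML file per image; `xmin/ymin/xmax/ymax` are
#'   1-based inclusive pixel indices, mapped to
#'   `(xmin - 1, ymin - 1, xmax, ymax)`.
#'
#' Annotations with non-positive width or height are rejected and counted
#' in a warning rather than silently kept.
#'
#' @param path file to read.
#' @param dialect `"coco"` or `"voc"`.
#' @return box data.frame with `image_id` and `label`; for COCO input the
#'   `images` table is attached as `attr(, "images")`.
#' @export
readAnnotations <- function(path, dialect = c("coco", "voc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "coco") {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed COCO JSON in ", path, ": ",
                           conditionMessage(e)))
    if (!all(c("images", "annotations") %in% names(doc)))
      stop("COCO file ", path, " lacks 'images'/'annotations'")
    images <- do.call(rbind, lapply(doc$images, function(im)
      data.frame(id = as.character(im$id),
                 width = im$width %||% NA_integer_,
                 height = im$height %||% NA_integer_,
                 file_name = im$file_name %||% NA_character_)))
    rows <- lapply(seq_along(doc$annotations), function(k) {
      a <- doc$annotations[[k]]
      bb <- unlist(a$bbox)
      if (length(bb) != 4)
        stop("annotation ", k, " in ", path, ": bbox must have 4 numbers")
      data.frame(x_min = bb[1], y_min = bb[2],
                 x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
                 score = NA_real_,
                 label = as.character(a$category_id %||% "fruit"),
                 image_id = as.character(a$image_id))
    })
    gt <- if (length(rows)) do.call(rbind, rows) else emptyBoxes()
  } else {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e)
                      stop("malformed VOC XML in ", path, ": ",
                           conditionMessage(e)))
    imageId <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
    if (is.na(imageId) || !nzchar(imageId))
      imageId <- tools::file_path_sans_ext(basename(path))
    objs <- xml2::xml_find_all(doc, ".//object")
    num <- function(o, tag)
      as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag))))
    rows <- lapply(objs, function(o)
      data.frame(x_min = num(o, "xmin") - 1, y_min = num(o, "ymin") - 1,
                 x_max = num(o, "xmax"), y_max = num(o, "ymax"),
                 score = NA_real_,
                 label = xml2::xml_text(xml2::xml_find_first(o, "./name")),
                 image_id = imageId))
    gt <- if (length(rows)) do.call(rbind, rows) else emptyBoxes()
    images <- NULL
  }
  bad <- gt$x_max <= gt$x_min | gt$y_max <= gt$y_min |
    !is.finite(gt$x_min) | !is.finite(gt$y_max)
  if (any(bad)) {
    warning(sum(bad), " annotation(s) with non-positive extent rejected")
    gt <- gt[!bad, , drop = FALSE]
  }
  checkBoxes(gt)
  logMsg("info", "read ", nrow(gt), " annotation(s) from ", path)
  rownames(gt) <- NULL
  if (dialect == "coco") attr(gt, "images") <- images
  gt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotations as COCO JSON
#'
#' @param gt box data.frame with `image_id`.
#' @param path output file.
#' @param images optional data.frame `id`, `width`, `height`, `file_name`;
#'   derived from `gt` when missing.
#' @return `path`, invisibly.
#' @export
writeAnnotationsCoco <- function(gt, path, images = NULL) {
  checkBoxes(gt)
  ids <- unique(as.character(gt$image_id))
  if (is.null(images))
    images <- data.frame(id = ids, width = NA_integer_, height = NA_integer_,
                         file_name = NA_character_)
  anns <- lapply(seq_len(nrow(gt)), function(k) list(
    id = k, image_id = as.character(gt$image_id[k]), category_id = 1,
    bbox = c(gt$x_min[k], gt$y_min[k],
             gt$x_max[k] - gt$x_min[k], gt$y_max[k] - gt$y_min[k]),
    area = boxArea(gt[k, , drop = FALSE]), iscrowd = 0))
  doc <- list(
    images = lapply(seq_len(nrow(images)), function(i) as.list(images[i, ])),
    annotations = anns,
    categories = list(list(id = 1, name = "fruit")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read / write detections as COCO-results JSON
#'
#' The file is a JSON array of `{image_id, bbox: [x, y, w, h], score}`
#' objects (the COCO results dialect); conversion to half-open corners
#' happens here and only here.
#'
#' @param path file to read or write.
#' @return `readDetectionsJson`: a scored box data.frame.
#' @export
readDetectionsJson <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed detections JSON in ", path, ": ",
                         conditionMessage(e)))
  rows <- lapply(seq_along(doc), function(k) {
    d <- doc[[k]]
    bb <- unlist(d$bbox)
    if (length(bb) != 4 || is.null(d$score))
      stop("detection ", k, " in ", path, ": needs bbox [x,y,w,h] and score")
    data.frame(x_min = bb[1], y_min = bb[2],
               x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
               score = as.numeric(d$score), label = "fruit",
               image_id = as.character(d$image_id %||% NA))
  })
  det <- if (length(rows)) do.call(rbind, rows) else emptyBoxes()
  checkBoxes(det)
  logMsg("info", "read ", nrow(det), " detection(s) from ", path)
  det
}

#' @rdname readDetectionsJson
#' @param detections scored box data.frame.
#' @export
writeDetectionsJson <- function(detections, path) {
  checkBoxes(detections)
  doc <- lapply(seq_len(nrow(detections)), function(k) list(
    image_id = as.character(detections$image_id[k]),
    bbox = c(detections$x_min[k], detections$y_min[k],
             detections$x_max[k] - detections$x_min[k],
             detections$y_max[k] - detections$y_min[k]),
    score = detections$score[k]))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 16-bit PNG depth map
#'
#' Stored sample values are multiplied by `scaleMmPerUnit` (default 1:
#' sample value = millimetres); 0 stays 0, i.e. invalid. 8-bit input is an
#' error — quantising depth to 256 levels loses the millimetre scale, so
#' it is refused rather than guessed at.
#'
#' @param path PNG file.
#' @param scaleMmPerUnit millimetres per stored unit.
#' @param camera optional [CameraModel] to attach.
#' @return a [DepthMap].
#' @export
readDepthPng <- function(path, scaleMmPerUnit = 1, camera = NULL) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth < 16)
    stop(path, " is ", info$bit.depth, "-bit; depth PNG must be 16-bit ",
         "(8-bit quantisation loses the millimetre scale)")
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 2) stop(path, " is not grayscale")
    img <- img[, , 1]
  }
  m <- round(img * 65535) * scaleMmPerUnit
  attributes(m) <- list(dim = dim(m))
  depthMap(m, camera)
}

#' Write a 16-bit grayscale PNG depth map
#'
#' Values are divided by `scaleMmPerUnit`, rounded, and clamped to the
#' 16-bit range; 0 (invalid) is preserved exactly.
#'
#' @param depth a [DepthMap].
#' @param path output file.
#' @param scaleMmPerUnit millimetres per stored unit.
#' @return `path`, invisibly.
#' @export
writeDepthPng <- function(depth, path, scaleMmPerUnit = 1) {
  v <- round(depthValues(depth) / scaleMmPerUnit)
  if (any(v > 65535))
    stop("depth exceeds 16-bit range at this scale; increase scaleMmPerUnit")
  v[v < 0] <- 0
  H <- nrow(v); W <- ncol(v)
  # 16-bit grayscale PNG container: scanlines are a filter byte (0) plus
  # big-endian samples, deflate-compressed in a zlib wrapper
  be4 <- function(n) as.raw(c(n %/% 16777216, n %/% 65536, n %/% 256, n) %% 256)
  chunk <- function(type, data) {
    crc <- digest::digest(c(charToRaw(type), data), algo = "crc32",
                          serialize = FALSE)
    crc <- paste0(strrep("0", 8 - nchar(crc)), crc)
    crc <- as.raw(strtoi(substring(crc, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L))
    c(be4(length(data)), charToRaw(type), data, crc)
  }
  scan <- matrix(as.raw(0), nrow = 2 * W + 1, ncol = H)
  tv <- t(v)                                    # W x H, column = scanline
  scan[seq(2, 2 * W, by = 2), ] <- as.raw(tv %/% 256)
  scan[seq(3, 2 * W + 1, by = 2), ] <- as.raw(tv %% 256)
  ihdr <- c(be4(W), be4(H), as.raw(c(16, 0, 0, 0, 0)))
  idat <- memCompress(as.vector(scan), "gzip")
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

#' Read / write a depth map as a whitespace-delimited text matrix
#'
#' Plain-text fixture format: one image row per line, values in mm.
#'
#' @param path text file.
#' @param camera optional [CameraModel] to attach.
#' @return a [DepthMap].
#' @export
readDepthText <- function(path, camera = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  depthMap(m, camera)
}

#' @rdname readDepthText
#' @param depth a [DepthMap].
#' @export
writeDepthText <- function(depth, path) {
  utils::write.table(depthValues(depth), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.cameraKeys <- c("focal_px", "fx", "fy", "cx", "cy", "width", "height",
                 "fov_h_deg", "fov_v_deg")

#' Read / write camera intrinsics from a key-value config file
#'
#' YAML-style keys: `width`, `height` (required), `focal_px` (or `fx` and
#' `fy`), `cx`, `cy`, `fov_h_deg`, `fov_v_deg`. Unknown keys are rejected
#' by name rather than ignored.
#'
#' @param path config file.
#' @return a [CameraModel].
#' @export
readCameraConfig <- function(path) {
  if (!file.exists(path)) stop("camera config not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .cameraKeys)
  if (length(unknown))
    stop("unknown camera config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$width) || is.null(cfg$height))
    stop("camera config needs 'width' and 'height'")
  focal <- if (!is.null(cfg$fx)) c(cfg$fx, cfg$fy %||% cfg$fx) else cfg$focal_px
  cameraModel(cfg$width, cfg$height, focalPx = focal,
              cx = cfg$cx, cy = cfg$cy,
              fovDeg = c(cfg$fov_h_deg %||% NA_real_,
                         cfg$fov_v_deg %||% NA_real_))
}

#' @rdname readCameraConfig
#' @param cam a [CameraModel].
#' @export
writeCameraConfig <- function(cam, path) {
  f <- focalPx(cam); pp <- principalPoint(cam)
  res <- cameraResolution(cam); fov <- fieldOfView(cam)
  cfg <- list(width = res[1], height = res[2], fx = f[1], fy = f[2],
              cx = pp[1], cy = pp[2])
  if (is.finite(fov[1])) cfg$fov_h_deg <- fov[1]
  if (is.finite(fov[2])) cfg$fov_v_deg <- fov[2]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.runKeys <- c("camera", "score_threshold", "depth_mode", "depth_window",
              "iou_thresholds", "size_breaks", "tile_mode", "tile_size",
              "overlap", "merge_iou", "out_dir", "log_level", "seed")

#' Read a pipeline run configuration
#'
#' YAML file with keys among: `camera` (path to a camera config),
#' `score_threshold`, `depth_mode` (`center`/`edges`), `depth_window`,
#' `iou_thresholds`, `size_breaks`, `tile_mode`, `tile_size`, `overlap`,
#' `merge_iou`, `out_dir`, `log_level`, `seed`. Unknown keys are rejected
#' by name; thresholds are range-checked.
#'
#' @param path YAML file.
#' @return named list of settings merged over defaults.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .runKeys)
  if (length(unknown))
    stop("unknown run config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(
    list(score_threshold = 0.75, depth_mode = "center", depth_window = 3,
         iou_thresholds = c(0.5, 0.75), size_breaks = c(22, 34),
         tile_mode = "corner", merge_iou = 0.5, log_level = "info",
         seed = 1), cfg)
  chk01 <- function(x, nm) if (any(x < 0 | x > 1))
    stop("run config '", nm, "' must lie in [0, 1]")
  chk01(out$score_threshold, "score_threshold")
  chk01(out$iou_thresholds, "iou_thresholds")
  chk01(out$merge_iou, "merge_iou")
  if (!out$depth_mode %in% c("center", "edges"))
    stop("run config 'depth_mode' must be 'center' or 'edges'")
  out
}
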