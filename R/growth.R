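#' Per-object diameter error and error rate
#'
#' `error_mm = |measured - predicted|`, `error_rate_pct = 100 * error /
#' measured`, both reported at 2 decimals (half away from zero), matching
#' the precision of printed caliper-verification tables.
#'
#' @param measured_mm caliper long-axis diameter(s), > 0.
#' @param predicted_mm algorithm long-axis diameter(s).
#' @return data.frame with `error_mm`, `error_rate_pct`.
#' @examples
#' scoreObject(33.64, 31.57)  # 2.07 mm, 6.15 %
#' @export
scoreObject <- function(measured_mm, predicted_mm) {
  if (any(measured_mm <= 0, na.rm = TRUE))
    stop("measured diameter must be positive")
  err <- abs(measured_mm - predicted_mm)
  data.frame(error_mm = roundHalfUp(err, 2),
             error_rate_pct = roundHalfUp(100 * err / measured_mm, 2))
}

#' Summarise verification records for one size class
#'
#' Arithmetic means over the detected records: measured and predicted
#' diameters, error and error rate — the error rate is the mean of the
#' per-object rates, not the ratio of the mean error to the mean measured
#' diameter (the two differ; verification tables print the former).
#' Undetected objects are excluded from every mean but counted in the
#' detection-rate denominator.
#'
#' @param records data.frame with `measured_mm`, `predicted_mm` (`NA` when
#'   undetected); `error_mm`/`error_rate_pct` are recomputed from raw
#'   values if absent.
#' @param n_total total objects in the class, detected or not (default
#'   `nrow(records)`).
#' @return one-row data.frame: `n_detected`, `n_total`,
#'   `mean_measured_mm`, `mean_predicted_mm`, `mean_error_mm`,
#'   `mean_error_rate_pct` (2 decimals), `detection_rate_pct`.
#' @export
summarizeClass <- function(records, n_total = nrow(records)) {
  det <- records[!is.na(records$predicted_mm), , drop = FALSE]
  n <- nrow(det)
  if (n == 0)
    return(data.frame(n_detected = 0L, n_total = n_total,
                      mean_measured_mm = NA_real_, mean_predicted_mm = NA_real_,
                      mean_error_mm = NA_real_, mean_error_rate_pct = NA_real_,
                      detection_rate_pct = 0))
  err <- abs(det$measured_mm - det$predicted_mm)
  rate <- 100 * err / det$measured_mm
  data.frame(
    n_detected = n, n_total = n_total,
    mean_measured_mm = roundHalfUp(mean(det$measured_mm), 2),
    mean_predicted_mm = roundHalfUp(mean(det$predicted_mm), 2),
    mean_error_mm = roundHalfUp(mean(err), 2),
    mean_error_rate_pct = roundHalfUp(mean(rate), 2),
    detection_rate_pct = roundHalfUp(100 * n / n_total, 2))
}

#' Match size estimates to caliper-measured reference objects
#'
#' Links each gated size estimate to the reference object whose box has
#' the highest IoU (at least `iouThreshold`, default 0.5), using the same
#' greedy score-ordered matcher as the detection evaluation; a reference
#' claimed by a higher-scored estimate is unavailable to later ones.
#' References never claimed become undetected records with `NA`
#' prediction. Comparison uses the long axis.
#'
#' @param estimates size-report data.frame (see [sizeReport()]); rows with
#'   `valid = FALSE` are skipped.
#' @param reference data.frame with `object_id`, box corners and
#'   `measured_mm`; optional `image_id`.
#' @param iouThreshold minimum IoU to accept a link.
#' @param sizeBreaks passed to [classifySize()] on the reference boxes.
#' @return verification records: `object_id`, `size_class`, `measured_mm`,
#'   `predicted_mm`, `error_mm`, `error_rate_pct`, `detected`.
#' @export
verificationRecords <- function(estimates, reference, iouThreshold = 0.5,
                                sizeBreaks = c(22, 34)) {
  checkBoxes(reference)
  stopifnot(all(c("object_id", "measured_mm") %in% names(reference)))
  est <- estimates[is.na(estimates$valid) | estimates$valid, , drop = FALSE]
  predicted <- rep(NA_real_, nrow(reference))
  byImage <- function(b) {
    if (!"image_id" %in% names(b)) return(rep("<single>", nrow(b)))
    id <- as.character(b$image_id); id[is.na(id)] <- "<single>"; id
  }
  refIds <- byImage(reference)
  estIds <- byImage(est)
  for (im in unique(refIds)) {
    ri <- which(refIds == im)
    ei <- which(estIds == im)
    if (!length(ei)) next
    m <- matchDetections(est[ei, , drop = FALSE],
                         reference[ri, , drop = FALSE], iouThreshold)
    hit <- !is.na(m$assignment)
    predicted[ri[m$assignment[hit]]] <- est$long_axis_mm[ei[m$order[hit]]]
  }
  sc <- scoreObject(reference$measured_mm, predicted)
  data.frame(object_id = reference$object_id,
             size_class = classifySize(reference, sizeBreaks),
             measured_mm = reference$measured_mm,
             predicted_mm = predicted,
             error_mm = sc$error_mm,
             error_rate_pct = sc$error_rate_pct,
             detected = !is.na(predicted))
}

#' Class-by-class verification summary
#'
#' @param records verification records (see [verificationRecords()] or
#'   [verificationTable()]).
#' @param n_total optional named vector of per-class object totals
#'   (including undetected objects missing from `records`).
#' @return data.frame with one row per size class plus an `"all"` row.
#' @export
summarizeVerification <- function(records, n_total = NULL) {
  classes <- levels(factor(records$size_class,
                           levels = c("small", "medium", "large")))
  rows <- lapply(classes, function(cl) {
    r <- records[records$size_class == cl, , drop = FALSE]
    nt <- if (!is.null(n_total) && cl %in% names(n_total)) n_total[[cl]] else nrow(r)
    cbind(size_class = cl, summarizeClass(r, n_total = nt))
  })
  ntAll <- if (is.null(n_total)) nrow(records) else sum(unlist(n_total))
  rows <- c(rows, list(cbind(size_class = "all",
                             summarizeClass(records, n_total = ntAll))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train/validation/test split bookkeeping
#'
#' Expresses split counts as percentages of their total, at 2 decimals.
#'
#' @param counts numeric vector of per-split counts (e.g.
#'   `c(train = 431, validation = 144, test = 144)`).
#' @return data.frame with `count` and `pct` per split.
#' @examples
#' splitBookkeeping(c(train = 431, validation = 144, test = 144))
#' @export
splitBookkeeping <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  data.frame(split = if (is.null(names(counts))) seq_along(counts) else names(counts),
             count = as.vector(counts),
             pct = roundHalfUp(100 * as.vector(counts) / sum(counts), 2))
}

#' Bundled caliper-verification measurements
#'
#' Per-object caliper (measured) and algorithm (predicted) long-axis
#' diameters from two RGB-D sizing verification scenes: an indoor
#' artificial tree hung with 30 artificial fruits of known diameter
#' (32-37 mm long axis), and an outdoor orchard scene of real fruit
#' (18-32 mm). Only detected objects appear — undetected fruits carry no
#' predicted diameter and are excluded from error averages. Columns:
#' `size_class` (pixel-area class of the object in the verification
#' image), `object_id`, `measured_mm`, `predicted_mm`, and the published
#' `error_mm` / `error_rate_pct` for cross-checking the arithmetic.
#'
#' @param setting `"indoor"` or `"outdoor"`.
#' @return data.frame of verification rows.
#' @export
verificationTable <- function(setting = c("indoor", "outdoor")) {
  setting <- match.arg(setting)
  path <- system.file("extdata", paste0("verification_", setting, ".csv"),
                      package = "rgbdsizer", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$size_class <- factor(df$size_class, levels = c("small", "medium", "large"))
  df
}
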