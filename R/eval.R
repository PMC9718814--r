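#' Classify boxes into small / medium / large
#'
#' Size classes are thresholds on box area expressed as equivalent squares:
#' with breaks `(22, 34)`, a box is small when its area is below
#' `22 x 22 = 484` px^2, large when above `34 x 34 = 1156` px^2, and medium
#' in between. Both boundary areas belong to medium (small is strictly
#' below the first break, large strictly above the second).
#'
#' @param boxes box data.frame.
#' @param breaks two side lengths in pixels, default `c(22, 34)`.
#' @return factor with levels `small`, `medium`, `large`.
#' @export
classifySize <- function(boxes, breaks = c(22, 34)) {
  stopifnot(length(breaks) == 2, breaks[1] > 0, breaks[1] < breaks[2])
  a <- boxArea(boxes)
  cls <- ifelse(a < breaks[1]^2, "small",
                ifelse(a > breaks[2]^2, "large", "medium"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Greedy IoU matching of detections to ground truth (one image)
#'
#' Detections are processed in order of descending score (ties by smaller
#' `x_min`); each claims the still-unmatched ground-truth box with the
#' highest IoU, provided that IoU reaches `iouThreshold` (IoU ties go to
#' the lower ground-truth index). A detection that claims a ground truth is
#' a true positive, otherwise a false positive; ground truths never claimed
#' are false negatives. Each ground truth is matched at most once.
#'
#' For size-stratified evaluation, `gtIgnore` marks ground truths outside
#' the class under evaluation: a detection may still claim one (preference
#' goes to non-ignored candidates), but is then flagged ignored rather than
#' counted, as is an unclaimed detection with `detIgnorable = TRUE` (its
#' own area lies outside the class). Ignored detections and ground truths
#' contribute to neither TP, FP nor FN.
#'
#' @param detections,groundTruth box data.frames for one image.
#' @param iouThreshold minimum IoU for a match.
#' @param gtIgnore logical per ground-truth row (default none ignored).
#' @param detIgnorable logical per detection row.
#' @return a `MatchResult` list: `order` (row indices of `detections` in
#'   processing order), `tp`, `ignored` (per processed detection),
#'   `assignment` (claimed ground-truth row or `NA`), `fn_count`, `n_gt`
#'   (non-ignored ground truths).
#' @export
matchDetections <- function(detections, groundTruth, iouThreshold = 0.5,
                            gtIgnore = NULL, detIgnorable = NULL) {
  checkBoxes(detections); checkBoxes(groundTruth)
  nd <- nrow(detections); ng <- nrow(groundTruth)
  if (nd && (!"score" %in% names(detections) || anyNA(detections$score)))
    stop("matching requires a score on every detection")
  if (is.null(gtIgnore)) gtIgnore <- rep(FALSE, ng)
  if (is.null(detIgnorable)) detIgnorable <- rep(FALSE, nd)

  ord <- if (nd) order(-detections$score, detections$x_min) else integer()
  iou <- iouMatrix(detections, groundTruth)
  claimed <- rep(FALSE, ng)
  tp <- logical(nd); ignored <- logical(nd); assignment <- rep(NA_integer_, nd)

  for (k in seq_len(nd)) {
    i <- ord[k]
    pick <- function(cand) {
      if (!length(cand)) return(NA_integer_)
      ious <- iou[i, cand]
      best <- max(ious)
      if (best < iouThreshold) return(NA_integer_)
      cand[which(ious == best)[1]]   # IoU tie -> lowest ground-truth index
    }
    j <- pick(which(!claimed & !gtIgnore))
    if (is.na(j)) {
      j <- pick(which(!claimed & gtIgnore))
      if (!is.na(j)) ignored[k] <- TRUE          # matched an ignored GT
      else if (detIgnorable[i]) ignored[k] <- TRUE  # FP outside the class
    } else tp[k] <- TRUE
    if (!is.na(j)) { claimed[j] <- TRUE; assignment[k] <- j }
  }
  structure(list(order = ord, tp = tp, ignored = ignored,
                 assignment = assignment,
                 fn_count = sum(!claimed & !gtIgnore),
                 n_gt = sum(!gtIgnore)),
            class = "MatchResult")
}

#' Cumulative precision-recall curve
#'
#' Point `k` of the curve is `(cumTP_k / n_gt, cumTP_k / k)` over the
#' score-ordered detections: precision is correct detections over all
#' detections so far, recall correct detections over all ground truths.
#'
#' @param tp logical vector of true-positive flags in score order (ignored
#'   detections already removed).
#' @param nGt number of (non-ignored) ground truths; must be positive —
#'   recall is undefined otherwise.
#' @return data.frame with columns `recall`, `precision`.
#' @export
prCurve <- function(tp, nGt) {
  if (nGt <= 0) stop("recall is undefined with no ground truth (nGt = 0)")
  if (inherits(tp, "MatchResult")) tp <- tp$tp[!tp$ignored]
  k <- seq_along(tp)
  ctp <- cumsum(tp)
  data.frame(recall = ctp / nGt, precision = if (length(k)) ctp / k else numeric())
}

#' Average precision from a precision-recall curve
#'
#' `"coco101"` (default) is the COCO-style summary: the precision envelope
#' `max{precision at recall >= r}` sampled at the 101 recall levels
#' `0, 0.01, ..., 1` and averaged (levels beyond the highest achieved
#' recall contribute 0). `"pascal_continuous"` integrates the same envelope
#' exactly over recall. Both depend on detections only through their score
#' order, so AP is invariant to monotone rescaling of scores.
#'
#' @param pr data.frame from [prCurve()] (an empty curve gives AP 0).
#' @param method `"coco101"` or `"pascal_continuous"`.
#' @return scalar AP in `[0, 1]`.
#' @export
averagePrecision <- function(pr, method = c("coco101", "pascal_continuous")) {
  method <- match.arg(method)
  if (nrow(pr) == 0) return(0)
  r <- pr$recall; p <- pr$precision
  if (method == "coco101") {
    levels <- seq(0, 1, by = 0.01)
    env <- vapply(levels, function(l) {
      sel <- r >= l - 1e-12
      if (any(sel)) max(p[sel]) else 0
    }, numeric(1))
    mean(env)
  } else {
    # precision envelope is a step function of recall; integrate exactly.
    ord <- order(r, p)
    r <- r[ord]; p <- p[ord]
    env <- rev(cummax(rev(p)))
    rPrev <- c(0, r[-length(r)])
    sum((r - rPrev) * env)
  }
}

#' Evaluate detections against ground truth
#'
#' Runs the full detection-evaluation protocol: per-image greedy IoU
#' matching pooled into a global score-ordered precision-recall curve,
#' with overall AP at each requested IoU threshold plus per-size-class AP
#' and detection rate at IoU 0.5. Stratification keys on ground-truth box
#' area; a detection inherits the class of the ground truth it matches.
#' Out-of-class ground truths and detections are ignored (COCO semantics),
#' not counted as errors, so each stratum is scored only on its own
#' objects.
#'
#' @param detections scored box data.frame; an `image_id` column routes
#'   boxes to images (a detection on an image absent from the ground truth
#'   is an error).
#' @param groundTruth box data.frame (scores ignored).
#' @param iouThresholds IoU thresholds for the overall rows, default
#'   `c(0.5, 0.75)`.
#' @param sizeBreaks side-length breaks for [classifySize()]; `NULL`
#'   disables stratified rows.
#' @param method AP summary passed to [averagePrecision()].
#' @return data.frame with class `EvalResult`: one row per
#'   (iou_threshold, size_class) with `ap`, `detection_rate`, `n_gt`,
#'   `n_det`; the pooled PR curves are in `attr(, "prCurves")`, keyed
#'   `"<iou>/<class>"`. Strata with no ground truth get `NA` AP.
#' @examples
#' gt <- boundingBoxes(c(0, 50), c(0, 50), c(30, 90), c(30, 90))
#' det <- gt; det$score <- c(0.9, 0.8)
#' evaluateDetections(det, gt)  # AP 1 everywhere populated
#' @export
evaluateDetections <- function(detections, groundTruth,
                               iouThresholds = c(0.5, 0.75),
                               sizeBreaks = c(22, 34),
                               method = c("coco101", "pascal_continuous")) {
  method <- match.arg(method)
  checkBoxes(detections); checkBoxes(groundTruth)
  idOf <- function(b) {
    if ("image_id" %in% names(b)) {
      id <- as.character(b$image_id); id[is.na(id)] <- "<single>"; id
    } else rep("<single>", nrow(b))
  }
  dId <- idOf(detections); gId <- idOf(groundTruth)
  imgs <- unique(gId)
  unknown <- setdiff(unique(dId), imgs)
  if (length(unknown))
    stop("detections reference image id(s) absent from ground truth: ",
         paste(unknown, collapse = ", "))

  dSplit <- split(seq_len(nrow(detections)), factor(dId, levels = imgs))
  gSplit <- split(seq_len(nrow(groundTruth)), factor(gId, levels = imgs))

  pooled <- function(thr, cls = NULL) {
    scores <- numeric(); xmins <- numeric(); tp <- logical()
    nGt <- 0L; matchedGt <- 0L; nDet <- 0L
    for (im in imgs) {
      d <- detections[dSplit[[im]], , drop = FALSE]
      g <- groundTruth[gSplit[[im]], , drop = FALSE]
      if (is.null(cls)) {
        gi <- rep(FALSE, nrow(g)); di <- rep(FALSE, nrow(d))
      } else {
        gi <- classifySize(g, sizeBreaks) != cls
        di <- if (nrow(d)) classifySize(d, sizeBreaks) != cls else logical()
      }
      m <- matchDetections(d, g, thr, gtIgnore = gi, detIgnorable = di)
      use <- !m$ignored
      scores <- c(scores, d$score[m$order][use])
      xmins <- c(xmins, d$x_min[m$order][use])
      tp <- c(tp, m$tp[use])
      nGt <- nGt + m$n_gt
      matchedGt <- matchedGt + (m$n_gt - m$fn_count)
      nDet <- nDet + sum(use)
    }
    ord <- order(-scores, xmins)
    list(tp = tp[ord], nGt = nGt, matchedGt = matchedGt, nDet = nDet)
  }

  rows <- list(); curves <- list()
  addRow <- function(thr, clsLabel, pool) {
    ap <- NA_real_; rate <- NA_real_
    if (pool$nGt > 0) {
      pr <- prCurve(pool$tp, pool$nGt)
      ap <- averagePrecision(pr, method)
      rate <- pool$matchedGt / pool$nGt
      curves[[paste0(thr, "/", clsLabel)]] <<- pr
    }
    rows[[length(rows) + 1]] <<- data.frame(
      iou_threshold = thr, size_class = clsLabel, ap = ap,
      detection_rate = rate, n_gt = pool$nGt, n_det = pool$nDet)
  }
  for (thr in iouThresholds) addRow(thr, "all", pooled(thr))
  if (!is.null(sizeBreaks))
    for (cls in c("small", "medium", "large"))
      addRow(0.5, cls, pooled(0.5, cls))

  out <- do.call(rbind, rows)
  attr(out, "prCurves") <- curves
  attr(out, "method") <- method
  class(out) <- c("EvalResult", "data.frame")
  out
}

#' @export
print.EvalResult <- function(x, ...) {
  cat("Detection evaluation (", attr(x, "method"), " AP)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
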