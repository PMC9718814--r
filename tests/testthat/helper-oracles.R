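# Independent reference implementations used as oracles. These are written
# against the plain definitions (scalar arithmetic, explicit loops) and share
# no code with the package internals.

# scalar IoU from first principles
refIoU <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

rowBox <- function(df, i) c(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i])

# reference NMS: repeatedly promote the best remaining box, then discard all
# remaining boxes it suppresses
refNms <- function(boxes, thr) {
  remaining <- boxes[order(-boxes$score, boxes$x_min, boxes$y_min), ,
                     drop = FALSE]
  kept <- NULL
  while (nrow(remaining)) {
    top <- remaining[1, , drop = FALSE]
    kept <- rbind(kept, top)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining)) {
      sup <- vapply(seq_len(nrow(remaining)), function(i)
        refIoU(rowBox(top, 1), rowBox(remaining, i)) >= thr, logical(1))
      remaining <- remaining[!sup, , drop = FALSE]
    }
  }
  rownames(kept) <- NULL
  kept
}

# reference greedy matcher: per-pair scalar IoU, explicit claim loop
refMatch <- function(det, gt, thr) {
  ord <- order(-det$score, det$x_min)
  claimed <- rep(FALSE, nrow(gt))
  tp <- logical(nrow(det))
  for (k in seq_along(ord)) {
    i <- ord[k]
    bestJ <- NA; bestIou <- -1
    for (j in seq_len(nrow(gt))) {
      if (claimed[j]) next
      v <- refIoU(rowBox(det, i), rowBox(gt, j))
      if (v > bestIou) { bestIou <- v; bestJ <- j }
    }
    if (!is.na(bestJ) && bestIou >= thr) {
      claimed[bestJ] <- TRUE
      tp[k] <- TRUE
    }
  }
  list(tp = tp, fn = sum(!claimed))
}

# reference COCO-style AP for a single image: greedy match, then the 101-level
# precision envelope evaluated directly
refAP <- function(det, gt, thr) {
  m <- refMatch(det, gt, thr)
  tp <- m$tp
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(gt)
  total <- 0
  for (level in seq(0, 1, by = 0.01)) {
    best <- 0
    for (k in seq_along(tp))
      if (rec[k] >= level - 1e-12 && prec[k] > best) best <- prec[k]
    total <- total + best
  }
  total / 101
}

# random scored boxes in a W x H canvas
randomBoxes <- function(n, W = 100, H = 100, minSide = 5, maxSide = 25,
                        scored = TRUE) {
  x0 <- runif(n, 0, W - maxSide)
  y0 <- runif(n, 0, H - maxSide)
  w <- runif(n, minSide, maxSide)
  h <- runif(n, minSide, maxSide)
  boundingBoxes(x0, y0, x0 + w, y0 + h,
                score = if (scored) runif(n) else NA_real_)
}
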