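# Detection evaluation: IoU, confidence-ranked greedy matching, precision /
# recall / F1, average precision over the P-R curve, mAP50 and mAP50:95, plus
# the radar-chart normalisation used for cross-model comparison.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`.
#' @export
iou <- function(boxA, boxB) {
  if (boxA[3] <= boxA[1] || boxA[4] <= boxA[2] ||
      boxB[3] <= boxB[1] || boxB[4] <= boxB[2]) {
    stop("degenerate box: x2/y2 must exceed x1/y1")
  }
  iw <- min(boxA[3], boxB[3]) - max(boxA[1], boxB[1])
  ih <- min(boxA[4], boxB[4]) - max(boxA[2], boxB[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  areaA <- (boxA[3] - boxA[1]) * (boxA[4] - boxA[2])
  areaB <- (boxB[3] - boxB[1]) * (boxB[4] - boxB[2])
  inter / (areaA + areaB - inter)
}

# vectorised IoU: rows of A (n,4) against rows of B (m,4) -> (n,m)
iou_matrix <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 4)
  if (!is.matrix(B)) B <- matrix(B, ncol = 4)
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  iw <- outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax)
  ih <- outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  aA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  aB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  out <- inter / (outer(aA, aB, "+") - inter)
  out[!is.finite(out)] <- 0
  out
}

#' Match scored predictions to ground truth boxes
#'
#' Greedy one-to-one matching in descending confidence: each prediction takes
#' the highest-IoU not-yet-matched ground truth provided the IoU reaches the
#' threshold. Unmatched predictions are false positives, unmatched ground
#' truths false negatives.
#' @param preds matrix/data.frame with columns x1,y1,x2,y2,conf
#' @param gts matrix/data.frame with columns x1,y1,x2,y2
#' @param iou_thr IoU threshold (reliability cut, default 0.5)
#' @return a `MatchCounts` list (TP, FP, FN) with per-prediction hit flags
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5) {
  P <- as.matrix(as.data.frame(preds))
  G <- as.matrix(as.data.frame(gts))
  np <- nrow(P) %||% 0L
  ng <- nrow(G) %||% 0L
  if (np == 0) {
    return(structure(list(TP = 0L, FP = 0L, FN = ng, hits = logical(0), order = integer(0)),
                     class = "MatchCounts"))
  }
  ord <- order(-P[, 5])
  hits <- logical(np)
  taken <- logical(ng)
  if (ng > 0) {
    M <- iou_matrix(P[, 1:4, drop = FALSE], G[, 1:4, drop = FALSE])
    for (i in ord) {
      avail <- which(!taken)
      if (length(avail) == 0) break
      j <- avail[which.max(M[i, avail])]
      if (M[i, j] >= iou_thr) {
        hits[i] <- TRUE
        taken[j] <- TRUE
      }
    }
  }
  tp <- sum(hits)
  structure(list(TP = tp, FP = np - tp, FN = ng - tp, hits = hits, order = ord),
            class = "MatchCounts")
}

#' Precision and recall (percent) from match counts
#' @param c a `MatchCounts` (or list with TP, FP, FN)
#' @export
precision_recall <- function(c) {
  P <- if (c$TP + c$FP > 0) 100 * c$TP / (c$TP + c$FP) else 0
  R <- if (c$TP + c$FN > 0) 100 * c$TP / (c$TP + c$FN) else 0
  c(P = P, R = R)
}

#' F1 score on the percentage scale
#' @param P,R precision and recall in percent
#' @export
f1_score <- function(P, R) {
  if (P + R == 0) return(0)
  2 * P * R / (P + R)
}

#' Average precision over the precision-recall curve
#'
#' @param hits logical vector: is each prediction a true positive, in
#'   descending-confidence order
#' @param gt_count number of ground truths (> 0)
#' @param interpolation "101" for 101-point COCO-style interpolation (default)
#'   or "all" for continuous all-point integration
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(hits, gt_count, interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  if (gt_count <= 0) stop("average precision is undefined without ground truths")
  if (length(hits) == 0 || !any(hits)) return(0)
  tp <- cumsum(hits)
  fp <- cumsum(!hits)
  rec <- tp / gt_count
  prec <- tp / (tp + fp)
  # envelope: precision at recall >= r
  penv <- rev(cummax(rev(prec)))
  if (interpolation == "101") {
    rpts <- seq(0, 1, by = 0.01)
    pq <- vapply(rpts, function(r) {
      i <- which(rec >= r)
      if (length(i) == 0) 0 else penv[i[1]]
    }, numeric(1))
    mean(pq)
  } else {
    r0 <- c(0, rec)
    sum((rec - r0[-length(r0)]) * penv)
  }
}

# pool predictions/gts across images at one threshold; preds/gts are lists of
# per-image matrices (x1,y1,x2,y2,conf) / (x1,y1,x2,y2)
ap_at_threshold <- function(preds, gts, thr, interpolation = "101") {
  confs <- numeric(0)
  hits <- logical(0)
  ngt <- 0L
  for (i in seq_along(gts)) {
    p <- preds[[i]]
    g <- gts[[i]]
    ngt <- ngt + (nrow(g) %||% 0L)
    if ((nrow(p) %||% 0L) == 0) next
    mc <- match_detections(p, g, thr)
    confs <- c(confs, p[mc$order, 5])
    hits <- c(hits, mc$hits[mc$order])
  }
  if (ngt == 0) return(NA_real_)
  ord <- order(-confs)
  average_precision(hits[ord], ngt, interpolation)
}

#' Full detection metrics over a prediction/ground-truth set
#'
#' mAP50 is average precision at IoU 0.5; mAP50:95 averages AP over the ten
#' thresholds 0.50 to 0.95 in steps of 0.05. P and R are reported at the
#' confidence that maximises F1 at IoU 0.5.
#' @param preds list of per-image prediction matrices `(x1,y1,x2,y2,conf)`
#' @param gts list of per-image ground-truth matrices `(x1,y1,x2,y2)`
#' @param interpolation AP interpolation rule
#' @return a `DetectionMetrics` list (percent scale)
#' @export
map_metrics <- function(preds, gts, interpolation = "101") {
  stopifnot(length(preds) == length(gts))
  thrs <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thrs, function(t) ap_at_threshold(preds, gts, t, interpolation),
                numeric(1))
  # max-F1 operating point at IoU 0.5
  confs <- sort(unique(unlist(lapply(preds, function(p) if ((nrow(p) %||% 0L) > 0) p[, 5]))),
                decreasing = TRUE)
  best <- list(F1 = -1, P = 0, R = 0)
  for (ct in confs) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(gts)) {
      p <- preds[[i]]
      keep <- if ((nrow(p) %||% 0L) > 0) p[, 5] >= ct else logical(0)
      mc <- match_detections(p[keep, , drop = FALSE], gts[[i]], 0.5)
      tp <- tp + mc$TP; fp <- fp + mc$FP; fn <- fn + mc$FN
    }
    pr <- precision_recall(list(TP = tp, FP = fp, FN = fn))
    f1 <- f1_score(pr["P"], pr["R"])
    if (f1 > best$F1) best <- list(F1 = f1, P = unname(pr["P"]), R = unname(pr["R"]))
  }
  if (best$F1 < 0) best <- list(F1 = 0, P = 0, R = 0)
  structure(list(P = best$P, R = best$R, F1 = best$F1,
                 mAP50 = 100 * aps[1], mAP50_95 = 100 * mean(aps),
                 ap_per_threshold = stats::setNames(100 * aps, sprintf("%.2f", thrs)),
                 N = 1L),
            class = "DetectionMetrics")
}

## ---- radar-chart normalisation ---------------------------------------------

#' Normalise a metric across models for radar-chart comparison
#'
#' Larger-is-better metrics are linearly mapped to `[0,1]`; smaller-is-better
#' metrics (parameter count, compute) are log10-transformed then reverse
#' linearly mapped, so 1 is always best. All-equal inputs map to 1.
#' @param values numeric vector across models
#' @param direction "positive" (larger better) or "negative" (smaller better)
#' @export
normalize_metric <- function(values, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(values) < 2 || max(values) == min(values)) return(rep(1, length(values)))
  if (direction == "positive") {
    (values - min(values)) / (max(values) - min(values))
  } else {
    if (any(values <= 0)) stop("negative-direction values must be positive for the log transform")
    u <- log10(values)
    (max(u) - u) / (max(u) - min(u))
  }
}

#' Area of a radar-chart polygon
#'
#' Vertices sit at radius `values[i]` on `k` equally spaced axes; the area is
#' `0.5 * sum(v_i * v_{i+1}) * sin(2*pi/k)` (cyclic).
#' @param values numeric in `[0,1]`, one per axis
#' @export
radar_polygon_area <- function(values) {
  k <- length(values)
  if (k < 3) stop("a radar polygon needs at least 3 axes")
  nxt <- c(values[-1], values[1])
  0.5 * sum(values * nxt) * sin(2 * pi / k)
}
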