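# Decoding raw head outputs into scored boxes: distribution-focal expectation,
# confidence filtering and non-maximum suppression.

# softmax over bins for a (reg_max, n) matrix of logits
softmax_m <- function(x) {
  e <- exp(sweep(x, 2, apply(x, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

# decode one level's raw outputs for batch element b -> matrix (x1,y1,x2,y2,conf)
decode_level <- function(box_raw, cls_raw, stride, b, reg_max = 16L, conf_thr = 0.25) {
  d <- dim(box_raw)
  H <- d[2]; W <- d[3]
  n <- H * W
  bm <- box_raw[, , , b]; dim(bm) <- c(reg_max, 4L, n)
  probs <- softmax_m(matrix(bm, reg_max, 4L * n))
  e <- matrix(as.numeric(0:(reg_max - 1)) %*% probs, 4L, n)   # ltrb, stride units
  cm <- cls_raw[, , , b]; dim(cm) <- c(dim(cls_raw)[1], n)
  conf <- 1 / (1 + exp(-apply(cm, 2, max)))
  # cell centers; column index (h fastest) matches tensor layout
  hh <- rep(seq_len(H), W) - 0.5
  ww <- rep(seq_len(W), each = H) - 0.5
  keep <- conf >= conf_thr & (e[1, ] + e[3, ]) > 1e-3 & (e[2, ] + e[4, ]) > 1e-3
  if (!any(keep)) return(matrix(numeric(0), 0, 5))
  cbind(x1 = (ww[keep] - e[1, keep]) * stride,
        y1 = (hh[keep] - e[2, keep]) * stride,
        x2 = (ww[keep] + e[3, keep]) * stride,
        y2 = (hh[keep] + e[4, keep]) * stride,
        conf = conf[keep])
}

#' Greedy non-maximum suppression
#' @param boxes matrix `(x1,y1,x2,y2,conf)`
#' @param iou_thr suppression IoU threshold
#' @return filtered matrix
#' @export
nms <- function(boxes, iou_thr = 0.7) {
  if (nrow(boxes) == 0) return(boxes)
  ord <- order(-boxes[, 5])
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    ious <- iou_matrix(boxes[i, 1:4, drop = FALSE], boxes[rest, 1:4, drop = FALSE])
    ord <- rest[ious[1, ] < iou_thr]
  }
  boxes[keep, , drop = FALSE]
}

#' Run detection on one image
#'
#' @param model a `cd_model`
#' @param img `(H, W, 3)` image 0..255, sides multiples of 32
#' @param conf_thr confidence threshold
#' @param iou_thr NMS IoU threshold
#' @return matrix `(x1, y1, x2, y2, conf)` in pixel coordinates
#' @export
predict_boxes <- function(model, img, conf_thr = 0.25, iou_thr = 0.7) {
  x <- img_to_tensor(img)
  outs <- forward_model(model, x, train = FALSE)
  decode_outputs(outs, model$strides, model$reg_max, conf_thr, iou_thr)[[1]]
}

# decode all batch elements of raw head outputs -> list of per-image matrices
decode_outputs <- function(outs, strides, reg_max = 16L, conf_thr = 0.25,
                           iou_thr = 0.7) {
  B <- dim(vval(outs[[1]]$box))[4]
  lapply(seq_len(B), function(b) {
    parts <- lapply(seq_along(outs), function(lv) {
      decode_level(vval(outs[[lv]]$box), vval(outs[[lv]]$cls), strides[lv], b,
                   reg_max, conf_thr)
    })
    nms(do.call(rbind, parts), iou_thr)
  })
}

#' Evaluate a model (or saved predictions) on a scene set
#'
#' @param model a `cd_model`, or `NULL` when `preds` are supplied
#' @param scenes list of scenes (`image` + `labels`) as returned by
#'   [generate_scene()] / in-memory [generate_dataset()]
#' @param preds optional precomputed list of per-image prediction matrices
#' @param conf_thr decoding confidence floor (kept low so the P-R sweep sees
#'   the full curve)
#' @return a `DetectionMetrics`
#' @export
evaluate_scenes <- function(model, scenes, preds = NULL, conf_thr = 0.05,
                            iou_thr = 0.7) {
  gts <- lapply(scenes, function(sc) {
    d <- dim(sc$image)
    yolo_to_xyxy(sc$labels, d[2], d[1])
  })
  if (is.null(preds)) {
    dims <- vapply(scenes, function(sc) dim(sc$image)[1:2], numeric(2))
    if (length(scenes) > 1 && all(dims == dims[, 1])) {
      # uniform sizes: one batched forward pass
      d <- dim(scenes[[1]]$image)
      xb <- array(0, c(3, d[1], d[2], length(scenes)))
      for (k in seq_along(scenes)) xb[, , , k] <- img_to_tensor(scenes[[k]]$image)[, , , 1]
      outs <- forward_model(model, xb, train = FALSE)
      preds <- decode_outputs(outs, model$strides, model$reg_max, conf_thr, iou_thr)
    } else {
      preds <- lapply(scenes, function(sc) {
        predict_boxes(model, sc$image, conf_thr, iou_thr)
      })
    }
  }
  map_metrics(preds, gts)
}
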