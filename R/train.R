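# Training: center-based target assignment, BCE + distribution-focal + IoU
# loss on the decoupled head outputs, SGD with momentum/weight decay/warmup,
# early stopping on validation mAP50, and the online augmentation set.

#' Training configuration
#'
#' Defaults are the published recipe: SGD, learning rate 0.01, momentum 0.937,
#' weight decay 0.0005, batch size 32, 400 epochs at 640 px with early-stopping
#' patience 50; online augmentations are translation, scaling, flipping,
#' Mosaic and Mixup.
#' @export
train_config <- function(optimizer = "SGD", learning_rate = 0.01, momentum = 0.937,
                         weight_decay = 5e-4, batch_size = 32L, epochs = 400L,
                         image_size = 640L, patience = 50L,
                         augmentations = c("translation", "scaling", "flipping",
                                           "mosaic", "mixup"),
                         augment = TRUE,
                         box_gain = 7.5, cls_gain = 0.5, dfl_gain = 1.5,
                         warmup_epochs = 3L, eval_every = 10L,
                         conf_thr = 0.25, nms_iou = 0.7, target_map50 = NULL) {
  stopifnot(learning_rate > 0, momentum >= 0, weight_decay >= 0, batch_size >= 1,
            epochs >= 1, image_size %% 32 == 0, patience >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 image_size = as.integer(image_size), patience = as.integer(patience),
                 augmentations = augmentations, augment = augment,
                 box_gain = box_gain, cls_gain = cls_gain, dfl_gain = dfl_gain,
                 warmup_epochs = as.integer(warmup_epochs),
                 eval_every = as.integer(eval_every),
                 conf_thr = conf_thr, nms_iou = nms_iou,
                 target_map50 = target_map50),
            class = "TrainConfig")
}

## ---- target assignment ------------------------------------------------------

# For one image: boxes (x1,y1,x2,y2) in pixels -> per-level assignment.
# A cell is a candidate for a gt when its center lies inside the box and all
# four ltrb offsets are representable (< reg_max - 1 stride units); each gt
# keeps its top-k closest candidate cells, conflicts go to the nearer gt.
assign_targets <- function(boxes, imgsz, strides, reg_max = 16L, topk = 6L) {
  out <- lapply(seq_along(strides), function(lv) {
    s <- strides[lv]
    H <- imgsz %/% s
    list(H = H, W = H, idx = integer(0), ltrb = matrix(0, 4, 0))
  })
  if (nrow(boxes) == 0) return(out)
  cand <- list()
  for (gi in seq_len(nrow(boxes))) {
    bx <- boxes[gi, ]
    gcx <- (bx[1] + bx[3]) / 2; gcy <- (bx[2] + bx[4]) / 2
    for (lv in seq_along(strides)) {
      s <- strides[lv]
      H <- imgsz %/% s
      hh <- rep(seq_len(H), H) - 0.5          # cell centers, stride units
      ww <- rep(seq_len(H), each = H) - 0.5
      cx <- ww * s; cy <- hh * s
      l <- (cx - bx[1]) / s; t <- (cy - bx[2]) / s
      r <- (bx[3] - cx) / s; b <- (bx[4] - cy) / s
      ok <- l > 0 & t > 0 & r > 0 & b > 0 &
        pmax(l, t, r, b) < reg_max - 1 - 1e-3
      if (!any(ok)) next
      ci <- which(ok)
      d2 <- (cx[ci] - gcx)^2 + (cy[ci] - gcy)^2
      keep <- ci[order(d2)[seq_len(min(topk, length(ci)))]]
      cand[[length(cand) + 1L]] <- data.frame(
        gt = gi, lv = lv, cell = keep,
        dist = d2[match(keep, ci)],
        l = l[keep], t = t[keep], r = r[keep], b = b[keep])
    }
  }
  if (length(cand) == 0) return(out)
  cand <- do.call(rbind, cand)
  # resolve cell conflicts: nearest gt wins
  key <- paste(cand$lv, cand$cell)
  cand <- cand[order(cand$dist), ]
  cand <- cand[!duplicated(paste(cand$lv, cand$cell)), ]
  for (lv in seq_along(strides)) {
    cl <- cand[cand$lv == lv, , drop = FALSE]
    out[[lv]]$idx <- cl$cell
    out[[lv]]$ltrb <- t(as.matrix(cl[, c("l", "t", "r", "b")]))
  }
  out
}

## ---- loss -------------------------------------------------------------------

detect_loss <- function(outs, targets_batch, cfg, reg_max = 16L) {
  nlv <- length(outs)
  B <- dim(vval(outs[[1]]$cls))[4]
  npos <- 0L
  bce_terms <- list(); dfl_terms <- list(); iou_terms <- list()
  for (lv in seq_len(nlv)) {
    cls_raw <- outs[[lv]]$cls
    box_raw <- outs[[lv]]$box
    d <- dim(vval(cls_raw))
    H <- d[2]; W <- d[3]
    n <- H * W
    tgt <- array(0, d)
    pos_cols <- integer(0)
    pos_ltrb <- matrix(0, 4, 0)
    for (b in seq_len(B)) {
      tb <- targets_batch[[b]][[lv]]
      if (length(tb$idx) > 0) {
        tgt[cbind(1L, ((tb$idx - 1L) %% H) + 1L, ((tb$idx - 1L) %/% H) + 1L, b)] <- 1
        pos_cols <- c(pos_cols, tb$idx + (b - 1L) * n)
        pos_ltrb <- cbind(pos_ltrb, tb$ltrb)
      }
    }
    npos <- npos + length(pos_cols)
    bce_terms[[lv]] <- op_bce_logits(cls_raw, tgt)
    if (length(pos_cols) > 0) {
      bm <- op_reshape(box_raw, c(4L * reg_max, n * B))
      sel <- op_cols(bm, pos_cols)                       # (64, npos_lv)
      logits <- op_reshape(sel, c(reg_max, 4L * length(pos_cols)))
      # two-hot distribution targets
      tt <- pmin(pmax(as.vector(pos_ltrb), 0), reg_max - 1 - 1e-3)
      lo <- floor(tt)
      wl <- lo + 1 - tt; wr <- tt - lo
      tdist <- matrix(0, reg_max, length(tt))
      tdist[cbind(lo + 1L, seq_along(tt))] <- wl
      tdist[cbind(pmin(lo + 2L, reg_max), seq_along(tt))] <- tdist[cbind(pmin(lo + 2L, reg_max), seq_along(tt))] + wr
      dfl_terms[[length(dfl_terms) + 1L]] <- op_softce_cols(logits, tdist)
      # IoU loss on decoded expectations (shared cell centers)
      probs <- op_softmax_cols(logits)
      e <- op_reshape(op_mm(matrix(0:(reg_max - 1), 1), probs), c(4L, length(pos_cols)))
      pr <- op_chunk_rows(e)
      tg <- lapply(1:4, function(i) matrix(pos_ltrb[i, ], 1))
      iw <- op_add(op_pmin(pr[[1]], tg[[1]]), op_pmin(pr[[3]], tg[[3]]))
      ih <- op_add(op_pmin(pr[[2]], tg[[2]]), op_pmin(pr[[4]], tg[[4]]))
      inter <- op_mul(iw, ih)
      area_p <- op_mul(op_add(pr[[1]], pr[[3]]), op_add(pr[[2]], pr[[4]]))
      area_t <- (tg[[1]] + tg[[3]]) * (tg[[2]] + tg[[4]])
      uni <- op_sub(op_add(area_p, area_t), inter)
      iou_v <- op_div(inter, uni)
      iou_terms[[length(iou_terms) + 1L]] <- op_sum(iou_v, -1)  # sum of -IoU
    }
  }
  norm <- max(1, npos)
  cls_l <- op_scalar_sum(bce_terms, rep(1 / norm, length(bce_terms)))
  dfl_l <- if (length(dfl_terms)) op_scalar_sum(dfl_terms, rep(1 / norm, length(dfl_terms))) else NULL
  iou_l <- if (length(iou_terms)) {
    # sum(1 - IoU)/norm = npos/norm + sum(-IoU)/norm
    op_scalar_sum(c(iou_terms, list(npos)), c(rep(1 / norm, length(iou_terms)), 1 / norm))
  } else NULL
  terms <- list(cls = cls_l, dfl = dfl_l, box = iou_l)
  total <- op_scalar_sum(Filter(Negate(is.null), list(
    if (!is.null(iou_l)) op_smul(iou_l, cfg$box_gain),
    op_smul(cls_l, cfg$cls_gain),
    if (!is.null(dfl_l)) op_smul(dfl_l, cfg$dfl_gain))))
  list(total = total,
       box = if (is.null(iou_l)) 0 else vval(iou_l),
       cls = vval(cls_l),
       dfl = if (is.null(dfl_l)) 0 else vval(dfl_l),
       npos = npos)
}

# split a (4, n) node into four (1, n) row nodes
op_chunk_rows <- function(x) {
  xv <- vval(x)
  nr <- nrow(xv)
  lapply(seq_len(nr), function(i) {
    rec(xv[i, , drop = FALSE], function(gy) {
      if (is_agv(x)) {
        full <- matrix(0, nr, ncol(xv))
        full[i, ] <- gy
        acc_grad(x, full)
      }
    })
  })
}

## ---- optimizer --------------------------------------------------------------

trainable_fields <- function(m) {
  switch(class(m)[1],
    nn_conv = list(c("w", "gw", TRUE), c("b", "gb", FALSE)),
    nn_linear = list(c("w", "gw", TRUE), c("b", "gb", FALSE)),
    nn_bn = list(c("gamma", "ggamma", FALSE), c("beta", "gbeta", FALSE)),
    nn_gate = list(c("g", "gg", FALSE)),
    list())
}

zero_grads <- function(lvs) {
  for (m in lvs) for (f in trainable_fields(m)) {
    if (!is.null(m[[f[1]]])) m[[f[2]]] <- m[[f[2]]] * 0
  }
  invisible(NULL)
}

sgd_step <- function(lvs, lr, momentum, weight_decay) {
  for (m in lvs) {
    if (!isTRUE(m$trainable)) next
    for (f in trainable_fields(m)) {
      w <- m[[f[1]]]
      if (is.null(w)) next
      g <- m[[f[2]]]
      if (as.logical(f[3]) && weight_decay > 0) g <- g + weight_decay * w
      vname <- paste0(".v_", f[1])
      v <- if (is.null(m[[vname]])) g * 0 else m[[vname]]
      v <- momentum * v + g
      m[[vname]] <- v
      m[[f[1]]] <- w - lr * v
    }
  }
  invisible(NULL)
}

## ---- augmentation -----------------------------------------------------------

aug_hflip <- function(sc) {
  W <- dim(sc$image)[2]
  sc$image <- sc$image[, W:1, , drop = FALSE]
  if (nrow(sc$labels) > 0) sc$labels$cx <- 1 - sc$labels$cx
  sc
}

aug_translate <- function(sc, max_frac = 0.1) {
  d <- dim(sc$image)
  dx <- round(stats::runif(1, -max_frac, max_frac) * d[2])
  dy <- round(stats::runif(1, -max_frac, max_frac) * d[1])
  out <- array(mean(sc$image), d)
  ys <- max(1, 1 - dy):min(d[1], d[1] - dy)
  xs <- max(1, 1 - dx):min(d[2], d[2] - dx)
  out[ys + dy, xs + dx, ] <- sc$image[ys, xs, , drop = FALSE]
  sc$image <- out
  if (nrow(sc$labels) > 0) {
    sc$labels$cx <- sc$labels$cx + dx / d[2]
    sc$labels$cy <- sc$labels$cy + dy / d[1]
    keep <- sc$labels$cx > 0 & sc$labels$cx < 1 & sc$labels$cy > 0 & sc$labels$cy < 1
    sc$labels <- sc$labels[keep, , drop = FALSE]
  }
  sc
}

resize_img <- function(img, H2, W2) {
  d <- dim(img)
  sh <- floor(seq(0, H2 - 1) * d[1] / H2) + 1L
  sw <- floor(seq(0, W2 - 1) * d[2] / W2) + 1L
  img[sh, sw, , drop = FALSE]
}

aug_scale <- function(sc, lo = 0.5, hi = 1.5) {
  d <- dim(sc$image)
  f <- stats::runif(1, lo, hi)
  H2 <- max(32, round(d[1] * f)); W2 <- max(32, round(d[2] * f))
  big <- resize_img(sc$image, H2, W2)
  out <- array(mean(sc$image), d)
  # center crop or pad back to the original canvas
  oy <- max(0, (H2 - d[1]) %/% 2); ox <- max(0, (W2 - d[2]) %/% 2)
  py <- max(0, (d[1] - H2) %/% 2); px <- max(0, (d[2] - W2) %/% 2)
  hh <- min(d[1], H2); ww <- min(d[2], W2)
  out[py + seq_len(hh), px + seq_len(ww), ] <- big[oy + seq_len(hh), ox + seq_len(ww), , drop = FALSE]
  if (nrow(sc$labels) > 0) {
    sc$labels$cx <- (sc$labels$cx * W2 - ox + px) / d[2]
    sc$labels$cy <- (sc$labels$cy * H2 - oy + py) / d[1]
    sc$labels$w <- sc$labels$w * W2 / d[2]
    sc$labels$h <- sc$labels$h * H2 / d[1]
    keep <- sc$labels$cx > 0 & sc$labels$cx < 1 & sc$labels$cy > 0 & sc$labels$cy < 1
    sc$labels <- sc$labels[keep, , drop = FALSE]
  }
  sc$image <- out
  sc
}

aug_mosaic <- function(scs) {
  # 4-image grid at half resolution each
  d <- dim(scs[[1]]$image)
  H <- d[1]; W <- d[2]
  h2 <- H %/% 2; w2 <- W %/% 2
  out <- array(0, d)
  labels <- list()
  offs <- list(c(0, 0), c(0, w2), c(h2, 0), c(h2, w2))
  for (i in 1:4) {
    sm <- resize_img(scs[[i]]$image, h2, w2)
    oy <- offs[[i]][1]; ox <- offs[[i]][2]
    out[oy + seq_len(h2), ox + seq_len(w2), ] <- sm
    lb <- scs[[i]]$labels
    if (nrow(lb) > 0) {
      lb$cx <- (lb$cx * w2 + ox) / W
      lb$cy <- (lb$cy * h2 + oy) / H
      lb$w <- lb$w / 2; lb$h <- lb$h / 2
      labels[[length(labels) + 1L]] <- lb
    }
  }
  list(image = out,
       labels = if (length(labels)) do.call(rbind, labels) else scs[[1]]$labels[0, ])
}

aug_mixup <- function(sc1, sc2, alpha = 8) {
  lam <- stats::rbeta(1, alpha, alpha)
  list(image = lam * sc1$image + (1 - lam) * sc2$image,
       labels = rbind(sc1$labels, sc2$labels))
}

augment_scene <- function(scenes, i, cfg) {
  sc <- scenes[[i]]
  if ("mosaic" %in% cfg$augmentations && stats::runif(1) < 0.5 && length(scenes) >= 4) {
    picks <- c(i, sample(seq_along(scenes), 3, replace = TRUE))
    sc <- aug_mosaic(scenes[picks])
  }
  if ("mixup" %in% cfg$augmentations && stats::runif(1) < 0.15 && length(scenes) >= 2) {
    sc <- aug_mixup(sc, scenes[[sample(seq_along(scenes), 1)]])
  }
  if ("translation" %in% cfg$augmentations && stats::runif(1) < 0.5) sc <- aug_translate(sc)
  if ("scaling" %in% cfg$augmentations && stats::runif(1) < 0.5) sc <- aug_scale(sc)
  if ("flipping" %in% cfg$augmentations && stats::runif(1) < 0.5) sc <- aug_hflip(sc)
  sc
}

# "precise BN": set running statistics to the exact activation statistics of
# one full pass over the given scenes (momentum temporarily 1), so eval-mode
# forward passes match training behaviour even after few optimizer steps.
bn_recalibrate <- function(model, scenes) {
  lvs <- model_leaves(model)
  bns <- Filter(function(m) inherits(m, "nn_bn"), lvs)
  old <- lapply(bns, function(m) m$mom)
  for (m in bns) m$mom <- 1
  imgsz <- dim(scenes[[1]]$image)[1]
  xb <- array(0, c(3, imgsz, imgsz, length(scenes)))
  for (k in seq_along(scenes)) xb[, , , k] <- img_to_tensor(scenes[[k]]$image)[, , , 1]
  forward_model(model, xb, train = TRUE)
  for (i in seq_along(bns)) bns[[i]]$mom <- old[[i]]
  invisible(model)
}

## ---- training loop ----------------------------------------------------------

#' Train a detector
#'
#' @param model a `cd_model`
#' @param scenes training scenes: list of `list(image, labels)` (images must
#'   share the configured size)
#' @param cfg a [train_config()]
#' @param val_scenes scenes used for the early-stopping metric (default: the
#'   training scenes, the overfit setting)
#' @param seed RNG seed controlling shuffling and augmentation
#' @param verbose print per-evaluation progress
#' @return list with the trained `model` and a `history` data.frame of losses
#'   and detection metrics per evaluation point
#' @export
train <- function(model, scenes, cfg = train_config(), val_scenes = scenes,
                  seed = 0L, verbose = FALSE) {
  if (length(scenes) == 0) stop("empty training set")
  lvs <- model_leaves(model)
  imgsz <- dim(scenes[[1]]$image)[1]
  history <- list()
  best <- -Inf; best_epoch <- 0L
  set.seed(seed)
  # cached assignment when no augmentation (images never change)
  cache_tgt <- NULL
  if (!cfg$augment) {
    cache_tgt <- lapply(scenes, function(sc) {
      assign_targets(yolo_to_xyxy(sc$labels, imgsz, imgsz), imgsz, model$strides,
                     model$reg_max)
    })
  }
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (epoch <= cfg$warmup_epochs) {
      cfg$learning_rate * epoch / cfg$warmup_epochs
    } else cfg$learning_rate
    idx <- sample(length(scenes))
    for (start in seq(1, length(idx), by = cfg$batch_size)) {
      bidx <- idx[start:min(start + cfg$batch_size - 1, length(idx))]
      B <- length(bidx)
      xb <- array(0, c(3, imgsz, imgsz, B))
      tgts <- vector("list", B)
      for (k in seq_len(B)) {
        sc <- if (cfg$augment) augment_scene(scenes, bidx[k], cfg) else scenes[[bidx[k]]]
        xb[, , , k] <- img_to_tensor(sc$image)[, , , 1]
        tgts[[k]] <- if (!cfg$augment) cache_tgt[[bidx[k]]] else
          assign_targets(yolo_to_xyxy(sc$labels, imgsz, imgsz), imgsz,
                         model$strides, model$reg_max)
      }
      ag_start()
      xn <- agv(xb)
      outs <- forward_model(model, xn, train = TRUE)
      ls <- detect_loss(outs, tgts, cfg, model$reg_max)
      if (!is.finite(vval(ls$total))) {
        ag_stop()
        stop("non-finite loss at epoch ", epoch, "; aborting")
      }
      ag_backward(ls$total)
      ag_stop()
      sgd_step(lvs, lr / max(1, B), cfg$momentum, cfg$weight_decay)
      zero_grads(lvs)
    }
    if (epoch %% cfg$eval_every == 0 || epoch == cfg$epochs) {
      bn_recalibrate(model, scenes[seq_len(min(16L, length(scenes)))])
      met <- evaluate_scenes(model, val_scenes, conf_thr = min(cfg$conf_thr, 0.05),
                             iou_thr = cfg$nms_iou)
      history[[length(history) + 1L]] <- data.frame(
        epoch = epoch, loss_box = ls$box, loss_cls = ls$cls, loss_dfl = ls$dfl,
        P = met$P, R = met$R, mAP50 = met$mAP50, mAP50_95 = met$mAP50_95)
      if (verbose) {
        cat(sprintf("epoch %d  box %.3f cls %.3f dfl %.3f  mAP50 %.1f\n",
                    epoch, ls$box, ls$cls, ls$dfl, met$mAP50))
      }
      if (met$mAP50 > best + 1e-9) { best <- met$mAP50; best_epoch <- epoch }
      if (!is.null(cfg$target_map50) && met$mAP50 >= cfg$target_map50) break
      if (epoch - best_epoch >= cfg$patience) break
    }
  }
  list(model = model, history = do.call(rbind, history))
}
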