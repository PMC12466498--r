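# Leaf modules and substrate blocks. Modules are environments; `fwd()` is the
# forward generic (works on plain arrays for inference, agv nodes for training).

new_module <- function(.cls, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  class(m) <- c(.cls, "nn_module")
  m
}

#' Forward pass through a module
#'
#' @param m module object
#' @param x input tensor, layout `(C, H, W, B)` (or a list for merge blocks)
#' @param train logical; use batch statistics and record the autodiff tape
#' @return output tensor (or list of tensors for the detection head)
#' @export
fwd <- function(m, x, train = FALSE) UseMethod("fwd")

## ---- leaves ----------------------------------------------------------------

autopad <- function(k, dilation = 1L) (dilation * (k - 1L)) %/% 2L

#' @export
nn_conv2d <- function(cin, cout, k, stride = 1L, pad = NULL, dilation = 1L,
                      groups = 1L, bias = FALSE, trainable = TRUE) {
  stopifnot(cin %% groups == 0, cout %% groups == 0)
  k <- rep(as.integer(k), length.out = 2)
  if (k[1] %% 2 == 0 || k[2] %% 2 == 0) {
    if (is.null(pad)) stop("even kernel sizes require an explicit pad")
  }
  if (is.null(pad)) pad <- c(autopad(k[1], dilation), autopad(k[2], dilation))
  pad <- rep(as.integer(pad), length.out = 2)
  fan_in <- cin / groups * k[1] * k[2]
  w <- matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
  new_module("nn_conv", cin = cin, cout = cout, k = k, stride = as.integer(stride),
             pad = pad, dilation = as.integer(dilation), groups = as.integer(groups),
             w = w, b = if (bias) numeric(cout) else NULL,
             gw = matrix(0, cout, fan_in), gb = if (bias) numeric(cout) else NULL,
             trainable = trainable, has_bn = FALSE)
}

#' @export
fwd.nn_conv <- function(m, x, train = FALSE) op_conv(m, x)

#' @export
nn_bn2d <- function(c, eps = 1e-3, mom = 0.03) {
  new_module("nn_bn", c = c, eps = eps, mom = mom,
             gamma = rep(1, c), beta = numeric(c),
             rm = numeric(c), rv = rep(1, c),
             ggamma = numeric(c), gbeta = numeric(c), trainable = TRUE)
}

#' @export
fwd.nn_bn <- function(m, x, train = FALSE) op_bn(m, x, train)

#' @export
nn_linear <- function(fin, fout, bias = TRUE) {
  w <- matrix(stats::rnorm(fout * fin, sd = sqrt(2 / fin)), fout, fin)
  new_module("nn_linear", fin = fin, fout = fout, w = w,
             b = if (bias) numeric(fout) else NULL,
             gw = matrix(0, fout, fin), gb = if (bias) numeric(fout) else NULL,
             trainable = TRUE)
}

#' @export
fwd.nn_linear <- function(m, x, train = FALSE) op_linear(m, x)

# learnable per-channel gate vector
#' @export
nn_gate <- function(c, init = 0) {
  new_module("nn_gate", c = c, g = rep(init, c), gg = numeric(c), trainable = TRUE)
}

op_gate <- function(m, x) {
  xv <- vval(x)
  d <- dim(xv)
  y <- xv * m$g                       # channel index is fastest -> recycles per channel
  rec(y, function(gy) {
    gm <- gy * xv; dim(gm) <- c(d[1], prod(d[-1]))
    if (isTRUE(m$trainable)) m$gg <- m$gg + rowSums(gm)
    if (is_agv(x)) acc_grad(x, gy * m$g)
  })
}

#' @export
fwd.nn_gate <- function(m, x, train = FALSE) op_gate(m, x)

## ---- CBS and friends -------------------------------------------------------

#' Convolution + batch norm + activation ("CBS" when activation is SiLU)
#'
#' The convolution carries no additive bias (the batch norm supplies it); "same"
#' padding so the output spatial size is ceiling(input/stride).
#' @export
cbs <- function(cin, cout, k = 1L, stride = 1L, groups = 1L, dilation = 1L,
                act = "silu") {
  conv <- nn_conv2d(cin, cout, k, stride, dilation = dilation, groups = groups)
  conv$has_bn <- TRUE
  bn <- nn_bn2d(cout)
  new_module("nn_cbs", conv = conv, bn = bn, act = act, cin = cin, cout = cout,
             children = list(conv = conv, bn = bn))
}

#' @export
fwd.nn_cbs <- function(m, x, train = FALSE) {
  y <- op_bn(m$bn, op_conv(m$conv, x), train)
  switch(m$act,
         silu = op_silu(y),
         sigmoid = op_sigmoid(y),
         none = y,
         stop("unknown activation: ", m$act))
}

# depthwise CBS
dwcbs <- function(c, k = 3L, stride = 1L, act = "silu") cbs(c, c, k, stride, groups = c, act = act)

## ---- substrate blocks ------------------------------------------------------

nn_bottleneck <- function(c1, c2, shortcut = TRUE, k = c(3L, 3L), e = 0.5) {
  ch <- floor(c2 * e)
  cv1 <- cbs(c1, ch, k[1])
  cv2 <- cbs(ch, c2, k[2])
  new_module("nn_bottleneck", cv1 = cv1, cv2 = cv2, add = shortcut && c1 == c2,
             children = list(cv1 = cv1, cv2 = cv2))
}

#' @export
fwd.nn_bottleneck <- function(m, x, train = FALSE) {
  y <- fwd(m$cv2, fwd(m$cv1, x, train), train)
  if (m$add) op_add(x, y) else y
}

nn_c3k <- function(c1, c2, n = 2L, shortcut = TRUE, e = 0.5, k = 3L) {
  ch <- floor(c2 * e)
  cv1 <- cbs(c1, ch, 1L)
  cv2 <- cbs(c1, ch, 1L)
  cv3 <- cbs(2L * ch, c2, 1L)
  ms <- lapply(seq_len(n), function(i) nn_bottleneck(ch, ch, shortcut, k = c(k, k), e = 1.0))
  new_module("nn_c3k", cv1 = cv1, cv2 = cv2, cv3 = cv3, ms = ms,
             children = c(list(cv1 = cv1, cv2 = cv2, cv3 = cv3), ms))
}

#' @export
fwd.nn_c3k <- function(m, x, train = FALSE) {
  a <- fwd(m$cv1, x, train)
  for (blk in m$ms) a <- fwd(blk, a, train)
  b <- fwd(m$cv2, x, train)
  fwd(m$cv3, op_cat(list(a, b)), train)
}

# CSP split-transform-merge stage; `transform` builds the per-repeat block on the
# hidden width, letting MSEIExtractor reuse this layout with a different core.
nn_c3k2 <- function(c1, c2, n = 1L, c3k = FALSE, e = 0.5, shortcut = TRUE,
                    transform = NULL) {
  ch <- floor(c2 * e)
  cv1 <- cbs(c1, 2L * ch, 1L)
  cv2 <- cbs((2L + n) * ch, c2, 1L)
  mk <- transform %||% function(c) if (c3k) nn_c3k(c, c, 2L, shortcut) else
    nn_bottleneck(c, c, shortcut, k = c(3L, 3L), e = 0.5)
  ms <- lapply(seq_len(n), function(i) mk(ch))
  new_module("nn_c3k2", cv1 = cv1, cv2 = cv2, ms = ms, ch = ch,
             children = c(list(cv1 = cv1, cv2 = cv2), ms))
}

#' @export
fwd.nn_c3k2 <- function(m, x, train = FALSE) {
  y <- fwd(m$cv1, x, train)
  parts <- op_chunk(y, c(m$ch, m$ch))
  for (blk in m$ms) parts[[length(parts) + 1L]] <- fwd(blk, parts[[length(parts)]], train)
  fwd(m$cv2, op_cat(parts), train)
}

nn_sppf <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  cv1 <- cbs(c1, ch, 1L)
  cv2 <- cbs(ch * 4L, c2, 1L)
  new_module("nn_sppf", cv1 = cv1, cv2 = cv2, k = k,
             children = list(cv1 = cv1, cv2 = cv2))
}

#' @export
fwd.nn_sppf <- function(m, x, train = FALSE) {
  y <- fwd(m$cv1, x, train)
  p1 <- op_maxpool(y, m$k)
  p2 <- op_maxpool(p1, m$k)
  p3 <- op_maxpool(p2, m$k)
  fwd(m$cv2, op_cat(list(y, p1, p2, p3)), train)
}

nn_attention <- function(dim, num_heads, attn_ratio = 0.5) {
  head_dim <- dim %/% num_heads
  key_dim <- floor(head_dim * attn_ratio)
  h <- dim + key_dim * num_heads * 2L
  qkv <- cbs(dim, h, 1L, act = "none")
  proj <- cbs(dim, dim, 1L, act = "none")
  pe <- cbs(dim, dim, 3L, groups = dim, act = "none")
  new_module("nn_attention", qkv = qkv, proj = proj, pe = pe, dim = dim,
             nh = num_heads, kd = key_dim, hd = head_dim,
             scale = key_dim^(-0.5),
             children = list(qkv = qkv, proj = proj, pe = pe))
}

#' @export
fwd.nn_attention <- function(m, x, train = FALSE) {
  d <- tdim(x); H <- d[2]; W <- d[3]; B <- d[4]
  y <- fwd(m$qkv, x, train)
  sizes <- rep(c(m$kd, m$kd, m$hd), m$nh)
  pieces <- op_chunk(y, sizes)          # head-major: q,k,v per head
  vparts <- pieces[seq(3, length(pieces), by = 3)]
  vfull <- op_cat(vparts)               # (dim, H, W, B)
  outs <- vector("list", B)
  for (b in seq_len(B)) {
    headouts <- vector("list", m$nh)
    for (g in seq_len(m$nh)) {
      q <- op_bslice(pieces[[3 * g - 2]], b)
      k <- op_bslice(pieces[[3 * g - 1]], b)
      v <- op_bslice(pieces[[3 * g]], b)
      logits <- op_smul(op_mm(op_aperm_mat(q), k), m$scale)   # (N,N): query x key
      attn <- op_softmax_rows(logits)
      headouts[[g]] <- op_mm(v, op_aperm_mat(attn))           # (hd, N)
    }
    outs[[b]] <- if (m$nh == 1L) headouts[[1]] else op_rbind(headouts)
  }
  xa <- op_stack_b(outs, H, W)
  fwd(m$proj, op_add(xa, fwd(m$pe, vfull, train)), train)
}

nn_psablock <- function(c) {
  attn <- nn_attention(c, max(1L, c %/% 64L))
  f1 <- cbs(c, c * 2L, 1L)
  f2 <- cbs(c * 2L, c, 1L, act = "none")
  new_module("nn_psablock", attn = attn, f1 = f1, f2 = f2,
             children = list(attn = attn, f1 = f1, f2 = f2))
}

#' @export
fwd.nn_psablock <- function(m, x, train = FALSE) {
  x <- op_add(x, fwd(m$attn, x, train))
  op_add(x, fwd(m$f2, fwd(m$f1, x, train), train))
}

nn_c2psa <- function(c1, n = 1L) {
  ch <- floor(c1 * 0.5)
  cv1 <- cbs(c1, 2L * ch, 1L)
  cv2 <- cbs(2L * ch, c1, 1L)
  ms <- lapply(seq_len(n), function(i) nn_psablock(ch))
  new_module("nn_c2psa", cv1 = cv1, cv2 = cv2, ms = ms, ch = ch,
             children = c(list(cv1 = cv1, cv2 = cv2), ms))
}

#' @export
fwd.nn_c2psa <- function(m, x, train = FALSE) {
  y <- fwd(m$cv1, x, train)
  parts <- op_chunk(y, c(m$ch, m$ch))
  a <- parts[[2]]
  for (blk in m$ms) a <- fwd(blk, a, train)
  fwd(m$cv2, op_cat(list(parts[[1]], a)), train)
}

## ---- graph glue modules ----------------------------------------------------

nn_upsample <- function() new_module("nn_upsample")
#' @export
fwd.nn_upsample <- function(m, x, train = FALSE) op_upsample2(x)

nn_concat <- function() new_module("nn_concat")
#' @export
fwd.nn_concat <- function(m, x, train = FALSE) op_cat(x)

## ---- detection heads -------------------------------------------------------

#' Baseline decoupled detect head with distribution-focal box regression
#'
#' Per pyramid level the box branch emits `4*reg_max` distribution logits and
#' the class branch `nc` logits; tensor layout is identical across all variants
#' so losses and decoding are head-agnostic.
#' @export
nn_detect <- function(nc, ch = c(64L, 128L, 256L), reg_max = 16L) {
  c2 <- max(16L, ch[1] %/% 4L, reg_max * 4L)
  c3 <- max(ch[1], min(nc, 100L))
  box <- lapply(ch, function(x) {
    list(cbs(x, c2, 3L), cbs(c2, c2, 3L), nn_conv2d(c2, 4L * reg_max, 1L, bias = TRUE))
  })
  cls <- lapply(ch, function(x) {
    list(dwcbs(x, 3L), cbs(x, c3, 1L), dwcbs(c3, 3L), cbs(c3, c3, 1L),
         nn_conv2d(c3, nc, 1L, bias = TRUE))
  })
  kids <- c(unlist(box, use.names = FALSE), unlist(cls, use.names = FALSE))
  m <- new_module("nn_detect", nc = nc, reg_max = reg_max, ch = ch, box = box, cls = cls,
                  children = kids)
  init_head_bias(m)
  m
}

# detection-prior initialisation: class logits start near a low objectness prior
init_head_bias <- function(m) {
  for (lv in seq_along(m$cls)) {
    fin <- m$cls[[lv]][[length(m$cls[[lv]])]]
    fin$b[] <- log(0.01 / 0.99)
    bx <- m$box[[lv]][[length(m$box[[lv]])]]
    bx$b[] <- 1.0
  }
  invisible(m)
}

#' @export
fwd.nn_detect <- function(m, x, train = FALSE) {
  lapply(seq_along(x), function(lv) {
    b <- x[[lv]]
    for (blk in m$box[[lv]]) b <- fwd(blk, b, train)
    cl <- x[[lv]]
    for (blk in m$cls[[lv]]) cl <- fwd(blk, cl, train)
    list(box = b, cls = cl)
  })
}

## ---- small matrix helpers used by attention --------------------------------

op_aperm_mat <- function(x) {
  xv <- vval(x)
  rec(t(xv), function(gy) acc_grad(x, t(gy)))
}

op_softmax_rows <- function(x) {
  # softmax over columns for each row (last-dim softmax)
  y <- op_softmax_cols(op_aperm_mat(x))
  op_aperm_mat(y)
}

op_rbind <- function(xs) {
  vs <- lapply(xs, vval)
  rows <- vapply(vs, nrow, numeric(1))
  y <- do.call(rbind, vs)
  rec(y, function(gy) {
    off <- 0
    for (i in seq_along(xs)) {
      acc_grad(xs[[i]], gy[(off + 1):(off + rows[i]), , drop = FALSE])
      off <- off + rows[i]
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
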