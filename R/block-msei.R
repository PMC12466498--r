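# Multi-scale edge information extractor: a CSP stage whose transform path is a
# four-scale pooling pyramid (MSEISelect) with high-frequency residual boosting
# (EIEnhance) and a dual-domain selective attention (DSM).

MSEI_SCALES <- c(3L, 6L, 9L, 12L)

# Internal width constants, frozen once against the printed parameter/compute
# budgets of the ablation tables (see the methods vignette):
#  gate_hidden: hidden width of the DSM spatial gate (constant across stages)
#  hp_cutoff:   radial cutoff (cycles/pixel) of the frequency-branch high-pass
msei_constants <- function() list(gate_hidden = 14L, hp_cutoff = 0.25)

## ---- EIEnhance -------------------------------------------------------------

#' Edge information enhancement
#'
#' Adds back a learnable projection of the high-frequency residual
#' `F - smooth(F)`, where `smooth` is a border-corrected 3x3 box filter
#' (so spatially constant inputs pass through unchanged).
#' @export
nn_eienhance <- function(c) {
  proj <- nn_conv2d(c, c, 1L, bias = TRUE)
  proj$w[] <- proj$w * 0.1
  new_module("nn_eienhance", proj = proj, c = c, children = list(proj = proj))
}

# normalised 3x3 box filter: S = D^-1 A with A the (symmetric) box-sum over
# available neighbours and D the per-pixel neighbour count. Its adjoint is
# S^T = A D^-1: divide by counts first, then box-sum.
box_sum <- function(v) {
  d <- dim(v)
  H <- d[2]; W <- d[3]
  acc <- array(0, d)
  for (dh in -1:1) for (dw in -1:1) {
    hs <- max(1, 1 + dh):min(H, H + dh)
    ht <- max(1, 1 - dh):min(H, H - dh)
    ws <- max(1, 1 + dw):min(W, W + dw)
    wt <- max(1, 1 - dw):min(W, W - dw)
    acc[, ht, wt, ] <- acc[, ht, wt, , drop = FALSE] + v[, hs, ws, , drop = FALSE]
  }
  acc
}

box_counts <- function(d) {
  H <- d[2]; W <- d[3]
  cnt <- matrix(0, H, W)
  for (dh in -1:1) for (dw in -1:1) {
    ht <- max(1, 1 - dh):min(H, H - dh)
    wt <- max(1, 1 - dw):min(W, W - dw)
    cnt[ht, wt] <- cnt[ht, wt] + 1
  }
  aperm(array(cnt, c(H, W, d[1], d[4])), c(3, 1, 2, 4))
}

box_smooth <- function(v) box_sum(v) / box_counts(dim(v))

op_box_residual <- function(x) {
  xv <- vval(x)
  y <- xv - box_smooth(xv)
  rec(y, function(gy) {
    if (is_agv(x)) acc_grad(x, gy - box_sum(gy / box_counts(dim(gy))))
  })
}

#' @export
fwd.nn_eienhance <- function(m, x, train = FALSE) {
  op_add(x, op_conv(m$proj, op_box_residual(x)))
}

## ---- DSM -------------------------------------------------------------------

#' Dual-domain selective attention
#'
#' Spatial branch: a sigmoid-gated convolutional weight map multiplying the
#' input. Frequency branch: radial high-pass of the 2-D spectrum. Learnable
#' per-channel gates fuse both with the input; at initialisation the gates are
#' (residual = 1, spatial = 0, frequency = 0) so the block is the identity.
#' @export
nn_dsm <- function(c, gate_hidden = msei_constants()$gate_hidden,
                   hp_cutoff = msei_constants()$hp_cutoff) {
  g1 <- cbs(c, gate_hidden, 5L)
  g2 <- nn_conv2d(gate_hidden, c, 3L, bias = TRUE)
  gate_res <- nn_gate(c, init = 1)
  gate_sp <- nn_gate(c, init = 0)
  gate_fr <- nn_gate(c, init = 0)
  new_module("nn_dsm", g1 = g1, g2 = g2, gate_res = gate_res, gate_sp = gate_sp,
             gate_fr = gate_fr, c = c, hp_cutoff = hp_cutoff,
             children = list(g1 = g1, g2 = g2, gate_res = gate_res,
                             gate_sp = gate_sp, gate_fr = gate_fr))
}

#' @export
fwd.nn_dsm <- function(m, x, train = FALSE) {
  d <- tdim(x)
  if (d[2] * d[3] < 4) stop("DSM frequency branch needs a spatial extent of at least 4 pixels")
  wmap <- op_sigmoid(op_conv(m$g2, fwd(m$g1, x, train)))
  spat <- op_mul(x, wmap)
  freq <- op_highpass(x, m$hp_cutoff)
  op_add(op_add(op_gate(m$gate_res, x), op_gate(m$gate_sp, spat)),
         op_gate(m$gate_fr, freq))
}

## ---- MSEISelect ------------------------------------------------------------

#' Multi-scale edge information selection
#'
#' Pools the input to 3/6/9/12 pyramid levels, edge-enhances each, projects and
#' resizes back, sums the branches, passes the fused map through the DSM, and
#' re-enters through a zero-initialised output gate so the whole block is the
#' identity at initialisation.
#' @export
nn_mseiselect <- function(c, scales = MSEI_SCALES) {
  eie <- nn_eienhance(c)                      # shared across the four scales
  projs <- lapply(scales, function(s) cbs(c, c, 1L))
  dsm <- nn_dsm(c)
  gate_out <- nn_gate(c, init = 0)
  new_module("nn_mseiselect", eie = eie, projs = projs, dsm = dsm,
             gate_out = gate_out, scales = scales, c = c,
             children = c(list(eie = eie, dsm = dsm, gate_out = gate_out), projs))
}

#' @export
fwd.nn_mseiselect <- function(m, x, train = FALSE) {
  d <- tdim(x); H <- d[2]; W <- d[3]
  fused <- NULL
  for (i in seq_along(m$scales)) {
    s <- m$scales[i]
    p <- op_adaptive_avgpool(x, s)
    e <- fwd(m$eie, p, train)
    b <- fwd(m$projs[[i]], e, train)
    r <- op_resize_nearest(b, H, W)
    fused <- if (is.null(fused)) r else op_add(fused, r)
  }
  sel <- fwd(m$dsm, fused, train)
  op_add(x, op_gate(m$gate_out, sel))
}

## ---- spec-facing op wrappers ------------------------------------------------

#' Edge-enhancement forward pass
#' @param F_map feature map `(C, H, W, B)`
#' @param m optional pre-built [nn_eienhance()] module (fresh weights otherwise)
#' @export
eienhance_forward <- function(F_map, m = NULL) {
  d <- dim(F_map)
  if (length(d) != 4 || d[1] < 1 || d[2] < 1 || d[3] < 1) {
    stop("expected a (C, H, W, B) feature map with C, H, W >= 1")
  }
  fwd(m %||% nn_eienhance(d[1]), F_map)
}

#' Dual-domain selective attention forward pass
#' @param F_map feature map `(C, H, W, B)`; spatial extent must be at least 4
#' @param m optional pre-built [nn_dsm()] module
#' @export
dsm_forward <- function(F_map, m = NULL) {
  fwd(m %||% nn_dsm(dim(F_map)[1]), F_map)
}

#' Multi-scale selection forward pass
#'
#' Requires `H, W >= 12` so the largest pyramid level is a true downsample;
#' resize smaller maps up before calling.
#' @param F_map feature map `(C, H, W, B)`
#' @param m optional pre-built [nn_mseiselect()] module
#' @export
mseiselect_forward <- function(F_map, m = NULL) {
  d <- dim(F_map)
  if (d[2] < 12 || d[3] < 12) {
    stop("spatial size ", d[2], "x", d[3], " is below the largest pyramid ",
         "level (12); resize the map to at least 12x12 first")
  }
  fwd(m %||% nn_mseiselect(d[1]), F_map)
}

#' Extractor-stage forward pass
#' @param F_map feature map `(C, H, W, B)`
#' @param m a pre-built [nn_mseiextractor()] stage (channel counts must match)
#' @export
mseiextractor_forward <- function(F_map, m) {
  if (dim(F_map)[1] != m$cv1$cin) {
    stop("channel mismatch: stage expects ", m$cv1$cin, " input channels, got ",
         dim(F_map)[1])
  }
  fwd(m, F_map)
}

#' Multi-scale edge information extractor stage
#'
#' CSP split-transform-merge layout of the substrate stage block with
#' MSEISelect as the transform path.
#' @export
nn_mseiextractor <- function(c1, c2, n = 1L, e = 0.5) {
  m <- nn_c3k2(c1, c2, n, e = e, transform = function(c) nn_mseiselect(c))
  class(m) <- c("nn_mseiextractor", class(m))
  m
}

#' @export
fwd.nn_mseiextractor <- function(m, x, train = FALSE) fwd.nn_c3k2(m, x, train)
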