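# Multi-scale separation-and-enhancement attention (occlusion attention) and
# the detect head that embeds it in both branches.

# Internal constants frozen once against the printed budget tables: the pooled
# concat is squeezed to channels/16 (SE-style ratio) before re-expansion.
mseam_constants <- function() list(patch_sizes = c(3L, 5L, 7L), fc_reduction = 16L)

#' Multi-scale separation-and-enhancement attention
#'
#' Three non-overlapping patch-embedding branches (kernel = stride = 3/5/7),
#' each followed by a depthwise-separable convolution and SiLU; branch maps and
#' the original features are globally average-pooled, concatenated, passed
#' through a fully connected expansion and a sigmoid, and the resulting
#' per-channel attention vector multiplies the input.
#' @export
nn_multiseam <- function(c, patch_sizes = mseam_constants()$patch_sizes,
                         fc_hidden = max(4L, c %/% mseam_constants()$fc_reduction)) {
  branches <- lapply(patch_sizes, function(k) {
    list(patch = cbs(c, c, k, stride = k, act = "none"),
         dw = cbs(c, c, 3L, groups = c, act = "none"),
         pw = cbs(c, c, 1L, act = "none"))
  })
  fc1 <- nn_linear(4L * c, fc_hidden)
  fc2 <- nn_linear(fc_hidden, c)
  kids <- c(unlist(branches, use.names = FALSE), list(fc1 = fc1, fc2 = fc2))
  new_module("nn_multiseam", branches = branches, patch_sizes = patch_sizes,
             fc1 = fc1, fc2 = fc2, c = c, children = kids)
}

# patch conv needs explicit zero padding = 0 and floor sizing; cbs() defaults to
# "same" padding, so fix the patch convs up at construction time:
fix_patch_pad <- function(m) {
  for (br in m$branches) br$patch$conv$pad <- c(0L, 0L)
  m
}

#' @export
fwd.nn_multiseam <- function(m, x, train = FALSE) {
  d <- tdim(x)
  if (d[2] < max(m$patch_sizes) || d[3] < max(m$patch_sizes)) {
    stop("input spatial size ", d[2], "x", d[3],
         " is smaller than the largest patch (", max(m$patch_sizes), ")")
  }
  pooled <- list(op_gap(x))
  for (br in m$branches) {
    y <- fwd(br$patch, x, train)
    y <- op_silu(fwd(br$pw, fwd(br$dw, y, train), train))
    pooled[[length(pooled) + 1L]] <- op_gap(y)
  }
  z <- op_rbind(pooled)                                  # (4C, B)
  attn <- op_sigmoid(fwd(m$fc2, op_silu(fwd(m$fc1, z, train)), train))
  op_cmul(x, attn)
}

#' Occlusion-attention forward pass
#' @param F_map feature map `(C, H, W, B)` with `H, W >=` the largest patch (7)
#' @param m optional pre-built [nn_multiseam()] module
#' @export
multiseam_forward <- function(F_map, m = NULL) {
  fwd(m %||% fix_patch_pad(nn_multiseam(dim(F_map)[1])), F_map)
}

#' Build the occlusion-attention detect head (spec API)
#' @param num_classes classes (>= 1)
#' @param reg_max distribution-focal bin count
#' @param ch per-level input channels
#' @export
build_dhmseam_head <- function(num_classes = 1L, reg_max = 16L,
                               ch = c(64L, 128L, 256L)) {
  stopifnot(num_classes >= 1)
  nn_dhmseam(num_classes, ch = ch, reg_max = reg_max)
}

#' Occlusion-attention detect head
#'
#' Decoupled head whose box branch replaces the second convolution with
#' MultiSEAM and whose class branch replaces the second depthwise-separable
#' block with MultiSEAM. Raw output layout is identical to the baseline head.
#' @export
nn_dhmseam <- function(nc, ch = c(64L, 128L, 256L), reg_max = 16L) {
  c2 <- max(16L, ch[1] %/% 4L, reg_max * 4L)
  c3 <- max(ch[1], min(nc, 100L))
  box <- lapply(ch, function(x) {
    list(cbs(x, c2, 3L), fix_patch_pad(nn_multiseam(c2)),
         nn_conv2d(c2, 4L * reg_max, 1L, bias = TRUE))
  })
  cls <- lapply(ch, function(x) {
    list(dwcbs(x, 3L), cbs(x, c3, 1L), fix_patch_pad(nn_multiseam(c3)),
         nn_conv2d(c3, nc, 1L, bias = TRUE))
  })
  kids <- c(unlist(box, use.names = FALSE), unlist(cls, use.names = FALSE))
  m <- new_module("nn_detect", nc = nc, reg_max = reg_max, ch = ch, box = box,
                  cls = cls, children = kids)
  class(m) <- c("nn_dhmseam", class(m))
  init_head_bias(m)
  m
}

#' @export
fwd.nn_dhmseam <- function(m, x, train = FALSE) fwd.nn_detect(m, x, train)
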