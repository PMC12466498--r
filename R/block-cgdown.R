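# Context-guided downsampling: stride-2 CBS, dual local/context branches at the
# downsampled resolution, joint activation + 1x1 reduction, and a global channel
# attention bottleneck, fused multiplicatively.

# Internal width constants, frozen once against the printed budget tables (see
# the methods vignette). The context branch width grows with the output channel
# count but is capped at the deepest stage: ctx = min(c2/2 + 40, 136).
cg_constants <- function() list(ctx_alpha = 0.5, ctx_base = 40L, ctx_cap = 136L,
                                reduction = 2L)

cg_ctx_width <- function(c2, k = cg_constants()) {
  min(as.integer(round(k$ctx_alpha * c2 + k$ctx_base)), k$ctx_cap)
}

#' Context-guided downsampling block
#'
#' Halves the spatial extent with a stride-2 3x3 CBS (doubling channels at
#' backbone sites), then fuses a 3x3 depthwise local branch with a dilated
#' (rate 2) context branch, reduces through SiLU + 1x1 CBS, and reweights
#' channels by a squeeze-excitation style global attention.
#' @param c1 input channels
#' @param c2 output channels (backbone convention: `2 * c1`)
#' @export
nn_cgdown <- function(c1, c2 = 2L * c1, reduction = cg_constants()$reduction) {
  if (c2 %% reduction != 0) stop("reduction_ratio must divide out_ch")
  cx <- cg_ctx_width(c2)
  down <- cbs(c1, c2, 3L, 2L)
  local <- cbs(c2, c2, 3L, groups = c2, act = "none")          # FE_Local (DWConv)
  context <- cbs(c2, cx, 3L, dilation = 2L, act = "none")      # FE_Context
  joint <- cbs(c2 + cx, c2, 1L)                                # FE_Joint
  fc1 <- nn_linear(c2, c2 %/% reduction)
  fc2 <- nn_linear(c2 %/% reduction, c2)
  new_module("nn_cgdown", down = down, local = local, context = context,
             joint = joint, fc1 = fc1, fc2 = fc2, c1 = c1, c2 = c2, cx = cx,
             reduction = reduction,
             children = list(down = down, local = local, context = context,
                             joint = joint, fc1 = fc1, fc2 = fc2))
}

#' @export
fwd.nn_cgdown <- function(m, x, train = FALSE) {
  d <- tdim(x)
  if (d[2] %% 2 != 0 || d[3] %% 2 != 0) {
    stop("context-guided downsampling requires even input height/width, got ",
         d[2], "x", d[3])
  }
  dn <- fwd(m$down, x, train)
  l <- fwd(m$local, dn, train)
  cx <- fwd(m$context, dn, train)
  j <- fwd(m$joint, op_silu(op_cat(list(l, cx))), train)
  op_cmul(j, cg_attention_weights(m, j, train))
}

cg_attention_weights <- function(m, j, train = FALSE) {
  g <- op_gap(j)                                               # (C, B)
  op_sigmoid(fwd(m$fc2, op_silu(fwd(m$fc1, g, train)), train))
}

#' Context-guided downsampling forward pass
#' @param F_map feature map `(C, H, W, B)` with even `H`, `W >= 4`
#' @param m optional pre-built [nn_cgdown()] module (backbone doubling default)
#' @export
cgdown_forward <- function(F_map, m = NULL) {
  fwd(m %||% nn_cgdown(dim(F_map)[1]), F_map)
}

#' Global channel attention weights of the context-guided block
#'
#' Squeeze (global average pool), two fully connected layers, sigmoid; returns
#' one weight in (0,1) per output channel and batch element.
#' @param m a `nn_cgdown` module
#' @param j post-reduction feature map `(2C, H, W, B)`
#' @return matrix `(2C, B)` of weights in (0,1)
#' @export
cg_global_attention <- function(m, j) {
  vval(cg_attention_weights(m, j, train = FALSE))
}
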