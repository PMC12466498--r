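# Variant assembly: the ablation grid over the three novel modules.

#' Variant flags
#'
#' The eight combinations map onto the ablation grid: all off = baseline,
#' head only = model1, extractor only = model2, downsampling only = model3,
#' pairwise = model4..model6, all on = the full chicken detector.
#' @param use_dhmseam occlusion-attention detect head
#' @param use_msei multi-scale edge information extractor backbone stages
#' @param use_cgdown context-guided downsampling
#' @return a `VariantFlags` list
#' @export
variant_flags <- function(use_dhmseam = FALSE, use_msei = FALSE, use_cgdown = FALSE) {
  structure(list(use_dhmseam = isTRUE(use_dhmseam), use_msei = isTRUE(use_msei),
                 use_cgdown = isTRUE(use_cgdown)), class = "VariantFlags")
}

#' Named model variants
#' @export
VARIANTS <- list(
  baseline       = c(FALSE, FALSE, FALSE),
  model1         = c(TRUE,  FALSE, FALSE),
  model2         = c(FALSE, TRUE,  FALSE),
  model3         = c(FALSE, FALSE, TRUE),
  model4         = c(TRUE,  TRUE,  FALSE),
  model5         = c(TRUE,  FALSE, TRUE),
  model6         = c(FALSE, TRUE,  TRUE),
  `chicken-yolo` = c(TRUE,  TRUE,  TRUE)
)

flags_for_variant <- function(name) {
  v <- VARIANTS[[name]]
  if (is.null(v)) stop("unknown variant: ", name, " (expected one of ",
                       paste(names(VARIANTS), collapse = ", "), ")")
  variant_flags(v[1], v[2], v[3])
}

#' Build a detector variant
#'
#' @param flags a `VariantFlags` (or variant name string)
#' @param nc number of classes (the housing dataset has one: chicken head-neck)
#' @param width,depth compound scaling; defaults are the nano substrate
#' @return a `cd_model`
#' @export
build_variant <- function(flags = variant_flags(), nc = 1L,
                          width = 0.25, depth = 0.5) {
  if (is.character(flags)) flags <- flags_for_variant(flags)
  stopifnot(inherits(flags, "VariantFlags"), nc >= 1)
  cfg <- model_config(use_msei = flags$use_msei, use_cgdown = flags$use_cgdown,
                      use_dhmseam = flags$use_dhmseam)
  m <- build_model(cfg, nc = nc, width = width, depth = depth)
  m$flags <- flags
  m
}

#' Baseline substrate builder
#'
#' @param num_classes number of classes
#' @return a `cd_model` with P3/P4/P5 outputs at strides 8/16/32
#' @export
build_yolo11n_baseline <- function(num_classes = 1L) {
  build_variant(variant_flags(), nc = num_classes)
}

#' Summaries for all eight variants
#'
#' @param nc number of classes
#' @param imgsz input side for GFLOPs
#' @return data.frame with params (fused), params_millions, gflops per variant
#' @export
summarize_variants <- function(nc = 1L, imgsz = 640L) {
  rows <- lapply(names(VARIANTS), function(nm) {
    m <- build_variant(nm, nc = nc)
    s <- model_summary(m, imgsz)
    data.frame(variant = nm,
               dhmseam = VARIANTS[[nm]][1], msei = VARIANTS[[nm]][2],
               cgdown = VARIANTS[[nm]][3],
               params = s$params_total, params_millions = s$params_millions,
               gflops = s$gflops)
  })
  do.call(rbind, rows)
}

## ---- spec-facing convolution block API --------------------------------------

#' Convolution block specification
#'
#' @param in_ch,out_ch channel counts
#' @param kernel odd kernel size
#' @param stride,dilation,groups convolution geometry
#' @param normalized include batch normalization (conv then carries no bias)
#' @param activation one of "SiLU", "Sigmoid", "none"
#' @return a `ConvBlockSpec`
#' @export
conv_block_spec <- function(in_ch, out_ch, kernel = 3L, stride = 1L,
                            dilation = 1L, groups = 1L, normalized = TRUE,
                            activation = c("SiLU", "Sigmoid", "none")) {
  activation <- match.arg(activation)
  if (kernel %% 2 == 0) stop("even kernel sizes are not supported (kernel = ", kernel, ")")
  if (in_ch %% groups != 0) stop("in_ch must be divisible by groups")
  if (any(c(in_ch, out_ch, stride, dilation, groups) < 1)) stop("all fields must be >= 1")
  structure(list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 dilation = as.integer(dilation), groups = as.integer(groups),
                 normalized = isTRUE(normalized), activation = activation),
            class = "ConvBlockSpec")
}

#' Build a conv (+BN+activation) block from a spec
#' @param spec a [conv_block_spec()]
#' @return an `nn_module` mapping `(B,in_ch,H,W)` to `(B,out_ch,ceil(H/s),ceil(W/s))`
#' @export
build_cbs <- function(spec) {
  stopifnot(inherits(spec, "ConvBlockSpec"))
  act <- c(SiLU = "silu", Sigmoid = "sigmoid", none = "none")[[spec$activation]]
  if (spec$normalized) {
    cbs(spec$in_ch, spec$out_ch, spec$kernel, spec$stride,
        groups = spec$groups, dilation = spec$dilation, act = act)
  } else {
    conv <- nn_conv2d(spec$in_ch, spec$out_ch, spec$kernel, spec$stride,
                      dilation = spec$dilation, groups = spec$groups, bias = TRUE)
    new_module("nn_cbs_nobn", conv = conv, act = act, children = list(conv = conv))
  }
}

#' @export
fwd.nn_cbs_nobn <- function(m, x, train = FALSE) {
  y <- op_conv(m$conv, x)
  switch(m$act, silu = op_silu(y), sigmoid = op_sigmoid(y), none = y)
}

#' Feature-map shape contract
#'
#' @param batch,channels,height,width positive extents
#' @param at_input require height/width divisible by 32 (three detection strides)
#' @export
feature_map_spec <- function(batch, channels, height, width, at_input = FALSE) {
  v <- c(batch = batch, channels = channels, height = height, width = width)
  if (any(v < 1)) stop("all FeatureMapSpec fields must be >= 1")
  if (at_input && (height %% 32 != 0 || width %% 32 != 0)) {
    stop("model input height/width must be multiples of 32")
  }
  structure(as.list(v), class = "FeatureMapSpec")
}
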