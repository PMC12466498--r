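# Layer-graph model container: config rows -> module DAG, forward pass,
# parameter counting and FLOPs profiling.

make_divisible <- function(x, div = 8L) as.integer(max(div, round(x / div) * div))

#' Baseline layer-list configuration (nano-scale substrate)
#'
#' Channels are given at full scale and shrunk by the width multiplier at build
#' time, mirroring the reference family's YAML dialect. `from = 0` is the image,
#' negative values are relative to the previous row.
#' @param use_msei replace the CSP stages of the backbone with the multi-scale
#'   edge information extractor
#' @param use_cgdown replace every stride-2 downsampling convolution of backbone
#'   and neck (P2 onward) with context-guided downsampling
#' @param use_dhmseam use the occlusion-attention detect head
#' @return a list of layer rows
#' @export
model_config <- function(use_msei = FALSE, use_cgdown = FALSE, use_dhmseam = FALSE) {
  stage <- function(cout, c3k, e = 0.5) {
    if (use_msei) list(type = "mseiextractor", cout = cout, n = 2L, e = e)
    else list(type = "c3k2", cout = cout, n = 2L, c3k = c3k, e = e)
  }
  down <- function(cout) {
    if (use_cgdown) list(type = "cgdown", cout = cout)
    else list(type = "cbs", cout = cout, k = 3L, s = 2L)
  }
  head <- if (use_dhmseam) list(type = "dhmseam") else list(type = "detect")
  rows <- list(
    list(type = "cbs", cout = 64L, k = 3L, s = 2L),                 # 1 P1/2
    down(128L),                                                     # 2 P2/4
    stage(256L, c3k = FALSE, e = 0.25),                             # 3
    down(256L),                                                     # 4 P3/8
    stage(512L, c3k = FALSE, e = 0.25),                             # 5
    down(512L),                                                     # 6 P4/16
    stage(512L, c3k = TRUE),                                        # 7
    down(1024L),                                                    # 8 P5/32
    stage(1024L, c3k = TRUE),                                       # 9
    list(type = "sppf", cout = 1024L),                              # 10
    list(type = "c2psa", cout = 1024L, n = 2L),                     # 11
    list(type = "upsample"),                                        # 12
    list(type = "concat", from = c(-1L, 7L)),                       # 13
    list(type = "c3k2", cout = 512L, n = 2L, c3k = FALSE),          # 14
    list(type = "upsample"),                                        # 15
    list(type = "concat", from = c(-1L, 5L)),                       # 16
    list(type = "c3k2", cout = 256L, n = 2L, c3k = FALSE),          # 17 P3 out
    down(256L),                                                     # 18
    list(type = "concat", from = c(-1L, 14L)),                      # 19
    list(type = "c3k2", cout = 512L, n = 2L, c3k = FALSE),          # 20 P4 out
    down(512L),                                                     # 21
    list(type = "concat", from = c(-1L, 11L)),                      # 22
    list(type = "c3k2", cout = 1024L, n = 2L, c3k = TRUE),          # 23 P5 out
    c(list(from = c(17L, 20L, 23L)), head)                          # 24
  )
  # neck downsamplers keep their channel counts (no doubling there)
  rows[[18]]$neck <- TRUE
  rows[[21]]$neck <- TRUE
  rows
}

#' Build a detector from a layer-list configuration
#'
#' @param cfg layer rows from [model_config()]
#' @param nc number of classes
#' @param width,depth,max_ch compound scaling (defaults: nano)
#' @return a `cd_model`
#' @export
build_model <- function(cfg, nc = 1L, width = 0.25, depth = 0.5, max_ch = 1024L) {
  wch <- function(c) make_divisible(min(c, max_ch) * width)
  nrep <- function(n) max(1L, as.integer(round(n * depth)))
  nodes <- vector("list", length(cfg))
  chans <- integer(length(cfg))
  getch <- function(i, self) {
    idx <- ifelse(i < 0L, self + i, i)
    ifelse(idx == 0L, 3L, chans[idx])
  }
  for (i in seq_along(cfg)) {
    row <- cfg[[i]]
    from <- row$from %||% -1L
    cin <- getch(from, i)
    m <- switch(row$type,
      cbs = cbs(cin[1], wch(row$cout), row$k, row$s),
      cgdown = nn_cgdown(cin[1], wch(row$cout)),
      c3k2 = nn_c3k2(cin[1], wch(row$cout), nrep(row$n), row$c3k %||% FALSE,
                     row$e %||% 0.5),
      mseiextractor = nn_mseiextractor(cin[1], wch(row$cout), nrep(row$n),
                                       row$e %||% 0.5),
      sppf = nn_sppf(cin[1], wch(row$cout)),
      c2psa = nn_c2psa(cin[1], nrep(row$n)),
      upsample = nn_upsample(),
      concat = nn_concat(),
      detect = nn_detect(nc, ch = cin),
      dhmseam = nn_dhmseam(nc, ch = cin),
      stop("unknown layer type: ", row$type)
    )
    chans[i] <- switch(row$type,
      cbs = , cgdown = , c3k2 = , mseiextractor = , sppf = wch(row$cout),
      c2psa = cin[1],
      upsample = cin[1],
      concat = sum(cin),
      detect = , dhmseam = 0L
    )
    nodes[[i]] <- list(m = m, from = from, type = row$type)
  }
  model <- new.env(parent = emptyenv())
  model$nodes <- nodes
  model$nc <- nc
  model$cfg <- cfg
  model$width <- width
  model$strides <- c(8L, 16L, 32L)
  model$reg_max <- 16L
  class(model) <- "cd_model"
  model
}

#' Forward pass of a detector
#'
#' @param model a `cd_model`
#' @param x image tensor `(3, H, W, B)`, H and W multiples of 32
#' @param train logical
#' @return list of per-level `list(box, cls)` raw outputs
#' @export
forward_model <- function(model, x, train = FALSE) {
  d <- tdim(x)
  if (d[2] %% 32 != 0 || d[3] %% 32 != 0) {
    stop("input height/width must be multiples of 32, got ", d[2], "x", d[3])
  }
  outs <- vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    from <- ifelse(nd$from < 0L, i + nd$from, nd$from)
    inp <- if (length(from) == 1L) {
      if (from == 0L) x else outs[[from]]
    } else {
      lapply(from, function(j) if (j == 0L) x else outs[[j]])
    }
    outs[[i]] <- fwd(nd$m, inp, train)
  }
  outs[[length(outs)]]
}

## ---- parameter counting ----------------------------------------------------

leaves <- function(m) {
  if (is.list(m)) return(do.call(c, lapply(m, leaves)))
  if (!inherits(m, "nn_module")) return(list())
  kids <- if (!is.null(m$children)) m$children else NULL
  if (is.null(kids)) list(m) else do.call(c, lapply(kids, leaves))
}

model_leaves <- function(model) do.call(c, lapply(model$nodes, function(nd) leaves(nd$m)))

n_params_leaf <- function(m, fused = FALSE) {
  if (!isTRUE(m$trainable)) return(0)
  cls <- class(m)[1]
  switch(cls,
    nn_conv = length(m$w) + length(m$b) + if (fused && isTRUE(m$has_bn)) m$cout else 0,
    nn_bn = if (fused) 0 else 2 * m$c,
    nn_linear = length(m$w) + length(m$b),
    nn_gate = length(m$g),
    0
  )
}

#' Count trainable parameters
#'
#' Counts every trainable weight of the model (or a single module) exactly once.
#' With `fused = TRUE` the count is taken on the inference graph where each
#' convolution absorbs its batch norm (the convolution gains a bias, the norm
#' disappears) -- the convention under which deployment-size budgets are quoted.
#' @param model a `cd_model` or any `nn_module`
#' @param fused count on the conv+BN-folded inference graph
#' @return integer parameter count
#' @export
count_params <- function(model, fused = FALSE) {
  ls <- if (inherits(model, "cd_model")) model_leaves(model) else leaves(model)
  sum(vapply(ls, n_params_leaf, numeric(1), fused = fused))
}

#' Per-layer parameter breakdown
#' @export
per_layer_params <- function(model, fused = TRUE) {
  stopifnot(inherits(model, "cd_model"))
  data.frame(
    layer = seq_along(model$nodes),
    type = vapply(model$nodes, function(nd) nd$type, character(1)),
    params = vapply(model$nodes, function(nd) {
      sum(vapply(leaves(nd$m), n_params_leaf, numeric(1), fused = fused))
    }, numeric(1))
  )
}

## ---- FLOPs profiling -------------------------------------------------------

#' Profile forward-pass compute
#'
#' Runs one forward pass on a zero image and accumulates the analytic cost of
#' every convolution and fully connected layer under the multiply-accumulate
#' times two convention on the fused inference graph (normalisation, activation,
#' pooling and attention matrix products are free, matching the common profiler
#' convention for these budgets).
#' @param model a `cd_model`
#' @param imgsz input side length (multiple of 32)
#' @return GFLOPs (billions of floating point operations per image)
#' @export
profile_flops <- function(model, imgsz = 640L) {
  if (imgsz %% 32 != 0) stop("imgsz must be a multiple of 32")
  x <- array(0, c(3L, imgsz, imgsz, 1L))
  prof_start()
  on.exit(prof_stop(), add = TRUE)
  forward_model(model, x, train = FALSE)
  macs <- .prof$macs
  prof_stop()
  on.exit(NULL)
  2 * macs / 1e9
}

#' Model summary: parameter and compute budget
#'
#' @param model a `cd_model`
#' @param imgsz input side for the FLOPs figure
#' @return a `ModelSummary` list: `params_total` (fused inference graph),
#'   `params_millions` (2 decimals), `gflops` (1 decimal at `imgsz`), `per_layer`
#' @export
model_summary <- function(model, imgsz = 640L) {
  pl <- per_layer_params(model, fused = TRUE)
  pt <- sum(pl$params)
  structure(list(
    params_total = pt,
    params_millions = round(pt / 1e6, 2),
    gflops = round(profile_flops(model, imgsz), 1),
    per_layer = pl
  ), class = "ModelSummary")
}

#' @export
print.ModelSummary <- function(x, ...) {
  cat(sprintf("params: %d (%.2f M)   GFLOPs: %.1f\n",
              x$params_total, x$params_millions, x$gflops))
  invisible(x)
}
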