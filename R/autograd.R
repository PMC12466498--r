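# Minimal reverse-mode autodiff used by the training loop.
#
# Design: there is no separate "tensor" class for inference. Every nn op accepts
# either a plain numeric array (layout C,H,W,B) or an `agv` node. When the tape
# is active (training), ops wrap their output in an agv node carrying a backward
# closure; parameter gradients are accumulated directly into the owning module
# environment, so the optimizer never touches the tape.

.ag <- new.env(parent = emptyenv())
.ag$active <- FALSE
.ag$nodes <- list()
.ag$n <- 0L

ag_active <- function() .ag$active

ag_start <- function() {
  .ag$active <- TRUE
  .ag$nodes <- vector("list", 4096L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_stop <- function() {
  .ag$active <- FALSE
  .ag$nodes <- list()
  .ag$n <- 0L
  invisible(NULL)
}

is_agv <- function(x) inherits(x, "agv")

#' @noRd
agv <- function(v, bw = NULL) {
  node <- new.env(parent = emptyenv())
  node$v <- v
  node$g <- NULL
  node$bw <- bw
  class(node) <- "agv"
  n <- .ag$n + 1L
  if (n > length(.ag$nodes)) .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
  .ag$nodes[[n]] <- node
  .ag$n <- n
  node
}

vval <- function(x) if (is_agv(x)) x$v else x

acc_grad <- function(node, g) {
  if (!is_agv(node)) return(invisible(NULL))
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

# Record an op result. `bw` receives the upstream gradient (same shape as val).
rec <- function(val, bw) {
  if (!.ag$active) return(val)
  agv(val, bw)
}

#' Run reverse-mode backpropagation from a scalar loss node.
#' @noRd
ag_backward <- function(loss) {
  stopifnot(is_agv(loss))
  loss$g <- 1
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$nodes[[i]]
    if (!is.null(node$g) && !is.null(node$bw)) node$bw(node$g)
  }
  invisible(NULL)
}
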