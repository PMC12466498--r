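# Primitive differentiable ops. All image tensors use layout (C, H, W, B).
# Each op accepts plain arrays or agv nodes; when the tape is active the result
# is an agv with a backward closure. Parameter gradients go straight into the
# owning module environment (fields gw/gb/ggamma/...).

.prof <- new.env(parent = emptyenv())
.prof$active <- FALSE
.prof$macs <- 0

prof_start <- function() { .prof$active <- TRUE; .prof$macs <- 0; invisible(NULL) }
prof_stop <- function() { .prof$active <- FALSE; m <- .prof$macs; .prof$macs <- 0; m }

tdim <- function(x) dim(vval(x))

conv_out_len <- function(n, k, s, p, d) (n + 2 * p - d * (k - 1) - 1) %/% s + 1

## ---- convolution -----------------------------------------------------------

op_conv <- function(m, x) {
  xv <- vval(x)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  stopifnot(C == m$cin)
  Ho <- conv_out_len(H, m$k[1], m$stride, m$pad[1], m$dilation)
  Wo <- conv_out_len(W, m$k[2], m$stride, m$pad[2], m$dilation)
  g <- m$groups
  if (.prof$active) {
    .prof$macs <- .prof$macs + as.numeric(Ho) * Wo * m$cout * (m$cin / g * m$k[1] * m$k[2])
  }
  xcol <- cpp_im2col(xv, C, H, W, B, m$k[1], m$k[2], m$stride, m$stride,
                     m$pad[1], m$pad[2], m$dilation, m$dilation)
  n <- ncol(xcol)
  if (g == 1L) {
    y <- m$w %*% xcol
  } else if (g == C && m$cout == C) {
    # depthwise: view xcol as (k2, C, n) and contract over kernel taps
    k2 <- m$k[1] * m$k[2]
    xa <- xcol; dim(xa) <- c(k2, C, n)
    wv <- as.vector(t(m$w))            # length k2*C, tap-fastest
    y <- colSums(xa * wv)              # (C, n)
  } else {
    cg_in <- C %/% g; cg_out <- m$cout %/% g; k2 <- m$k[1] * m$k[2]
    y <- matrix(0, m$cout, n)
    for (gi in seq_len(g)) {
      rin <- ((gi - 1) * cg_in * k2 + 1):(gi * cg_in * k2)
      rout <- ((gi - 1) * cg_out + 1):(gi * cg_out)
      y[rout, ] <- m$w[rout, , drop = FALSE] %*% xcol[rin, , drop = FALSE]
    }
  }
  if (!is.null(m$b)) y <- y + m$b
  dim(y) <- c(m$cout, Ho, Wo, B)
  rec(y, function(gy) {
    dim(gy) <- c(m$cout, Ho * Wo * B)
    if (isTRUE(m$trainable)) {
      if (g == 1L) {
        m$gw <- m$gw + tcrossprod(gy, xcol)
      } else if (g == C && m$cout == C) {
        k2 <- m$k[1] * m$k[2]
        xa <- xcol; dim(xa) <- c(k2, C, n)
        gyr <- gy[rep(seq_len(C), each = k2) + 0L, , drop = FALSE]
        dim(gyr) <- c(k2, C, n)
        dW <- rowSums(xa * gyr, dims = 2)          # (k2, C)
        m$gw <- m$gw + t(dW)
      } else {
        cg_in <- C %/% g; cg_out <- m$cout %/% g; k2 <- m$k[1] * m$k[2]
        for (gi in seq_len(g)) {
          rin <- ((gi - 1) * cg_in * k2 + 1):(gi * cg_in * k2)
          rout <- ((gi - 1) * cg_out + 1):(gi * cg_out)
          m$gw[rout, ] <- m$gw[rout, ] + gy[rout, , drop = FALSE] %*% t(xcol[rin, , drop = FALSE])
        }
      }
      if (!is.null(m$b)) m$gb <- m$gb + rowSums(gy)
    }
    if (is_agv(x)) {
      if (g == 1L) {
        dxcol <- crossprod(m$w, gy)
      } else if (g == C && m$cout == C) {
        k2 <- m$k[1] * m$k[2]
        wv <- as.vector(t(m$w))
        gyr <- gy[rep(seq_len(C), each = k2) + 0L, , drop = FALSE]
        dim(gyr) <- c(k2 * C, n)
        dxcol <- gyr * wv
      } else {
        cg_in <- C %/% g; cg_out <- m$cout %/% g; k2 <- m$k[1] * m$k[2]
        dxcol <- matrix(0, C * k2, n)
        for (gi in seq_len(g)) {
          rin <- ((gi - 1) * cg_in * k2 + 1):(gi * cg_in * k2)
          rout <- ((gi - 1) * cg_out + 1):(gi * cg_out)
          dxcol[rin, ] <- t(m$w[rout, , drop = FALSE]) %*% gy[rout, , drop = FALSE]
        }
      }
      dx <- cpp_col2im(dxcol, C, H, W, B, m$k[1], m$k[2], m$stride, m$stride,
                       m$pad[1], m$pad[2], m$dilation, m$dilation)
      acc_grad(x, dx)
    }
  })
}

## ---- batch normalization ---------------------------------------------------

op_bn <- function(m, x, train = FALSE) {
  xv <- vval(x)
  d <- dim(xv); C <- d[1]; n <- prod(d[-1])
  if (train) {
    fw <- cpp_bn_fwd(xv, C, m$gamma, m$beta, m$eps)
    y <- fw$y; dim(y) <- d
    m$rm <- (1 - m$mom) * m$rm + m$mom * fw$mu
    m$rv <- (1 - m$mom) * m$rv + m$mom * fw$var * n / max(1, n - 1)
    rec(y, function(gy) {
      bw <- cpp_bn_bwd(gy, fw$xhat, fw$invsd, m$gamma, C)
      m$ggamma <- m$ggamma + bw$dgamma
      m$gbeta <- m$gbeta + bw$dbeta
      if (is_agv(x)) {
        dx <- bw$dx; dim(dx) <- d
        acc_grad(x, dx)
      }
    })
  } else {
    xm <- xv; dim(xm) <- c(C, n)
    y <- m$gamma * (xm - m$rm) / sqrt(m$rv + m$eps) + m$beta
    dim(y) <- d
    y
  }
}

## ---- activations & elementwise ---------------------------------------------

op_silu <- function(x) {
  xv <- vval(x)
  fw <- cpp_silu_fwd(xv)
  y <- fw$y
  if (!is.null(dim(xv))) dim(y) <- dim(xv)
  rec(y, function(gy) {
    if (is_agv(x)) {
      dx <- cpp_silu_bwd(gy, xv, fw$s)
      if (!is.null(dim(xv))) dim(dx) <- dim(xv)
      acc_grad(x, dx)
    }
  })
}

op_sigmoid <- function(x) {
  xv <- vval(x)
  s <- 1 / (1 + exp(-xv))
  rec(s, function(gy) if (is_agv(x)) acc_grad(x, gy * s * (1 - s)))
}

op_add <- function(a, b) {
  y <- vval(a) + vval(b)
  rec(y, function(gy) { acc_grad(a, gy); acc_grad(b, gy) })
}

op_sub <- function(a, b) {
  y <- vval(a) - vval(b)
  rec(y, function(gy) { acc_grad(a, gy); acc_grad(b, -gy) })
}

op_mul <- function(a, b) {
  av <- vval(a); bv <- vval(b)
  rec(av * bv, function(gy) { acc_grad(a, gy * bv); acc_grad(b, gy * av) })
}

op_smul <- function(x, s) {  # multiply by a fixed scalar
  rec(vval(x) * s, function(gy) acc_grad(x, gy * s))
}

op_div <- function(a, b) {
  av <- vval(a); bv <- vval(b)
  y <- av / bv
  rec(y, function(gy) { acc_grad(a, gy / bv); acc_grad(b, -gy * av / (bv * bv)) })
}

op_pmax <- function(a, b) {
  av <- vval(a); bv <- vval(b)
  if (length(bv) == 1) bv <- array(bv, dim = dim(av))
  mask <- av >= bv
  rec(pmax(av, bv), function(gy) {
    acc_grad(a, gy * mask)
    acc_grad(b, gy * !mask)
  })
}

op_pmin <- function(a, b) {
  av <- vval(a); bv <- vval(b)
  if (length(bv) == 1) bv <- array(bv, dim = dim(av))
  mask <- av <= bv
  rec(pmin(av, bv), function(gy) {
    acc_grad(a, gy * mask)
    acc_grad(b, gy * !mask)
  })
}

## ---- channel concat / split ------------------------------------------------

op_cat <- function(xs) {
  vs <- lapply(xs, vval)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[1], numeric(1))
  Ct <- sum(cs)
  y <- array(0, c(Ct, d1[2], d1[3], d1[4]))
  off <- 0
  for (i in seq_along(vs)) {
    y[(off + 1):(off + cs[i]), , , ] <- vs[[i]]
    off <- off + cs[i]
  }
  rec(y, function(gy) {
    off <- 0
    for (i in seq_along(xs)) {
      if (is_agv(xs[[i]])) {
        acc_grad(xs[[i]], gy[(off + 1):(off + cs[i]), , , , drop = FALSE])
      }
      off <- off + cs[i]
    }
  })
}

op_chunk <- function(x, sizes) {
  xv <- vval(x)
  d <- dim(xv)
  out <- vector("list", length(sizes))
  off <- 0
  for (i in seq_along(sizes)) {
    sl <- xv[(off + 1):(off + sizes[i]), , , , drop = FALSE]
    local({
      lo <- off + 1L; hi <- off + sizes[i]
      out[[i]] <<- rec(sl, function(gy) {
        if (is_agv(x)) {
          full <- array(0, d)
          full[lo:hi, , , ] <- gy
          acc_grad(x, full)
        }
      })
    })
    off <- off + sizes[i]
  }
  out
}

## ---- pooling / resampling --------------------------------------------------

op_maxpool <- function(x, k, stride = 1L, pad = k %/% 2) {
  xv <- vval(x)
  d <- dim(xv); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  xp <- array(-Inf, c(C, Hp, Wp, B))
  xp[, (pad + 1):(pad + H), (pad + 1):(pad + W), ] <- xv
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  hi <- seq(1L, by = stride, length.out = Ho)
  wi <- seq(1L, by = stride, length.out = Wo)
  y <- array(-Inf, c(C, Ho, Wo, B))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    y <- pmax(y, xp[, hi + i - 1L, wi + j - 1L, , drop = FALSE])
  }
  rec(y, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    dxp <- array(0, c(C, Hp, Wp, B))
    left <- array(TRUE, dim(y))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      sl <- xp[, hi + i - 1L, wi + j - 1L, , drop = FALSE]
      hit <- (sl == y) & left
      left <- left & !hit
      dxp[, hi + i - 1L, wi + j - 1L, ] <- dxp[, hi + i - 1L, wi + j - 1L, , drop = FALSE] + gy * hit
    }
    acc_grad(x, dxp[, (pad + 1):(pad + H), (pad + 1):(pad + W), , drop = FALSE])
  })
}

op_upsample2 <- function(x) {
  xv <- vval(x)
  d <- dim(xv); H <- d[2]; W <- d[3]
  y <- xv[, rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
  rec(y, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    e1 <- seq(1L, 2L * H, by = 2L); e2 <- e1 + 1L
    o1 <- seq(1L, 2L * W, by = 2L); o2 <- o1 + 1L
    dx <- gy[, e1, o1, , drop = FALSE] + gy[, e2, o1, , drop = FALSE] +
      gy[, e1, o2, , drop = FALSE] + gy[, e2, o2, , drop = FALSE]
    acc_grad(x, dx)
  })
}

rowsum_place <- function(m, idx, nlev) {
  # rowsum of matrix m grouped by idx, placed into nlev rows (zero elsewhere)
  rs <- rowsum(m, idx)
  out <- matrix(0, nlev, ncol(m))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

op_resize_nearest <- function(x, ho, wo) {
  xv <- vval(x)
  d <- dim(xv); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  sh <- floor(seq(0, ho - 1) * H / ho) + 1L
  sw <- floor(seq(0, wo - 1) * W / wo) + 1L
  y <- xv[, sh, sw, , drop = FALSE]
  rec(y, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    a <- aperm(gy, c(2, 1, 3, 4)); dim(a) <- c(ho, C * wo * B)
    t1 <- rowsum_place(a, sh, H)                      # (H, C*wo*B)
    dim(t1) <- c(H, C, wo, B)
    a2 <- aperm(t1, c(3, 2, 1, 4)); dim(a2) <- c(wo, C * H * B)
    t2 <- rowsum_place(a2, sw, W)                     # (W, C*H*B)
    dim(t2) <- c(W, C, H, B)
    acc_grad(x, aperm(t2, c(2, 3, 1, 4)))
  })
}

adaptive_bins <- function(n, s) {
  i <- seq_len(s) - 1L
  list(lo = floor(i * n / s) + 1L, hi = ceiling((i + 1) * n / s))
}

op_adaptive_avgpool <- function(x, s) {
  xv <- vval(x)
  d <- dim(xv); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  bh <- adaptive_bins(H, s); bw_ <- adaptive_bins(W, s)
  y <- array(0, c(C, s, s, B))
  for (i in seq_len(s)) for (j in seq_len(s)) {
    blk <- xv[, bh$lo[i]:bh$hi[i], bw_$lo[j]:bw_$hi[j], , drop = FALSE]
    nb <- prod(dim(blk)[2:3])
    dim(blk) <- c(C, nb, B)
    y[, i, j, ] <- colSums(aperm(blk, c(2, 1, 3))) / nb
  }
  rec(y, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    dx <- array(0, d)
    for (i in seq_len(s)) for (j in seq_len(s)) {
      hr <- bh$lo[i]:bh$hi[i]; wr <- bw_$lo[j]:bw_$hi[j]
      nb <- length(hr) * length(wr)
      g <- gy[, i, j, , drop = FALSE] / nb             # (C,1,1,B)
      dx[, hr, wr, ] <- dx[, hr, wr, , drop = FALSE] +
        array(rep(g, each = 1), c(C, 1, 1, B))[, rep(1, length(hr)), rep(1, length(wr)), , drop = FALSE]
    }
    acc_grad(x, dx)
  })
}

op_gap <- function(x) {
  xv <- vval(x)
  d <- dim(xv); C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  xm <- xv; dim(xm) <- c(C, HW, B)
  y <- colSums(aperm(xm, c(2, 1, 3))) / HW             # (C, B)
  rec(y, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    dx <- array(0, c(C, HW, B))
    for (b in seq_len(B)) dx[, , b] <- gy[, b] / HW
    dim(dx) <- d
    acc_grad(x, dx)
  })
}

# multiply tensor (C,H,W,B) by per-channel-per-batch weights a (C,B)
op_cmul <- function(x, a) {
  xv <- vval(x); av <- vval(a)
  d <- dim(xv); C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  ae <- array(0, c(C, HW, B))
  for (b in seq_len(B)) ae[, , b] <- av[, b]
  dim(ae) <- d
  rec(xv * ae, function(gy) {
    acc_grad(x, gy * ae)
    if (is_agv(a)) {
      gm <- gy * xv; dim(gm) <- c(C, HW, B)
      da <- colSums(aperm(gm, c(2, 1, 3)))             # (C,B)
      acc_grad(a, da)
    }
  })
}

## ---- linear / matrix ops ---------------------------------------------------

op_linear <- function(m, x) {
  xv <- vval(x)                                        # (F, B)
  if (.prof$active) .prof$macs <- .prof$macs + as.numeric(m$fin) * m$fout
  y <- m$w %*% xv
  if (!is.null(m$b)) y <- y + m$b
  rec(y, function(gy) {
    if (isTRUE(m$trainable)) {
      m$gw <- m$gw + gy %*% t(xv)
      if (!is.null(m$b)) m$gb <- m$gb + rowSums(gy)
    }
    if (is_agv(x)) acc_grad(x, t(m$w) %*% gy)
  })
}

op_mm <- function(a, b) {
  av <- vval(a); bv <- vval(b)
  rec(av %*% bv, function(gy) {
    acc_grad(a, gy %*% t(bv))
    acc_grad(b, t(av) %*% gy)
  })
}

op_reshape <- function(x, dims) {
  xv <- vval(x)
  d0 <- dim(xv)
  y <- xv; dim(y) <- dims
  rec(y, function(gy) { dim(gy) <- d0; acc_grad(x, gy) })
}

op_aperm <- function(x, perm) {
  xv <- vval(x)
  y <- aperm(xv, perm)
  inv <- order(perm)
  rec(y, function(gy) acc_grad(x, aperm(gy, inv)))
}

op_softmax_cols <- function(x) {
  xv <- vval(x)                                        # matrix, softmax over rows per column
  mx <- apply(xv, 2, max)
  e <- exp(sweep(xv, 2, mx))
  s <- sweep(e, 2, colSums(e), "/")
  rec(s, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    dot <- colSums(gy * s)
    acc_grad(x, s * sweep(gy, 2, dot))
  })
}

## ---- spectral high-pass ----------------------------------------------------

radial_hp_mask <- function(H, W, cutoff) {
  fh <- c(0:(H %/% 2), if (H > 1) -((H - (H %/% 2) - 1):1)) / H
  fw <- c(0:(W %/% 2), if (W > 1) -((W - (W %/% 2) - 1):1)) / W
  r <- sqrt(outer(fh^2, fw^2, "+"))
  (r >= cutoff) * 1
}

# Linear, self-adjoint (real symmetric mask) high-pass via 2-D FFT, per channel/batch.
op_highpass <- function(x, cutoff = 0.25) {
  xv <- vval(x)
  d <- dim(xv); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  mask <- radial_hp_mask(H, W, cutoff)
  apply_hp <- function(v) {
    out <- array(0, d)
    for (b in seq_len(B)) for (c in seq_len(C)) {
      X <- stats::fft(matrix(v[c, , , b], H, W))
      out[c, , , b] <- Re(stats::fft(X * mask, inverse = TRUE)) / (H * W)
    }
    out
  }
  y <- apply_hp(xv)
  rec(y, function(gy) if (is_agv(x)) acc_grad(x, apply_hp(gy)))
}

# gather columns of a matrix (scatter-add on the way back)
op_cols <- function(x, idx) {
  xv <- vval(x)
  d <- dim(xv)
  y <- xv[, idx, drop = FALSE]
  rec(y, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    dx <- matrix(0, d[1], d[2])
    for (k in seq_along(idx)) dx[, idx[k]] <- dx[, idx[k]] + gy[, k]
    acc_grad(x, dx)
  })
}

## ---- batch slicing (attention heads) ---------------------------------------

# Extract batch b as a (C, H*W) matrix
op_bslice <- function(x, b) {
  xv <- vval(x)
  d <- dim(xv)
  y <- xv[, , , b, drop = FALSE]
  dim(y) <- c(d[1], d[2] * d[3])
  rec(y, function(gy) {
    if (!is_agv(x)) return(invisible(NULL))
    full <- array(0, d)
    full[, , , b] <- gy
    acc_grad(x, full)
  })
}

# Stack a list of (C, H*W) matrices (one per batch) into (C,H,W,B)
op_stack_b <- function(xs, H, W) {
  B <- length(xs)
  C <- nrow(vval(xs[[1]]))
  y <- array(0, c(C, H, W, B))
  for (b in seq_len(B)) y[, , , b] <- vval(xs[[b]])
  rec(y, function(gy) {
    for (b in seq_len(B)) {
      if (is_agv(xs[[b]])) {
        g <- gy[, , , b, drop = FALSE]
        dim(g) <- c(C, H * W)
        acc_grad(xs[[b]], g)
      }
    }
  })
}

## ---- scalar reductions / losses --------------------------------------------

op_sum <- function(x, w = 1) {
  xv <- vval(x)
  y <- sum(xv * w)
  d <- dim(xv)
  rec(y, function(gy) {
    g <- if (length(w) == 1) array(gy * w, d) else gy * w
    if (is.null(dim(g)) && !is.null(d)) dim(g) <- d
    acc_grad(x, g)
  })
}

op_scalar_sum <- function(xs, ws = rep(1, length(xs))) {
  y <- 0
  for (i in seq_along(xs)) y <- y + ws[i] * vval(xs[[i]])
  rec(y, function(gy) for (i in seq_along(xs)) acc_grad(xs[[i]], gy * ws[i]))
}

# binary cross-entropy with logits; elementwise weights w; returns sum
op_bce_logits <- function(x, target, w = 1) {
  xv <- vval(x)
  s <- 1 / (1 + exp(-xv))
  eps <- 1e-12
  loss <- sum(w * (-(target * log(s + eps) + (1 - target) * log(1 - s + eps))))
  d <- dim(xv)
  rec(loss, function(gy) {
    g <- gy * w * (s - target)
    if (!is.null(d)) dim(g) <- d
    acc_grad(x, g)
  })
}

# cross-entropy between column-softmax of logits (K,n) and target distributions (K,n),
# with per-column weights; returns sum over columns
op_softce_cols <- function(logits, tdist, wcol = 1) {
  xv <- vval(logits)
  mx <- apply(xv, 2, max)
  e <- exp(sweep(xv, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  loss <- -sum(sweep(tdist * log(p + 1e-12), 2, wcol, "*"))
  rec(loss, function(gy) {
    g <- sweep(p - tdist, 2, wcol, "*") * gy
    acc_grad(logits, g)
  })
}
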