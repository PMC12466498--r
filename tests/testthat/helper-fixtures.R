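# Shared fixtures and independent oracles. Everything is generated in code;
# nothing is read from disk.

cd <- function(name) get(name, envir = asNamespace("cagedetect"))

rand_tensor <- function(C, H, W, B = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(C * H * W * B), c(C, H, W, B))
}

# central finite-difference gradient of scalar-valued f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# input-gradient check of a module via the tape (loss = sum(y * sin weights))
grad_check_module <- function(make_mod, C, H, W, B = 2, train = TRUE, seed = 7) {
  set.seed(seed)
  m <- make_mod()
  x <- rand_tensor(C, H, W, B)
  lossfun <- function(xx) {
    y <- cd("vval")(fwd(m, xx, train = train))
    sum(y * array(sin(seq_along(y)), dim(y)))
  }
  cd("ag_start")()
  xn <- cd("agv")(x)
  y <- fwd(m, xn, train = train)
  lw <- array(sin(seq_along(cd("vval")(y))), dim(cd("vval")(y)))
  loss <- cd("op_sum")(y, lw)
  cd("ag_backward")(loss)
  ga <- xn$g
  cd("ag_stop")()
  gn <- num_grad(lossfun, x)
  max(abs(ga - gn)) / max(1e-8, max(abs(gn)))
}

# ---- independent detection-metric oracle ------------------------------------
# Deliberately separate implementation: quadratic loops, all-point integration
# with explicit rectangle sums, no shared helpers with the package.

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

oracle_ap <- function(preds, gts, thr) {
  # preds/gts: lists of per-image matrices; returns all-point AP
  recs <- list()
  ngt <- 0
  allconf <- c(); allhit <- c()
  for (i in seq_along(gts)) {
    g <- gts[[i]]
    ngt <- ngt + nrow(g)
    p <- preds[[i]]
    if (nrow(p) == 0) next
    p <- p[order(p[, 5], decreasing = TRUE), , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    for (k in seq_len(nrow(p))) {
      best <- 0; bj <- 0
      if (nrow(g) > 0) for (j in seq_len(nrow(g))) {
        if (used[j]) next
        v <- oracle_iou(p[k, 1:4], g[j, 1:4])
        if (v > best) { best <- v; bj <- j }
      }
      hit <- best >= thr && bj > 0
      if (hit) used[bj] <- TRUE
      allconf <- c(allconf, p[k, 5]); allhit <- c(allhit, hit)
    }
  }
  if (ngt == 0) return(NA_real_)
  if (length(allhit) == 0 || !any(allhit)) return(0)
  o <- order(allconf, decreasing = TRUE)
  h <- allhit[o]
  tp <- cumsum(h); fp <- cumsum(!h)
  rec <- tp / ngt; prec <- tp / (tp + fp)
  # all-point AP with precision envelope
  ap <- 0; prev_r <- 0
  penv <- rev(cummax(rev(prec)))
  for (k in seq_along(rec)) {
    ap <- ap + (rec[k] - prev_r) * penv[k]
    prev_r <- rec[k]
  }
  ap
}

# small random detection instances for the equivalence suite
random_instance <- function(seed, n_img = 3, max_boxes = 6) {
  set.seed(seed)
  gts <- lapply(seq_len(n_img), function(i) {
    n <- sample(0:max_boxes, 1)
    if (n == 0) return(matrix(numeric(0), 0, 4))
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    cbind(x1, y1, x1 + runif(n, 5, 20), y1 + runif(n, 5, 20))
  })
  preds <- lapply(gts, function(g) {
    base <- if (nrow(g) > 0) g[sample(nrow(g), nrow(g), replace = TRUE), , drop = FALSE] else
      matrix(numeric(0), 0, 4)
    if (nrow(base) > 0) base <- base + matrix(rnorm(4 * nrow(base), sd = 3), nrow(base), 4)
    extra <- sample(0:3, 1)
    px1 <- runif(extra, 0, 80); py1 <- runif(extra, 0, 80)
    ex <- matrix(c(px1, py1, px1 + runif(extra, 5, 20), py1 + runif(extra, 5, 20)),
                 ncol = 4)
    all <- rbind(base, ex)
    if (nrow(all) == 0) return(matrix(numeric(0), 0, 5))
    all[, 3] <- pmax(all[, 3], all[, 1] + 1)
    all[, 4] <- pmax(all[, 4], all[, 2] + 1)
    cbind(all, runif(nrow(all)))
  })
  list(preds = preds, gts = gts)
}

tiny_scenes <- function(n = 4, imgsz = 160, n_chickens = 2, seed0 = 200) {
  lapply(seq_len(n), function(i) {
    generate_scene(scene_spec(n_chickens = n_chickens, tier = "upper",
                              seed = seed0 + i, imgsz = imgsz))
  })
}
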