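# Multi-stage annotation-enhancement pipeline: directional HSV saturation boost
# (comb red targeted), gamma brightening, CLAHE on the luminance plane, and
# edge-aware (bilateral) denoising -- used ONLY to make dark/occluded birds
# annotatable; enhanced frames never enter the train/val/test sets.

#' Enhancement parameters
#'
#' No numeric constants for this pipeline are published; the defaults shipped
#' here are the package's own documented choices ("unspecified upstream").
#' @param red_hue_band hue interval in degrees targeting comb red (wraps at 360)
#' @param sat_gain_red,sat_gain_global multiplicative saturation gains (>= 1)
#' @param gamma brightening exponent in (0, 1]
#' @param clahe_clip CLAHE clip limit (multiples of the mean bin height, > 0)
#' @param clahe_tiles CLAHE tile grid side (>= 2)
#' @param denoise_sigma_s,denoise_sigma_r bilateral spatial / range sigmas
#' @return an `EnhanceParams` list
#' @export
enhance_params <- function(red_hue_band = c(330, 30), sat_gain_red = 1.4,
                           sat_gain_global = 1.15, gamma = 0.6,
                           clahe_clip = 2.0, clahe_tiles = 8L,
                           denoise_sigma_s = 1.5, denoise_sigma_r = 20) {
  if (sat_gain_red < 1 || sat_gain_global < 1) stop("saturation gains must be >= 1")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (clahe_clip <= 0) stop("clahe_clip must be > 0")
  if (clahe_tiles < 2) stop("clahe_tiles must be >= 2")
  structure(list(red_hue_band = red_hue_band, sat_gain_red = sat_gain_red,
                 sat_gain_global = sat_gain_global, gamma = gamma,
                 clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 denoise_sigma_s = denoise_sigma_s, denoise_sigma_r = denoise_sigma_r),
            class = "EnhanceParams")
}

check_img <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("expected a 3-channel (H, W, 3) image")
  }
  invisible(img)
}

hsv_to_rgb <- function(h, s, v) {
  # h in [0,1), s,v in [0,1]; returns 3 x n matrix in [0,1]
  h6 <- (h * 6) %% 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Directional saturation enhancement in HSV space
#'
#' Saturation is multiplied by `sat_gain_red` inside the red hue band (comb)
#' and by `sat_gain_global` elsewhere, clipped at channel maximum; hue and
#' value are untouched.
#' @param img `(H, W, 3)` image, 0..255
#' @param p an [enhance_params()]
#' @export
saturation_boost <- function(img, p = enhance_params()) {
  check_img(img)
  d <- dim(img)
  px <- t(matrix(img, d[1] * d[2], 3))                 # 3 x n
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  hdeg <- hsv[1, ] * 360
  lo <- p$red_hue_band[1]; hi <- p$red_hue_band[2]
  in_band <- if (lo <= hi) hdeg >= lo & hdeg <= hi else hdeg >= lo | hdeg <= hi
  gain <- ifelse(in_band, p$sat_gain_red, p$sat_gain_global)
  s2 <- pmin(1, hsv[2, ] * gain)
  out <- hsv_to_rgb(hsv[1, ], s2, hsv[3, ]) * 255
  array(t(out), d)
}

#' Gamma correction
#'
#' `v -> v_max * (v / v_max)^gamma`; endpoints 0 and `v_max` are fixed and
#' `gamma < 1` brightens.
#' @param img `(H, W, 3)` image, 0..255
#' @param gamma exponent (> 0)
#' @export
gamma_correct <- function(img, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  check_img(img)
  255 * (pmax(img, 0) / 255)^gamma
}

# contrast-limited adaptive histogram equalisation of one plane (0..255 scale)
clahe_plane <- function(x, clip = 2.0, tiles = 8L, nbins = 256L) {
  H <- nrow(x); W <- ncol(x)
  xb <- as.integer(floor(x))
  xb[xb < 0L] <- 0L
  xb[xb > nbins - 1L] <- nbins - 1L
  dim(xb) <- c(H, W)
  ty <- floor(seq(0, H, length.out = tiles + 1))
  tx <- floor(seq(0, W, length.out = tiles + 1))
  cy <- (ty[-1] + ty[-(tiles + 1)] + 1) / 2            # tile centers (1-based-ish)
  cx <- (tx[-1] + tx[-(tiles + 1)] + 1) / 2
  maps <- array(0, c(tiles, tiles, nbins))
  for (i in seq_len(tiles)) for (j in seq_len(tiles)) {
    blk <- xb[(ty[i] + 1):ty[i + 1], (tx[j] + 1):tx[j + 1]]
    h <- tabulate(blk + 1L, nbins)
    n <- length(blk)
    lim <- max(1, clip * n / nbins)
    excess <- sum(pmax(h - lim, 0))
    h <- pmin(h, lim) + excess / nbins
    cdf <- cumsum(h) / n
    maps[i, j, ] <- cdf * (nbins - 1)
  }
  # bilinear interpolation between the four surrounding tile mappings
  ri <- findInterval(seq_len(H), cy)                   # lower tile index (0..tiles)
  ci <- findInterval(seq_len(W), cx)
  r0 <- pmax(ri, 1); r1 <- pmin(ri + 1, tiles)
  c0 <- pmax(ci, 1); c1 <- pmin(ci + 1, tiles)
  wy <- ifelse(r1 == r0, 0, (seq_len(H) - cy[r0]) / (cy[r1] - cy[r0]))
  wx <- ifelse(c1 == c0, 0, (seq_len(W) - cx[c0]) / (cx[c1] - cx[c0]))
  wy <- pmax(0, pmin(1, wy)); wx <- pmax(0, pmin(1, wx))
  out <- matrix(0, H, W)
  bin <- xb + 1L
  idx <- function(r, c) {
    # lookup maps[r[row], c[col], bin[row,col]] vectorised
    rr <- matrix(r, H, W); cc <- matrix(c, H, W, byrow = TRUE)
    maps[cbind(as.vector(rr), as.vector(cc), as.vector(bin))]
  }
  v00 <- idx(r0, c0); v01 <- idx(r0, c1); v10 <- idx(r1, c0); v11 <- idx(r1, c1)
  WY <- matrix(wy, H, W); WX <- matrix(wx, H, W, byrow = TRUE)
  out <- (1 - WY) * ((1 - WX) * v00 + WX * v01) + WY * ((1 - WX) * v10 + WX * v11)
  matrix(out, H, W)
}

#' CLAHE on the luminance plane
#'
#' The image is taken to CIE Lab, contrast-limited adaptive histogram
#' equalisation is applied to L only, and the result is recomposed; the
#' chrominance planes are untouched.
#' @param img `(H, W, 3)` image, 0..255
#' @param clip clip limit
#' @param tiles tile grid side
#' @export
clahe_luminance <- function(img, clip = 2.0, tiles = 8L) {
  check_img(img)
  d <- dim(img)
  srgb <- matrix(img, d[1] * d[2], 3) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1], d[1], d[2])                    # 0..100
  if (max(L) - min(L) < 1e-9) return(img)              # constant image fixed point
  L2 <- clahe_plane(L * 255 / 100, clip, tiles) * 100 / 255
  lab[, 1] <- as.vector(L2)
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(pmax(0, pmin(1, out)) * 255, d)
}

#' Edge-aware (bilateral) denoising
#'
#' Gaussian spatial kernel modulated by a Gaussian range kernel on luminance
#' differences: variance shrinks in flat regions while step edges survive.
#' @param img `(H, W, 3)` image, 0..255
#' @param p an [enhance_params()] (sigma fields used)
#' @export
edge_denoise <- function(img, p = enhance_params()) {
  check_img(img)
  d <- dim(img)
  r <- max(1L, ceiling(2 * p$denoise_sigma_s))
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  H <- d[1]; W <- d[2]
  acc <- array(0, d)
  wacc <- matrix(0, H, W)
  for (dh in -r:r) for (dw in -r:r) {
    hs <- max(1, 1 + dh):min(H, H + dh)
    ht <- max(1, 1 - dh):min(H, H - dh)
    ws <- max(1, 1 + dw):min(W, W + dw)
    wt <- max(1, 1 - dw):min(W, W - dw)
    wsp <- exp(-(dh^2 + dw^2) / (2 * p$denoise_sigma_s^2))
    dr <- lum[hs, ws] - lum[ht, wt]
    wgt <- wsp * exp(-dr^2 / (2 * p$denoise_sigma_r^2))
    wacc[ht, wt] <- wacc[ht, wt] + wgt
    for (ch in 1:3) {
      acc[ht, wt, ch] <- acc[ht, wt, ch] + wgt * img[hs, ws, ch]
    }
  }
  out <- acc / array(rep(wacc, 3), d)
  out
}

#' Full enhancement pipeline
#'
#' Exact composition in the stated order: saturation boost, gamma correction,
#' CLAHE on luminance, edge-aware denoising.
#' @param img `(H, W, 3)` image, 0..255
#' @param p an [enhance_params()]
#' @export
enhance_pipeline <- function(img, p = enhance_params()) {
  img <- saturation_boost(img, p)
  img <- gamma_correct(img, p$gamma)
  img <- clahe_luminance(img, p$clahe_clip, p$clahe_tiles)
  edge_denoise(img, p)
}

#' Audit a dataset manifest against an enhanced-image directory
#'
#' Enhanced frames are an annotation aid only and must never appear in the
#' train/val/test manifests. This check errors if any manifest image resolves
#' into the enhanced directory or shares bytes with an enhanced frame of the
#' same stem.
#' @param manifest dataset manifest (data.frame with an `image` column)
#' @param dataset_dir root the manifest paths are relative to
#' @param enhanced_dir directory holding enhanced frames
#' @return invisibly TRUE when clean
#' @export
audit_no_enhanced <- function(manifest, dataset_dir, enhanced_dir) {
  if (!dir.exists(enhanced_dir)) return(invisible(TRUE))
  offenders <- character(0)
  enh <- list.files(enhanced_dir, pattern = "\\.ppm$")
  for (img in manifest$image) {
    f <- file.path(dataset_dir, img)
    if (normalizePath(dirname(f), mustWork = FALSE) ==
        normalizePath(enhanced_dir, mustWork = FALSE)) {
      offenders <- c(offenders, img)
      next
    }
    twin <- file.path(enhanced_dir, basename(img))
    if (basename(img) %in% enh && file.exists(f) &&
        identical(readLines(f, warn = FALSE), readLines(twin, warn = FALSE))) {
      offenders <- c(offenders, img)
    }
  }
  if (length(offenders)) {
    stop("enhanced frames found in the dataset manifest: ",
         paste(offenders, collapse = ", "))
  }
  invisible(TRUE)
}

## ---- annotation transfer ----------------------------------------------------

#' Transfer labels drawn on enhanced images back to the originals
#'
#' Enhancement changes only the visual quality of a frame, never object
#' geometry, so labels pair to original images purely by filename stem. Label
#' geometry is copied verbatim; orphans on either side are reported.
#' @param enhanced_label_dir directory of YOLO `.txt` labels (named by stem)
#' @param original_image_dir directory of original images
#' @param out_dir if non-NULL, paired labels are copied here
#' @return list with `pairs` (data.frame stem/label/image), `orphan_labels`,
#'   `orphan_images`; orphans make the pairing incomplete
#' @export
transfer_labels <- function(enhanced_label_dir, original_image_dir, out_dir = NULL) {
  labs <- list.files(enhanced_label_dir, pattern = "\\.txt$")
  imgs <- list.files(original_image_dir, pattern = "\\.(ppm|pgm)$")
  lstem <- tools::file_path_sans_ext(labs)
  istem <- tools::file_path_sans_ext(imgs)
  common <- intersect(lstem, istem)
  pairs <- data.frame(stem = common,
                      label = labs[match(common, lstem)],
                      image = imgs[match(common, istem)])
  if (!is.null(out_dir) && nrow(pairs) > 0) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(enhanced_label_dir, pairs$label),
              file.path(out_dir, pairs$label), overwrite = TRUE)
  }
  list(pairs = pairs,
       orphan_labels = setdiff(lstem, istem),
       orphan_images = setdiff(istem, lstem))
}
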