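# Annotation enhancement pipeline: stage identities, fixed points, ordering
# sensitivity, determinism, and label transfer.

ramp_fixture <- function(h = 40, w = 40, lo = 80, hi = 140) {
  g <- matrix(rep(seq(lo, hi, length.out = w), each = h), h, w)
  array(rep(g, 3), c(h, w, 3))
}

noisy_flat <- function(h = 24, w = 24, level = 100, sd = 12, seed = 1) {
  set.seed(seed)
  img <- array(level, c(h, w, 3)) + array(rnorm(h * w * 3, sd = sd), c(h, w, 3))
  pmax(pmin(img, 255), 0)
}

test_that("saturation boost: gray fixed point, unit gains identity, clipping", {
  p <- enhance_params()
  gray <- array(120, c(8, 8, 3))
  expect_equal(saturation_boost(gray, p), gray, tolerance = 1e-9)

  p1 <- enhance_params(sat_gain_red = 1, sat_gain_global = 1)
  set.seed(2)
  img <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  expect_equal(saturation_boost(img, p1), img, tolerance = 1e-6)

  # fully saturated red pixel stays at channel max under gain 1.5
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  out <- saturation_boost(red, enhance_params(sat_gain_red = 1.5))
  expect_equal(as.vector(out), c(255, 0, 0))
  expect_error(saturation_boost(matrix(1, 3, 3)), "3-channel")
  expect_error(enhance_params(sat_gain_red = 0.5), ">= 1")
})

test_that("gamma correction brightens with fixed endpoints and worked value", {
  img <- array(c(0, 128, 255), c(3, 1, 3))
  out <- gamma_correct(img, 0.5)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[3, 1, 1], 255)
  expect_equal(round(out[2, 1, 1]), 181)     # 255*(128/255)^0.5 = 180.6
  expect_equal(gamma_correct(img, 1), img)
  expect_true(all(gamma_correct(ramp_fixture(), 0.6) >= ramp_fixture() - 1e-9))
  expect_error(gamma_correct(img, 0), "> 0")
})

test_that("CLAHE: constant fixed point, flatter luminance, chrominance kept", {
  const <- array(90, c(32, 32, 3))
  expect_equal(clahe_luminance(const), const)

  # histogram flatness over a coarse 32-bin partition of 0..255: a stretched
  # low-contrast ramp occupies more bins more evenly
  entropy32 <- function(v) {
    h <- tabulate(pmax(1, pmin(32, floor(v / 8) + 1)), 32)
    p <- h[h > 0] / sum(h)
    -sum(p * log2(p))
  }
  img <- ramp_fixture(lo = 100, hi = 130)    # low-contrast ramp
  out <- clahe_luminance(img, clip = 4, tiles = 4)
  lum_in <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  lum_out <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
  expect_gte(entropy32(lum_out), entropy32(lum_in))
  expect_gt(diff(range(lum_out)), diff(range(lum_in)))   # contrast stretched

  # chrominance planes: Lab a/b of the output match the input up to sRGB
  # roundtrip noise (fixture kept inside the gamut: mild saturation)
  set.seed(3)
  base <- runif(16 * 16, 80, 170)
  img2 <- array(c(base + runif(256, -12, 12), base + runif(256, -12, 12),
                  base + runif(256, -12, 12)), c(16, 16, 3))
  out2 <- clahe_luminance(img2, 2, 4)
  lab_in <- grDevices::convertColor(matrix(img2, 256, 3) / 255, "sRGB", "Lab")
  lab_out <- grDevices::convertColor(matrix(out2, 256, 3) / 255, "sRGB", "Lab")
  expect_lt(max(abs(lab_in[, 2:3] - lab_out[, 2:3])), 1.0)
})

test_that("bilateral denoising shrinks flat-region variance but keeps edges", {
  p <- enhance_params()
  const <- array(77, c(12, 12, 3))
  expect_equal(edge_denoise(const, p), const, tolerance = 1e-9)

  nf <- noisy_flat()
  out <- edge_denoise(nf, p)
  expect_lt(var(as.vector(out[5:20, 5:20, 1])), var(as.vector(nf[5:20, 5:20, 1])))

  # step edge of height 100 survives to at least 90
  step <- array(60, c(20, 20, 3))
  step[, 11:20, ] <- 160
  outs <- edge_denoise(step, p)
  edge_height <- mean(outs[, 14:17, 1]) - mean(outs[, 4:7, 1])
  expect_gte(edge_height, 90)
})

test_that("the pipeline composes in the stated order and is deterministic", {
  set.seed(4)
  dark <- pmax(pmin(ramp_fixture(lo = 15, hi = 70) +
                      array(rnorm(40 * 40 * 3, sd = 6), c(40, 40, 3)), 255), 0)
  p <- enhance_params()
  out1 <- enhance_pipeline(dark, p)
  out2 <- enhance_pipeline(dark, p)
  expect_identical(out1, out2)                       # deterministic
  expect_gt(mean(out1), mean(dark))                  # dark fixture brightens

  # order sensitivity: denoise-first then the rest differs from the pipeline
  alt <- clahe_luminance(gamma_correct(saturation_boost(edge_denoise(dark, p), p),
                                       p$gamma), p$clahe_clip, p$clahe_tiles)
  expect_gt(max(abs(alt - out1)), 1e-6)
})

test_that("enhanced frames are barred from dataset manifests", {
  root <- tempfile()
  ds <- file.path(root, "ds"); enh <- file.path(root, "enh")
  dir.create(file.path(ds, "images"), recursive = TRUE)
  dir.create(enh, recursive = TRUE)
  img <- array(round(runif(12 * 12 * 3, 0, 255)), c(12, 12, 3))
  write_ppm(img, file.path(ds, "images", "a.ppm"))
  mf <- data.frame(image = "images/a.ppm")
  expect_true(audit_no_enhanced(mf, ds, enh))
  # same stem, same bytes in the enhanced dir -> flagged
  write_ppm(img, file.path(enh, "a.ppm"))
  expect_error(audit_no_enhanced(mf, ds, enh), "enhanced frames")
  # genuinely enhanced twin (different bytes) is fine: originals are in use
  write_ppm(gamma_correct(img, 0.6), file.path(enh, "a.ppm"))
  expect_true(audit_no_enhanced(mf, ds, enh))
})

test_that("label transfer pairs by stem and reports orphans", {
  root <- tempfile()
  ldir <- file.path(root, "labels"); idir <- file.path(root, "imgs")
  dir.create(ldir, recursive = TRUE); dir.create(idir, recursive = TRUE)
  lab <- data.frame(class_id = 0L, cx = 0.5, cy = 0.25, w = 0.1, h = 0.2)
  for (s in c("a", "b", "c")) write_yolo_labels(lab, file.path(ldir, paste0(s, ".txt")))
  img <- array(100, c(8, 8, 3))
  for (s in c("a", "b", "c")) write_ppm(img, file.path(idir, paste0(s, ".ppm")))

  rep3 <- transfer_labels(ldir, idir, file.path(root, "out"))
  expect_identical(nrow(rep3$pairs), 3L)
  expect_length(rep3$orphan_labels, 0)
  # geometry byte-identical after transfer
  expect_identical(readLines(file.path(root, "out", "a.txt")),
                   readLines(file.path(ldir, "a.txt")))

  write_yolo_labels(lab, file.path(ldir, "extra.txt"))
  rep4 <- transfer_labels(ldir, idir)
  expect_identical(rep4$orphan_labels, "extra")
  expect_error(cli_transfer_labels(ldir, idir, file.path(root, "out2")), "unpaired")
})
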