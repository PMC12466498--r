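# Training plumbing: configuration defaults, target assignment, loss descent,
# augmentation geometry, decode/NMS round trip.

test_that("the default configuration round-trips the published recipe", {
  cfg <- train_config()
  expect_identical(cfg$optimizer, "SGD")
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$momentum, 0.937)
  expect_equal(cfg$weight_decay, 5e-4)
  expect_identical(cfg$batch_size, 32L)
  expect_identical(cfg$epochs, 400L)
  expect_identical(cfg$image_size, 640L)
  expect_identical(cfg$patience, 50L)
  expect_setequal(cfg$augmentations,
                  c("translation", "scaling", "flipping", "mosaic", "mixup"))
  expect_error(train_config(image_size = 100))
})

test_that("target assignment places cells inside boxes with representable offsets", {
  boxes <- matrix(c(40, 40, 90, 80), 1)
  tg <- cd("assign_targets")(boxes, 160L, c(8L, 16L, 32L))
  npos <- sum(sapply(tg, function(l) length(l$idx)))
  expect_gt(npos, 0)
  for (lv in seq_along(tg)) {
    if (length(tg[[lv]]$idx) == 0) next
    expect_true(all(tg[[lv]]$ltrb > 0))
    expect_true(all(tg[[lv]]$ltrb < 15))
    # offsets reconstruct the box: (l+r)*stride = box width
    s <- c(8, 16, 32)[lv]
    expect_equal(unname(colSums(tg[[lv]]$ltrb[c(1, 3), , drop = FALSE]) * s),
                 rep(50, length(tg[[lv]]$idx)))
  }
  # empty ground truth -> no assignment
  tg0 <- cd("assign_targets")(matrix(numeric(0), 0, 4), 160L, c(8L, 16L, 32L))
  expect_true(all(sapply(tg0, function(l) length(l$idx) == 0)))
})

test_that("a few SGD steps reduce the detection loss on a tiny fixture", {
  set.seed(9)
  scenes <- tiny_scenes(n = 2, imgsz = 96)
  m <- build_variant("baseline", nc = 1, width = 0.0625)
  cfg <- train_config(learning_rate = 0.02, batch_size = 2, epochs = 8,
                      image_size = 96, augment = FALSE, eval_every = 8,
                      patience = 100)
  res <- train(m, scenes, cfg, seed = 1)
  h <- res$history
  first <- h[1, ]
  expect_true(all(is.finite(c(first$loss_box, first$loss_cls, first$loss_dfl))))
  # rerun for more epochs: the losses at the end are lower than at epoch 8
  set.seed(9)
  m2 <- build_variant("baseline", nc = 1, width = 0.0625)
  cfg2 <- train_config(learning_rate = 0.02, batch_size = 2, epochs = 40,
                       image_size = 96, augment = FALSE, eval_every = 40,
                       patience = 100)
  res2 <- train(m2, scenes, cfg2, seed = 1)
  expect_lt(res2$history$loss_cls[1], first$loss_cls)
  expect_lt(res2$history$loss_dfl[1], first$loss_dfl)
})

test_that("train rejects empty datasets", {
  m <- build_variant("baseline", nc = 1, width = 0.0625)
  expect_error(train(m, list(), train_config()), "empty")
})

test_that("augmentations preserve label geometry contracts", {
  sc <- tiny_scenes(n = 1, imgsz = 96)[[1]]
  # horizontal flip is an involution on labels and pixels
  fl2 <- cd("aug_hflip")(cd("aug_hflip")(sc))
  expect_equal(fl2$image, sc$image)
  expect_equal(fl2$labels$cx, sc$labels$cx)

  set.seed(1)
  tr <- cd("aug_translate")(sc)
  expect_identical(dim(tr$image), dim(sc$image))
  if (nrow(tr$labels) > 0) {
    expect_true(all(tr$labels$cx > 0 & tr$labels$cx < 1))
  }
  set.seed(2)
  scl <- cd("aug_scale")(sc)
  expect_identical(dim(scl$image), dim(sc$image))

  mos <- cd("aug_mosaic")(tiny_scenes(n = 4, imgsz = 96))
  expect_identical(dim(mos$image), dim(sc$image))
  expect_true(all(mos$labels$w <= 0.5 + 1e-9))

  set.seed(3)
  mix <- cd("aug_mixup")(sc, tiny_scenes(n = 1, seed0 = 300, imgsz = 96)[[1]])
  expect_identical(dim(mix$image), dim(sc$image))
  expect_gte(nrow(mix$labels), nrow(sc$labels))
})

test_that("decode + NMS recovers boxes that the loss was trained toward", {
  # construct raw outputs that encode one crisp box and check the round trip
  imgsz <- 64L
  m <- build_variant("baseline", nc = 1, width = 0.0625)
  strides <- m$strides
  outs <- lapply(strides, function(s) {
    H <- imgsz %/% s
    box <- array(0, c(64, H, H, 1))
    cls <- array(-20, c(1, H, H, 1))
    list(box = box, cls = cls)
  })
  # put a confident detection at level 1, cell (4,4): ltrb = 2 stride units
  H1 <- imgsz %/% strides[1]
  outs[[1]]$cls[1, 4, 4, 1] <- 10
  enc <- rep(-20, 16)
  for (side in 0:3) {
    v <- enc; v[3] <- 20                  # bin index 2 -> offset 2
    outs[[1]]$box[side * 16 + 1:16, 4, 4, 1] <- v
  }
  dets <- cd("decode_outputs")(outs, strides)[[1]]
  expect_identical(nrow(dets), 1L)
  cx <- (4 - 0.5) * strides[1]
  expect_equal(unname(dets[1, 1:4]),
               c(cx - 16, cx - 16, cx + 16, cx + 16), tolerance = 1e-6)
  expect_gt(dets[1, 5], 0.99)

  # NMS keeps the higher-confidence of two near-duplicates
  b <- rbind(c(0, 0, 10, 10, 0.9), c(0.5, 0, 10, 10, 0.8), c(30, 30, 40, 40, 0.5))
  kept <- nms(b, 0.7)
  expect_identical(nrow(kept), 2L)
  expect_equal(kept[1, 5], 0.9)
})
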