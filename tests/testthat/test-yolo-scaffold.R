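# Substrate: conv blocks, shape contracts, parameter counting, FLOPs profiling.

test_that("build_cbs enforces the ConvBlockSpec contract", {
  expect_error(conv_block_spec(64, 128, kernel = 4), "even kernel")
  expect_error(conv_block_spec(5, 8, groups = 2), "divisible by groups")

  set.seed(1)
  m <- build_cbs(conv_block_spec(3, 16, kernel = 3))
  # hand arithmetic: 3*16*9 conv weights + 2*16 norm affine
  expect_identical(count_params(m), 3 * 16 * 9 + 2 * 16)

  # downsampling doubles channels, halves space (ceiling rule)
  m2 <- build_cbs(conv_block_spec(64, 128, kernel = 3, stride = 2))
  y <- fwd(m2, rand_tensor(64, 80, 80, 1, seed = 2))
  expect_identical(dim(y), c(128L, 40L, 40L, 1L))

  # identity spatial case
  m3 <- build_cbs(conv_block_spec(8, 8, kernel = 1))
  x <- rand_tensor(8, 11, 7, 2, seed = 3)
  expect_identical(dim(fwd(m3, x)), dim(x))
})

test_that("conv output shapes follow spec arithmetic over random valid specs", {
  set.seed(42)
  for (i in 1:12) {
    g <- sample(c(1, 1, 2), 1)
    cin <- g * sample(1:4, 1) * 2
    spec <- conv_block_spec(cin, sample(c(4, 8, 12), 1),
                            kernel = sample(c(1, 3, 5), 1),
                            stride = sample(1:2, 1),
                            dilation = sample(1:2, 1), groups = g)
    H <- sample(8:17, 1); W <- sample(8:17, 1)
    y <- fwd(build_cbs(spec), rand_tensor(cin, H, W, 1))
    expect_identical(dim(y)[1:3],
                     c(spec$out_ch, as.integer(ceiling(H / spec$stride)),
                       as.integer(ceiling(W / spec$stride))))
  }
})

test_that("baseline model has the contracted pyramid outputs and stride set", {
  set.seed(1)
  m <- build_yolo11n_baseline(num_classes = 1)
  expect_identical(m$strides, c(8L, 16L, 32L))
  out <- forward_model(m, array(0, c(3, 320, 320, 1)))
  expect_length(out, 3)
  # box branch: 4*reg_max distribution bins; cls branch: num_classes
  for (lv in 1:3) {
    expect_identical(dim(out[[lv]]$box)[1], 64L)
    expect_identical(dim(out[[lv]]$cls)[1], 1L)
    expect_identical(dim(out[[lv]]$box)[2], 320L %/% m$strides[lv])
  }
  expect_error(forward_model(m, array(0, c(3, 100, 100, 1))), "multiples of 32")
})

test_that("count_params counts each trainable weight once and skips frozen ones", {
  set.seed(1)
  m <- cd("cbs")(3, 16, 3)
  expect_identical(count_params(m), 464)
  expect_identical(count_params(m, fused = TRUE), 3 * 16 * 9 + 16)
  conv <- nn_conv2d(4, 4, 3, trainable = FALSE)
  expect_identical(count_params(conv), 0)
})

test_that("profile_flops matches the closed-form conv cost convention", {
  # 1x1 conv C->C on HxW costs 2*C^2*H*W under MAC*2 counting
  set.seed(1)
  conv <- nn_conv2d(6, 6, 1)
  cd("prof_start")()
  fwd(conv, rand_tensor(6, 13, 9, 1))
  macs <- cd("prof_stop")()
  expect_equal(2 * macs, 2 * 6^2 * 13 * 9)
})

test_that("conv FLOPs scale with H*W while params do not", {
  set.seed(1)
  m <- build_yolo11n_baseline(1)
  f1 <- profile_flops(m, 64)
  f2 <- profile_flops(m, 128)
  expect_equal(f2 / f1, 4, tolerance = 1e-8)
  expect_identical(count_params(m), {
    set.seed(1); count_params(build_yolo11n_baseline(1))
  })
  expect_error(profile_flops(m, 100), "multiple of 32")
})

test_that("feature map spec validates the input divisibility contract", {
  expect_error(feature_map_spec(1, 3, 0, 64), ">= 1")
  expect_error(feature_map_spec(1, 3, 100, 96, at_input = TRUE), "multiples of 32")
  s <- feature_map_spec(2, 3, 640, 640, at_input = TRUE)
  expect_s3_class(s, "FeatureMapSpec")
})
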