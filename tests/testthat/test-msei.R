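# Multi-scale edge information extractor: EIEnhance residual arithmetic, DSM
# identity-at-init and branch behaviour, pyramid partition, stage contract.

test_that("EIEnhance passes constant inputs through and boosts an impulse by 8/9", {
  set.seed(1)
  m <- nn_eienhance(3)
  const <- array(2.5, c(3, 6, 6, 1))
  expect_equal(fwd(m, const), const, tolerance = 1e-12)

  # single-pixel impulse on zeros: 3x3 mean smoother leaves residual 1 - 1/9
  # at the (interior) center
  x <- array(0, c(1, 7, 7, 1))
  x[1, 4, 4, 1] <- 1
  resid <- cd("vval")(cd("op_box_residual")(x))
  expect_equal(resid[1, 4, 4, 1], 1 - 1 / 9, tolerance = 1e-12)
  expect_identical(dim(fwd(m, rand_tensor(3, 9, 9, 2))), c(3L, 9L, 9L, 2L))
})

test_that("DSM is the identity at initialisation and gates behave as documented", {
  set.seed(2)
  m <- nn_dsm(4)
  x <- rand_tensor(4, 8, 8, 2)
  expect_identical(fwd(m, x), x)        # bit-equal identity at init

  # spatial weight map strictly inside (0,1)
  wmap <- cd("vval")(cd("op_sigmoid")(cd("op_conv")(m$g2, fwd(m$g1, x))))
  expect_true(all(wmap > 0 & wmap < 1))

  # opening only the frequency gate adds energy only above the spectral cutoff
  m$gate_fr$g[] <- 1
  y <- fwd(m, x)
  delta <- (y - x)[1, , , 1]
  X <- fft(delta)
  mask <- cd("radial_hp_mask")(8, 8, 0.25)
  low_energy <- sum(Mod(X[mask == 0])^2)
  high_energy <- sum(Mod(X[mask == 1])^2)
  expect_lt(low_energy, 1e-16 * max(high_energy, 1))
  expect_error(fwd(nn_dsm(2), array(1, c(2, 1, 1, 1))), "at least 4")
})

test_that("DSM gates all receive gradient on a backward pass", {
  set.seed(3)
  m <- nn_mseiselect(4)
  x <- rand_tensor(4, 13, 13, 1)
  cd("ag_start")()
  y <- fwd(m, cd("agv")(x), train = TRUE)
  loss <- cd("op_sum")(y, array(sin(seq_along(cd("vval")(y))), dim(cd("vval")(y))))
  cd("ag_backward")(loss)
  cd("ag_stop")()
  expect_true(any(m$gate_out$gg != 0))
  # inner DSM gates sit behind the zero-initialised output gate, so their own
  # gradients flow once that gate is open; check via a second pass
  m$gate_out$g[] <- 0.5
  cd("ag_start")()
  y <- fwd(m, cd("agv")(x), train = TRUE)
  loss <- cd("op_sum")(y, array(sin(seq_along(cd("vval")(y))), dim(cd("vval")(y))))
  cd("ag_backward")(loss)
  cd("ag_stop")()
  expect_true(all(abs(m$dsm$gate_res$gg) > 0))
  expect_true(all(abs(m$dsm$gate_sp$gg) > 0))
  expect_true(any(m$dsm$gate_fr$gg != 0))
})

test_that("MSEISelect uses the 3/6/9/12 pyramid and preserves shape and identity", {
  set.seed(4)
  m <- nn_mseiselect(5)
  expect_identical(m$scales, c(3L, 6L, 9L, 12L))
  x <- rand_tensor(5, 40, 40, 1)
  y <- fwd(m, x)
  expect_identical(dim(y), dim(x))
  expect_identical(y, x)                # zero-init output gate => identity

  # adaptive pooling partition property: bins tile the input exactly
  xx <- rand_tensor(2, 13, 17, 1)
  for (s in c(3, 6, 9, 12)) {
    p <- cd("vval")(cd("op_adaptive_avgpool")(xx, s))
    expect_identical(dim(p)[2:3], as.integer(c(s, s)))
  }
  # when size divides evenly, sum(bin mean * bin area) = total sum
  xe <- rand_tensor(1, 12, 12, 1)
  p <- cd("vval")(cd("op_adaptive_avgpool")(xe, 3))
  expect_equal(sum(p) * (4 * 4), sum(xe), tolerance = 1e-9)
  # scale 12 on a 12x12 input is the identity partition
  p12 <- cd("vval")(cd("op_adaptive_avgpool")(xe, 12))
  expect_equal(p12, xe, tolerance = 1e-12)
})

test_that("the exported MSEISelect op rejects sub-pyramid inputs", {
  set.seed(5)
  expect_error(mseiselect_forward(rand_tensor(4, 11, 16, 1)),
               "resize")
  y <- mseiselect_forward(rand_tensor(4, 12, 12, 1))
  expect_identical(dim(y), c(4L, 12L, 12L, 1L))
})

test_that("MSEIExtractor keeps the stage contract and matches its shell at init", {
  set.seed(6)
  m <- nn_mseiextractor(8, 8, 1)
  x <- rand_tensor(8, 16, 16, 1)
  y <- fwd(m, x)
  expect_identical(dim(y), dim(x))

  # identity-at-init: with the novel branch zeroed the stage equals the same
  # CSP shell with an identity transform path
  y_manual <- local({
    h <- fwd(m$cv1, x)
    parts <- cd("op_chunk")(h, c(m$ch, m$ch))
    fwd(m$cv2, cd("op_cat")(list(parts[[1]], parts[[2]], parts[[2]])))
  })
  expect_equal(y, y_manual, tolerance = 1e-12)
})
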