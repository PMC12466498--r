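# Synthetic scene generator: determinism, labelling rules, split arithmetic,
# illumination structure, special sets.

test_that("scenes are byte-identical under identical spec and seed", {
  sp <- scene_spec(n_chickens = 3, tier = "lower", occluders = c("pipe"),
                   seed = 11, imgsz = 96)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  # a different seed changes pixels but not the schema
  c2 <- generate_scene(scene_spec(n_chickens = 3, tier = "lower",
                                  occluders = "pipe", seed = 12, imgsz = 96))
  expect_false(identical(a$image, c2$image))
  expect_identical(names(a$labels), names(c2$labels))
})

test_that("labelling follows the visibility threshold; empty scenes are empty", {
  sp0 <- scene_spec(n_chickens = 0, seed = 1, imgsz = 96)
  expect_identical(nrow(generate_scene(sp0)$labels), 0L)
  expect_error(scene_spec(n_chickens = -1), ">= 0")
  expect_error(scene_spec(imgsz = 8), "degenerate")
  expect_error(scene_spec(occluders = "fox"), "unknown occluders")

  # every emitted label clears the visibility threshold and stays in [0,1]
  thr <- cd("SYNTH_VISIBILITY_THRESHOLD")
  dropped_any <- FALSE
  for (s in 1:30) {
    sc <- generate_scene(scene_spec(n_chickens = 3, occluders = c("trough", "pipe"),
                                    seed = s, imgsz = 96))
    if (nrow(sc$labels) > 0) {
      expect_true(all(sc$labels$visibility >= thr))
      expect_true(all(sc$labels$cx >= 0 & sc$labels$cx <= 1))
      expect_true(all(sc$labels$w > 0 & sc$labels$w <= 1))
    }
    if (nrow(sc$labels) < 3) dropped_any <- TRUE
  }
  # occluders do suppress near-fully-hidden birds somewhere in 30 scenes
  expect_true(dropped_any)
})

test_that("the rendered box tightly contains the head-neck mask by construction", {
  # re-render the head-neck geometry for one bird and compare to its label
  sc <- generate_scene(scene_spec(n_chickens = 1, seed = 21, imgsz = 96))
  expect_identical(nrow(sc$labels), 1L)
  lb <- sc$labels
  # comb pixels (distinctive red) must lie inside the labelled box
  img <- sc$image
  redness <- img[, , 1] - pmax(img[, , 2], img[, , 3])
  comb <- which(redness > 80, arr.ind = TRUE)   # comb red, not feather tint
  if (nrow(comb) > 0) {
    S <- 96
    expect_true(all(comb[, 1] / S >= lb$cy - lb$h / 2 - 1 / S))
    expect_true(all(comb[, 1] / S <= lb$cy + lb$h / 2 + 1 / S))
    expect_true(all(comb[, 2] / S >= lb$cx - lb$w / 2 - 1 / S))
    expect_true(all(comb[, 2] / S <= lb$cx + lb$w / 2 + 1 / S))
  }
})

test_that("dataset generation writes a consistent YOLO layout", {
  out <- tempfile()
  mf <- generate_dataset(6, out_dir = out, seed = 4, imgsz = 64)
  expect_identical(nrow(mf), 6L)
  expect_length(list.files(file.path(out, "images")), 6)
  expect_length(list.files(file.path(out, "labels")), 6)
  # label counts in the manifest match a recount from the stored files
  for (i in seq_len(6)) {
    lb <- read_yolo_labels(file.path(out, mf$label[i]))
    expect_identical(nrow(lb), mf$n_labels[i])
  }
  expect_error(generate_dataset(2, out_dir = out, seed = 4), "force")
  # PPM round trip is lossless up to integer quantisation
  img <- read_ppm(file.path(out, mf$image[1]))
  expect_identical(dim(img), c(64L, 64L, 3L))
  # changing only the seed changes hashes but not the schema
  out2 <- tempfile()
  mf2 <- generate_dataset(6, out_dir = out2, seed = 5, imgsz = 64)
  expect_identical(names(mf), names(mf2))
  expect_false(identical(readLines(file.path(out, mf$image[1])),
                         readLines(file.path(out2, mf2$image[1]))))
})

test_that("split arithmetic reproduces the published counts and partitions", {
  expect_identical(split_dataset(3851), list(train = 2695L, val = 770L, test = 386L))
  expect_identical(split_dataset(10), list(train = 7L, val = 2L, test = 1L))
  expect_error(split_dataset(9), "at least 10")
  expect_error(split_dataset(100, ratios = c(0.5, 0.2, 0.2)), "sum to 1")

  mf <- generate_dataset(12, seed = 1, imgsz = 64)
  sp <- split_dataset(mf, seed = 3)
  all_rows <- sort(c(sp$train$image, sp$val$image, sp$test$image))
  expect_identical(all_rows, sort(mf$image))
  expect_identical(length(intersect(sp$train$image, sp$val$image)), 0L)
  expect_identical(length(intersect(sp$train$image, sp$test$image)), 0L)
})

test_that("upper tier scenes are brighter than lower tier scenes on average", {
  lum <- function(tier, n = 40) {
    mean(sapply(seq_len(n), function(i) {
      mean(generate_scene(scene_spec(n_chickens = 2, tier = tier, seed = 1000 + i,
                                     imgsz = 48))$image)
    }))
  }
  expect_gt(lum("upper"), lum("lower"))
})

test_that("special sets have the stated sizes and structure", {
  sets <- make_special_sets(n_each = 20, seed = 2, imgsz = 48)
  expect_identical(nrow(sets$poor_light), 20L)
  expect_identical(nrow(sets$multi_occ), 20L)
  # poor-light scenes are darker than a standard batch
  std <- generate_dataset(20, seed = 2, imgsz = 48)
  lum_of <- function(mf, ns) {
    mean(sapply(seq_len(nrow(mf)), function(i) {
      sc <- generate_scene(scene_spec(
        n_chickens = mf$n_chickens[i], tier = mf$tier[i],
        illumination = mf$illumination[i],
        occluders = strsplit(mf$occluders[i], ";")[[1]],
        depth_falloff = mf$depth_falloff[i], seed = mf$scene_seed[i], imgsz = 48))
      mean(sc$image)
    }))
  }
  expect_lt(mean(sets$poor_light$illumination), mean(std$illumination))
  # every multi-occlusion scene lists at least two occluder types
  n_occ <- sapply(strsplit(sets$multi_occ$occluders, ";"), length)
  expect_true(all(n_occ >= 2))
})
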