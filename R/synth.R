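# Procedural generator of caged-chicken-like scenes. Emulates the structure of
# the (undeposited) farm dataset: multi-tier cages with a strong illumination
# gradient (bright upper tier, dark lower tier and cage depth), wire mesh,
# three occluder types (water pipe, feed trough, conspecific crowding), and
# single-class head-neck labels in YOLO text format. Everything is
# deterministic under (spec, seed).

# fraction of the head-neck region that must remain visible for a bird to be
# annotated (near-total occlusion is left unlabelled; repo policy constant)
SYNTH_VISIBILITY_THRESHOLD <- 0.15

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Scene specification
#'
#' @param n_chickens number of birds (>= 0)
#' @param tier "upper" (bright) or "lower" (dim)
#' @param illumination base luminance factor in `[0, 1]`; default depends on tier
#' @param occluders subset of `c("pipe", "trough", "crowd")`
#' @param depth_falloff luminance decay toward the cage rear (image top), `[0, 1)`
#' @param seed RNG seed; identical spec + seed gives identical bytes
#' @param imgsz square image side in pixels
#' @return a `SceneSpec`
#' @export
scene_spec <- function(n_chickens = 4L, tier = c("upper", "lower"),
                       illumination = NULL, occluders = character(0),
                       depth_falloff = 0.5, seed = 1L, imgsz = 320L) {
  tier <- match.arg(tier)
  occluders <- occluders[nzchar(occluders)]
  if (n_chickens < 0) stop("n_chickens must be >= 0")
  if (imgsz < 32) stop("zero-area or degenerate scene rejected (imgsz >= 32)")
  bad <- setdiff(occluders, c("pipe", "trough", "crowd"))
  if (length(bad)) stop("unknown occluders: ", paste(bad, collapse = ", "))
  if (is.null(illumination)) illumination <- if (tier == "upper") 0.85 else 0.35
  structure(list(n_chickens = as.integer(n_chickens), tier = tier,
                 illumination = illumination, occluders = occluders,
                 depth_falloff = depth_falloff, seed = as.integer(seed),
                 imgsz = as.integer(imgsz)),
            class = "SceneSpec")
}

# rotated ellipse mask on the pixel grid
ellipse_mask <- function(X, Y, cx, cy, a, b, theta = 0) {
  xr <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  yr <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

paint <- function(img, mask, col, noise_sd = 0) {
  n <- sum(mask)
  if (n == 0) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    v <- col[ch] + if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    plane[mask] <- v
    img[, , ch] <- plane
  }
  img
}

#' Render one synthetic caged scene
#'
#' @param spec a [scene_spec()]
#' @return list with `image` (H,W,3 array, 0..255), `labels`
#'   (data.frame class_id, cx, cy, w, h, visibility), and `spec`
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  with_seed(spec$seed, {
    S <- spec$imgsz
    X <- matrix(rep(seq_len(S), each = S), S, S)    # column index
    Y <- matrix(rep(seq_len(S), S), S, S)           # row index
    img <- array(0, c(S, S, 3))
    base <- c(84, 74, 62)
    for (ch in 1:3) img[, , ch] <- base[ch] + stats::rnorm(S * S, sd = 5)

    n_birds <- spec$n_chickens
    n_extra <- if ("crowd" %in% spec$occluders) max(2L, ceiling(n_birds / 2)) else 0L
    total <- n_birds + n_extra
    owner <- matrix(0L, S, S)
    birds <- list()
    if (total > 0) {
      cxs <- stats::runif(total, 0.15 * S, 0.85 * S)
      cys <- stats::runif(total, 0.30 * S, 0.80 * S)
      if (n_extra > 0) {
        # crowding: extras pushed next to labelled birds
        anchor <- sample(seq_len(max(1, n_birds)), n_extra, replace = TRUE)
        cxs[n_birds + seq_len(n_extra)] <- pmin(pmax(cxs[anchor] +
          stats::runif(n_extra, -0.08, 0.08) * S, 0.1 * S), 0.9 * S)
        cys[n_birds + seq_len(n_extra)] <- pmin(cys[anchor] +
          stats::runif(n_extra, 0.02, 0.10) * S, 0.85 * S)
      }
      ord <- order(cys)                              # back-to-front
      for (id in ord) {
        a <- stats::runif(1, 0.085, 0.125) * S
        b <- 0.68 * a
        th <- stats::runif(1, -0.35, 0.35)
        body <- ellipse_mask(X, Y, cxs[id], cys[id], a, b, th)
        # head-neck capsule above/forward of the body
        side <- sample(c(-1, 1), 1)
        hx <- cxs[id] + side * 0.75 * a
        hy <- cys[id] - 0.85 * b
        hr <- 0.38 * b
        neck <- ellipse_mask(X, Y, (cxs[id] + side * 0.45 * a + hx) / 2,
                             (cys[id] - 0.2 * b + hy) / 2, 0.85 * hr, 1.7 * hr,
                             side * 0.5)
        head <- ellipse_mask(X, Y, hx, hy, hr, hr)
        comb <- ellipse_mask(X, Y, hx, hy - 1.05 * hr, 0.55 * hr, 0.35 * hr)
        headneck <- neck | head | comb
        img <- paint(img, body, c(182, 142, 66), noise_sd = 16)
        img <- paint(img, neck, c(190, 150, 74), noise_sd = 12)
        img <- paint(img, head, c(196, 152, 78), noise_sd = 10)
        img <- paint(img, comb, c(198, 34, 30), noise_sd = 6)
        owner[body | headneck] <- id
        birds[[id]] <- list(mask = headneck, labelled = id <= n_birds)
      }
    }

    if ("pipe" %in% spec$occluders) {
      # transverse water pipe: thick enough to hide a head-neck region outright
      py <- stats::runif(1, 0.35, 0.6) * S
      ph <- 0.05 * S
      mask <- Y >= py - ph & Y <= py + ph
      img <- paint(img, mask, c(96, 98, 104), noise_sd = 3)
      owner[mask] <- -1L
    }
    if ("trough" %in% spec$occluders) {
      # feed trough: covers the lower band where foraging heads dip
      ty <- 0.68 * S
      mask <- Y >= ty
      img <- paint(img, mask, c(128, 118, 104), noise_sd = 4)
      rim <- Y >= ty & Y <= ty + 0.02 * S
      img <- paint(img, rim, c(150, 140, 126), noise_sd = 2)
      owner[mask] <- -1L
    }

    # wire mesh (in front of everything; thin, does not count as occlusion)
    pitch <- max(12L, round(S / 13))
    mesh <- (X %% pitch) < 2 | (Y %% pitch) < 2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mesh] <- 0.55 * plane[mesh] + 0.45 * 40
      img[, , ch] <- plane
    }

    # tier illumination gradient: dark toward the cage rear (image top)
    light <- spec$illumination * (1 - spec$depth_falloff * (1 - (seq_len(S) - 0.5) / S))
    for (ch in 1:3) img[, , ch] <- img[, , ch] * light
    img <- img + stats::rnorm(S * S * 3, sd = 3)      # sensor grain
    img <- pmax(pmin(img, 255), 0)                    # (img first: keeps dim)

    labels <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                         w = numeric(0), h = numeric(0), visibility = numeric(0))
    for (id in seq_along(birds)) {
      bd <- birds[[id]]
      if (is.null(bd) || !bd$labelled) next
      tot <- sum(bd$mask)
      if (tot == 0) next
      vis <- sum(bd$mask & owner == id) / tot
      if (vis < SYNTH_VISIBILITY_THRESHOLD) next
      rows <- range(Y[bd$mask]); cols <- range(X[bd$mask])
      labels <- rbind(labels, data.frame(
        class_id = 0L,
        cx = mean(cols) / S, cy = mean(rows) / S,
        w = (diff(cols) + 1) / S, h = (diff(rows) + 1) / S,
        visibility = vis))
    }
    list(image = img, labels = labels, spec = spec)
  })
}

## ---- dataset assembly -------------------------------------------------------

sample_spec <- function(imgsz, scene_seed, force_tier = NULL, force_occ = NULL,
                        illum_range = NULL) {
  tier <- force_tier %||% sample(c("upper", "lower"), 1)
  occ <- force_occ %||% {
    o <- character(0)
    if (stats::runif(1) < 0.35) o <- c(o, "pipe")
    if (stats::runif(1) < 0.35) o <- c(o, "trough")
    if (stats::runif(1) < 0.25) o <- c(o, "crowd")
    o
  }
  ir <- illum_range %||% if (tier == "upper") c(0.6, 0.95) else c(0.15, 0.5)
  scene_spec(n_chickens = sample(2:6, 1), tier = tier,
             illumination = stats::runif(1, ir[1], ir[2]),
             occluders = occ,
             depth_falloff = stats::runif(1, 0.3, 0.7),
             seed = scene_seed, imgsz = imgsz)
}

scene_seed_for <- function(seed, i, namespace = 0L) {
  as.integer((as.numeric(seed) * 100003 + namespace * 499979 + i) %% 2147483629)
}

#' Generate a synthetic dataset in YOLO layout
#'
#' @param n_images number of scenes (>= 1)
#' @param out_dir output directory (`images/`, `labels/`, `manifest.csv`);
#'   `NULL` keeps scenes in memory
#' @param seed master seed; per-scene seeds are derived from it
#' @param imgsz image side
#' @param mix optional list of overrides passed to the scene sampler
#'   (`force_tier`, `force_occ`, `illum_range`)
#' @param force overwrite an existing non-empty `out_dir`
#' @return manifest data.frame (one row per scene); with `out_dir = NULL` the
#'   scenes are attached as attribute `"scenes"`
#' @export
generate_dataset <- function(n_images, out_dir = NULL, seed = 0L, imgsz = 320L,
                             mix = list(), force = FALSE) {
  if (n_images < 1) stop("n_images must be >= 1")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
      stop("output directory ", out_dir, " is non-empty; use force = TRUE")
    }
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- vector("list", n_images)
  scenes <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    ssd <- scene_seed_for(seed, i, mix$namespace %||% 0L)
    spec <- with_seed(ssd, do.call(sample_spec, c(list(imgsz = imgsz, scene_seed = ssd),
                                                  mix[setdiff(names(mix), "namespace")])))
    sc <- generate_scene(spec)
    img_name <- sprintf("scene_%05d.ppm", i)
    lab_name <- sprintf("scene_%05d.txt", i)
    if (!is.null(out_dir)) {
      write_ppm(sc$image, file.path(out_dir, "images", img_name))
      write_yolo_labels(sc$labels, file.path(out_dir, "labels", lab_name))
    } else {
      scenes[[i]] <- sc
    }
    rows[[i]] <- data.frame(
      image = file.path("images", img_name), label = file.path("labels", lab_name),
      tier = spec$tier, illumination = spec$illumination,
      depth_falloff = spec$depth_falloff,
      occluders = paste(spec$occluders, collapse = ";"),
      n_chickens = spec$n_chickens, scene_seed = spec$seed,
      n_labels = nrow(sc$labels))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  } else {
    attr(manifest, "scenes") <- scenes
  }
  manifest
}

#' Split a dataset manifest 7:2:1
#'
#' Sizes follow the floor/floor/remainder rule: `floor(0.7 N)` train,
#' `floor(0.2 N)` validation, the remainder test -- the rule that reproduces
#' 2695/770/386 from 3851 items. The split is a disjoint, exhaustive partition.
#' @param manifest data.frame (or integer N for size arithmetic only)
#' @param ratios length-3 proportions summing to 1
#' @param seed shuffling seed
#' @return list of three manifests (`train`, `val`, `test`)
#' @export
split_dataset <- function(manifest, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  N <- if (is.data.frame(manifest)) nrow(manifest) else as.integer(manifest)
  if (N < 10) stop("at least 10 items are required for a 7:2:1 split")
  n_train <- floor(ratios[1] * N)
  n_val <- floor(ratios[2] * N)
  n_test <- N - n_train - n_val
  idx <- with_seed(seed, sample.int(N))
  parts <- list(train = sort(idx[seq_len(n_train)]),
                val = sort(idx[n_train + seq_len(n_val)]),
                test = sort(idx[n_train + n_val + seq_len(n_test)]))
  if (!is.data.frame(manifest)) return(lapply(parts, length))
  lapply(parts, function(ix) manifest[ix, , drop = FALSE])
}

#' Build the two special robustness test sets
#'
#' A poor-illumination set (lower tier, base illumination in the lowest band)
#' and a multiple-occlusion set (at least two occluder types per scene), each
#' `n_each` images, generated in seed namespaces disjoint from any train/val
#' material derived from the same master seed.
#' @param n_each images per set
#' @param seed master seed
#' @param imgsz image side
#' @param out_dir optional root; sets land in `poor_light/` and `multi_occ/`
#' @return list of two manifests
#' @export
make_special_sets <- function(n_each = 100L, seed = 0L, imgsz = 320L,
                              out_dir = NULL) {
  poor <- generate_dataset(
    n_each, out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "poor_light"),
    seed = seed, imgsz = imgsz,
    mix = list(namespace = 5L, force_tier = "lower", illum_range = c(0.05, 0.30)))
  occ_choices <- list(c("pipe", "trough"), c("pipe", "crowd"), c("trough", "crowd"),
                      c("pipe", "trough", "crowd"))
  # >= 2 occluder types per scene, enforced constructively
  multi <- do.call(rbind, lapply(seq_len(n_each), function(i) {
    ssd <- scene_seed_for(seed, i, 6L)
    occ <- with_seed(ssd + 7L, occ_choices[[sample.int(length(occ_choices), 1)]])
    spec <- with_seed(ssd, sample_spec(imgsz, ssd, force_occ = occ))
    sc <- generate_scene(spec)
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, "multi_occ", "images"), recursive = TRUE, showWarnings = FALSE)
      dir.create(file.path(out_dir, "multi_occ", "labels"), recursive = TRUE, showWarnings = FALSE)
      write_ppm(sc$image, file.path(out_dir, "multi_occ", "images", sprintf("scene_%05d.ppm", i)))
      write_yolo_labels(sc$labels, file.path(out_dir, "multi_occ", "labels", sprintf("scene_%05d.txt", i)))
    }
    data.frame(image = file.path("images", sprintf("scene_%05d.ppm", i)),
               label = file.path("labels", sprintf("scene_%05d.txt", i)),
               tier = spec$tier, illumination = spec$illumination,
               depth_falloff = spec$depth_falloff,
               occluders = paste(spec$occluders, collapse = ";"),
               n_chickens = spec$n_chickens, scene_seed = spec$seed,
               n_labels = nrow(sc$labels))
  }))
  if (!is.null(out_dir)) {
    utils::write.csv(poor, file.path(out_dir, "poor_light", "manifest.csv"), row.names = FALSE)
    utils::write.csv(multi, file.path(out_dir, "multi_occ", "manifest.csv"), row.names = FALSE)
  }
  list(poor_light = poor, multi_occ = multi)
}
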