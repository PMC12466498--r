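# Plain-text image and label I/O. Images travel as ASCII portable pixmaps
# (PPM "P3" / PGM "P2"): no binary image codecs are assumed to exist in the
# deployment environment, and text images diff cleanly in fixtures.
#
# In-memory image convention: numeric array (H, W, 3), values 0..255.

#' Write an image as ASCII PPM (P3)
#' @param img array `(H, W, 3)` with values 0..255
#' @param path output path (conventionally `.ppm`)
#' @param maxval maximum channel value
#' @export
write_ppm <- function(img, path, maxval = 255L) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  d <- dim(img)
  v <- as.integer(round(pmax(0, pmin(maxval, img))))
  dim(v) <- d
  # interleave channels row-major: r g b r g b ... per pixel, rows top-down
  px <- aperm(v, c(3, 2, 1))              # (3, W, H): channel fastest, then col
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), as.character(maxval)), con)
  writeLines(paste(as.vector(px)[seq_along(px)], collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PPM (P3) or PGM (P2) image
#' @param path file path
#' @return array `(H, W, 3)`, values 0..maxval (grayscale replicated to 3 channels)
#' @export
read_ppm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = " "), what = numeric(), quiet = TRUE)
  magic <- trimws(txt[1])
  W <- tok[1]; H <- tok[2]; maxval <- tok[3]
  vals <- tok[-(1:3)]
  if (magic == "P3") {
    stopifnot(length(vals) == 3 * W * H)
    px <- array(vals, c(3, W, H))
    img <- aperm(px, c(3, 2, 1))
  } else if (magic == "P2") {
    stopifnot(length(vals) == W * H)
    g <- t(matrix(vals, W, H))
    img <- array(rep(g, 3), c(H, W, 3))
  } else {
    stop("unsupported image magic: ", magic, " (expected ASCII P2/P3)")
  }
  img
}

## ---- YOLO text labels -------------------------------------------------------

#' Read YOLO-format labels
#'
#' One `class cx cy w h` row per object, coordinates normalised to `[0,1]`.
#' @param path label file (may be missing/empty -> zero rows)
#' @return data.frame(class_id, cx, cy, w, h)
#' @export
read_yolo_labels <- function(path) {
  empty <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Write YOLO-format labels
#' @param labels data.frame(class_id, cx, cy, w, h)
#' @param path output path
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- if (nrow(labels) == 0) character(0) else
    sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id, labels$cx, labels$cy,
            labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

# normalised (cx,cy,w,h) -> pixel-space corners (x1,y1,x2,y2)
yolo_to_xyxy <- function(labels, width, height) {
  if (nrow(labels) == 0) return(matrix(numeric(0), 0, 4))
  cbind(x1 = (labels$cx - labels$w / 2) * width,
        y1 = (labels$cy - labels$h / 2) * height,
        x2 = (labels$cx + labels$w / 2) * width,
        y2 = (labels$cy + labels$h / 2) * height)
}

# image (H,W,3) 0..255 -> model tensor (3,H,W,1) in [0,1]
img_to_tensor <- function(img) {
  x <- aperm(img, c(3, 1, 2)) / 255
  dim(x) <- c(dim(x), 1L)
  x
}
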