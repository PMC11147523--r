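# Fundus-image preprocessing (bilinear resize, median filter, CLAHE) and a
# 30-variant augmentation catalogue (sharpen, emboss, Gaussian blur,
# rotation, edge enhancement, skew, flip, shear) with sevenfold dataset
# expansion and train/test split accounting. Pixels are stored as matrices
# (grayscale) or r x c x 3 arrays (RGB) with values in [0, 1]. Geometric ops
# keep the input canvas, sampling out-of-range coordinates by mirror
# (reflect-101) padding, so shapes are stable down the pipeline.

#' Construct an image record
#'
#' @param pixels matrix or `r x c x 3` array with values in `[0, 1]`.
#' @param label optional class tag.
#' @param id source identifier.
#' @return an object of class `image_record` with append-only `provenance`.
#' @export
image_record <- function(pixels, label = NA_character_, id = "img") {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3)))
    stop("pixels must be a matrix or 3-d array")
  if (any(pixels < 0 | pixels > 1)) stop("pixel values must lie in [0, 1]")
  structure(list(pixels = pixels, label = label, id = id,
                 provenance = character()),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image record '%s' (%s): %dx%d%s, label=%s\n", x$id,
              paste(x$provenance, collapse = " -> "),
              d[1], d[2], if (length(d) == 3) "x3" else "", x$label))
  invisible(x)
}

per_channel <- function(pixels, f) {
  if (is.matrix(pixels)) return(f(pixels))
  chans <- lapply(seq_len(dim(pixels)[3]), function(ch) f(pixels[, , ch]))
  out <- array(0, c(dim(chans[[1]]), length(chans)))
  for (ch in seq_along(chans)) out[, , ch] <- chans[[ch]]
  out
}

# Bilinear resampling weights: output pixel centers map to input coordinates
# by src = (dst + 0.5) * n_in / n_out - 0.5 (edge samples clamped), so a 2x
# downsample averages each aligned 2x2 block exactly.
resize_weights <- function(n_out, n_in) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(pos)
  f <- pos - i0
  lo <- clamp(i0, 0, n_in - 1) + 1
  hi <- clamp(i0 + 1, 0, n_in - 1) + 1
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    w[i, lo[i]] <- w[i, lo[i]] + (1 - f[i])
    w[i, hi[i]] <- w[i, hi[i]] + f[i]
  }
  w
}

#' Bilinear image resize
#'
#' @param pixels matrix or 3-d array in `[0, 1]`.
#' @param out_size target `(rows, cols)`.
#' @return resized pixels, clipped to `[0, 1]`.
#' @export
bilinear_resize <- function(pixels, out_size) {
  d <- dim(pixels)
  wy <- resize_weights(out_size[1], d[1])
  wx <- resize_weights(out_size[2], d[2])
  per_channel(pixels, function(m) clamp(wy %*% m %*% t(wx), 0, 1))
}

# reflect-101 index mapping into 1..n (mirror at the border pixels)
reflect101 <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  m <- (i - 1L) %% p
  m[m < 0] <- m[m < 0] + p
  m[m >= n - 1L] <- p - m[m >= n - 1L]
  m + 1L
}

# Inverse-map affine warp about the image center with bilinear sampling and
# reflect-101 padding. `ainv` maps output (y, x) offsets to source offsets.
warp_affine <- function(mat, ainv) {
  d <- dim(mat)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yo <- matrix(seq_len(d[1]) - cy, d[1], d[2])
  xo <- matrix(seq_len(d[2]) - cx, d[1], d[2], byrow = TRUE)
  sy <- ainv[1, 1] * yo + ainv[1, 2] * xo + cy
  sx <- ainv[2, 1] * yo + ainv[2, 2] * xo + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  g <- function(yi, xi) {
    matrix(mat[cbind(reflect101(as.integer(yi), d[1]),
                     reflect101(as.integer(xi), d[2]))], d[1], d[2])
  }
  v <- g(y0, x0) * (1 - fy) * (1 - fx) + g(y0 + 1, x0) * fy * (1 - fx) +
    g(y0, x0 + 1) * (1 - fy) * fx + g(y0 + 1, x0 + 1) * fy * fx
  v
}

rotate_pixels <- function(pixels, angle) {
  a <- angle %% 360
  if (a == 0) return(pixels)
  if (a == 180) return(per_channel(pixels, function(m)
    m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]))
  d <- dim(pixels)
  if (a %in% c(90, 270) && d[1] == d[2]) {
    # exact index permutation on square canvases
    f <- if (a == 90) function(m) t(m)[rev(seq_len(nrow(m))), , drop = FALSE]
         else function(m) t(m)[, rev(seq_len(ncol(m))), drop = FALSE]
    return(per_channel(pixels, f))
  }
  th <- a * pi / 180
  ainv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  per_channel(pixels, function(m) clamp(warp_affine(m, ainv), 0, 1))
}

shear_pixels <- function(pixels, axis, degrees) {
  t <- tan(degrees * pi / 180)
  ainv <- if (axis == "x") matrix(c(1, 0, t, 1), 2, 2, byrow = TRUE)
          else matrix(c(1, t, 0, 1), 2, 2, byrow = TRUE)
  per_channel(pixels, function(m) clamp(warp_affine(m, ainv), 0, 1))
}

conv3x3 <- function(m, k) {
  d <- dim(m)
  pr <- reflect101(0:(d[1] + 1), d[1])
  pc <- reflect101(0:(d[2] + 1), d[2])
  p <- m[pr, pc, drop = FALSE]
  out <- matrix(0, d[1], d[2])
  for (i in 1:3) for (j in 1:3)
    out <- out + k[i, j] * p[i:(i + d[1] - 1), j:(j + d[2] - 1)]
  out
}

blend_filter <- function(pixels, kernel, level, absval = FALSE) {
  per_channel(pixels, function(m) {
    f <- conv3x3(m, kernel)
    if (absval) f <- abs(f)
    clamp(m + level * (clamp(f, 0, 1) - m), 0, 1)
  })
}

#' Preprocess an image: bilinear resize, median filter, CLAHE
#'
#' Applies, in order: bilinear resize to `out_size`, a `median_k x median_k`
#' median filter (`median_k = 1` disables it), and contrast-limited adaptive
#' histogram equalization (`clahe = NULL` disables it). Values stay in
#' `[0, 1]`.
#'
#' @param img an [image_record()] (or raw pixel matrix/array).
#' @param out_size target `(rows, cols)`, default `c(256, 256)`.
#' @param median_k odd median kernel width, default 3.
#' @param clahe list with `clip` (contrast limit, default 2) and `tiles`
#'   (grid, default `c(8, 8)`), or `NULL` to disable.
#' @return an object of the same type as `img`, provenance appended.
#' @export
preprocess_image <- function(img, out_size = c(256, 256), median_k = 3,
                             clahe = list(clip = 2, tiles = c(8, 8))) {
  rec <- if (inherits(img, "image_record")) img else image_record(img)
  if (any(out_size < 1)) stop("out_size must be positive")
  if (median_k %% 2 != 1 || median_k < 1) stop("median_k must be odd >= 1")
  px <- bilinear_resize(rec$pixels, out_size)
  if (median_k > 1)
    px <- per_channel(px, function(m)
      as.matrix(EBImage::medianFilter(m, (median_k - 1) / 2)))
  if (!is.null(clahe))
    px <- per_channel(px, function(m)
      clamp(as.matrix(EBImage::clahe(m, nx = clahe$tiles[1],
                                     ny = clahe$tiles[2],
                                     limit = clahe$clip)), 0, 1))
  rec$pixels <- px
  rec$provenance <- c(rec$provenance, sprintf("preprocess(%dx%d,median%d,%s)",
    out_size[1], out_size[2], median_k,
    if (is.null(clahe)) "noclahe" else "clahe"))
  if (inherits(img, "image_record")) rec else rec$pixels
}

#' The 30-variant augmentation catalogue
#'
#' Four intensity levels each of sharpen and emboss (0.5, 1, 1.5, 2), four
#' Gaussian blur scales (0.25, 0.5, 1, 2), four rotation angles (45, 90,
#' 135, 180 degrees), four edge-enhancement levels (0.25, 0.5, 0.75, 1),
#' four skew directions (left, right, forward, backward; 10 degrees), four
#' flips (left, right, top, bottom) and shears of 10 degrees along each of
#' the two axes: 4 x 7 + 2 = 30 operations.
#'
#' @return a data.frame with columns `name` and `parameter` (30 rows, unique
#'   pairs).
#' @export
augmentation_catalogue <- function() {
  rbind(
    data.frame(name = "sharpen", parameter = c("0.5", "1", "1.5", "2")),
    data.frame(name = "emboss", parameter = c("0.5", "1", "1.5", "2")),
    data.frame(name = "gaussian_blur", parameter = c("0.25", "0.5", "1", "2")),
    data.frame(name = "rotate", parameter = c("45", "90", "135", "180")),
    data.frame(name = "edge", parameter = c("0.25", "0.5", "0.75", "1")),
    data.frame(name = "skew", parameter = c("left", "right", "forward", "backward")),
    data.frame(name = "flip", parameter = c("left", "right", "top", "bottom")),
    data.frame(name = "shear", parameter = c("x", "y"))
  )
}

#' Apply one augmentation operation
#'
#' Output canvas equals the input canvas; values are clipped to `[0, 1]`;
#' the record's provenance is appended. Filter "levels" blend between the
#' identity image and the unit-strength filtered image (level 1 is the full
#' filter effect; level 2 over-drives it, then clips).
#'
#' @param img an [image_record()] (or raw pixels).
#' @param name op name from [augmentation_catalogue()].
#' @param parameter op parameter (level / angle / direction / axis) as in
#'   the catalogue.
#' @return augmented image of the same type as `img`.
#' @export
apply_augmentation <- function(img, name, parameter) {
  rec <- if (inherits(img, "image_record")) img else image_record(img)
  px <- rec$pixels
  sharpen_k <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
  emboss_k <- matrix(c(-2, -1, 0, -1, 1, 1, 0, 1, 2), 3, 3)
  laplace_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  out <- switch(name,
    sharpen = blend_filter(px, sharpen_k, as.numeric(parameter)),
    emboss = blend_filter(px, emboss_k, as.numeric(parameter)),
    edge = blend_filter(px, laplace_k, as.numeric(parameter), absval = TRUE),
    gaussian_blur = per_channel(px, function(m) {
      sg <- as.numeric(parameter)
      r <- 2 * ceiling(3 * sg) + 1
      r <- min(r, (min(dim(m)) %/% 2) * 2 - 1)  # brush must fit the image
      clamp(as.matrix(EBImage::gblur(m, sigma = sg, radius = r)), 0, 1)
    }),
    rotate = rotate_pixels(px, as.numeric(parameter)),
    flip = switch(parameter,
      left = , right = per_channel(px, function(m)
        m[, rev(seq_len(ncol(m))), drop = FALSE]),
      top = , bottom = per_channel(px, function(m)
        m[rev(seq_len(nrow(m))), , drop = FALSE]),
      stop("unknown flip parameter: ", parameter)),
    skew = switch(parameter,
      left = shear_pixels(px, "x", -10),
      right = shear_pixels(px, "x", 10),
      forward = shear_pixels(px, "y", -10),
      backward = shear_pixels(px, "y", 10),
      stop("unknown skew parameter: ", parameter)),
    shear = switch(parameter,
      x = shear_pixels(px, "x", 10),
      y = shear_pixels(px, "y", 10),
      stop("unknown shear parameter: ", parameter)),
    stop("unknown augmentation op: ", name))
  rec$pixels <- out
  rec$provenance <- c(rec$provenance, paste0(name, "(", parameter, ")"))
  if (inherits(img, "image_record")) rec else rec$pixels
}

#' Sevenfold augmentation plan
#'
#' For each source image, keeps the original and samples 6 distinct
#' operations from the 30-variant catalogue without replacement, so the
#' dataset grows exactly sevenfold with labels inherited. Separating the
#' plan from its application makes the dataset arithmetic (expansion and
#' split counts) checkable without touching pixels.
#'
#' @param manifest data.frame with columns `id` and `label`, one row per
#'   source image.
#' @param seed integer seed for the per-image op sampling.
#' @return a data.frame with columns `id`, `label`, `op`, `parameter`
#'   (7 rows per source; `op = "original"` for the untouched copy).
#' @export
sevenfold_plan <- function(manifest, seed = 1L) {
  if (nrow(manifest) == 0) stop("empty dataset")
  cat30 <- augmentation_catalogue()
  set.seed(seed)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    pick <- sample.int(nrow(cat30), 6)
    data.frame(id = manifest$id[i], label = manifest$label[i],
               op = c("original", cat30$name[pick]),
               parameter = c("", cat30$parameter[pick]))
  })
  do.call(rbind, rows)
}

#' Sevenfold dataset augmentation
#'
#' Applies a [sevenfold_plan()] to a list of image records: each source
#' contributes itself plus six augmented variants; output length is exactly
#' seven times the input length, per class and in total.
#'
#' @param records list of [image_record()]s.
#' @param seed integer seed (drives the op sampling).
#' @return a list of `7 * length(records)` image records.
#' @export
sevenfold_augment <- function(records, seed = 1L) {
  if (length(records) == 0) stop("empty dataset")
  manifest <- data.frame(
    id = vapply(records, function(r) r$id, character(1)),
    label = vapply(records, function(r) as.character(r$label), character(1)))
  plan <- sevenfold_plan(manifest, seed)
  out <- vector("list", nrow(plan))
  by_id <- stats::setNames(seq_along(records), manifest$id)
  for (i in seq_len(nrow(plan))) {
    src <- records[[by_id[[plan$id[i]]]]]
    out[[i]] <- if (plan$op[i] == "original") src
      else apply_augmentation(src, plan$op[i], plan$parameter[i])
  }
  out
}

#' Train/test split accounting
#'
#' Default rule: `test = floor((1 - train_frac) * count)` and
#' `train = count - test` per class. When `test_overrides` is supplied
#' (named per-class test counts, e.g. to reproduce a published split table
#' exactly), `train = count - override`.
#'
#' @param class_counts named integer vector of per-class totals.
#' @param train_frac training fraction in (0, 1), default 0.7.
#' @param test_overrides optional named per-class test counts.
#' @return a data.frame with columns `class`, `train`, `test`
#'   (`train + test == count` for every class).
#' @export
split_counts <- function(class_counts, train_frac = 0.7, test_overrides = NULL) {
  if (any(class_counts < 1)) stop("counts must be >= 1")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  cls <- names(class_counts)
  test <- if (is.null(test_overrides)) {
    floor((1 - train_frac) * class_counts)
  } else {
    ov <- test_overrides[cls]
    if (any(is.na(ov))) stop("test_overrides must name every class")
    if (any(ov > class_counts)) stop("override exceeds class count")
    as.numeric(ov)
  }
  data.frame(class = cls, train = as.numeric(class_counts) - test,
             test = as.numeric(test), row.names = NULL)
}

#' Per-source, per-class fundus dataset counts
#'
#' The source image inventory the augmentation bookkeeping starts from:
#' 516 diabetic-retinopathy images (IDRiD), 10 each of DR, diabetic macular
#' edema and glaucoma (DR-HAGIS) and 1131/171/207 (ODIR), 2055 in total.
#'
#' @return a data.frame with columns `source`, `class`, `count`.
#' @export
fundus_dataset_counts <- function() {
  data.frame(
    source = c("IDRiD", rep("DR-HAGIS", 3), rep("ODIR", 3)),
    class = c("DR", "DR", "DME", "Glaucoma", "DR", "DME", "Glaucoma"),
    count = c(516, 10, 10, 10, 1131, 171, 207))
}

#' Read / write PNG images and binary masks
#'
#' Images map 8-bit PNG values to `[0, 1]`; masks binarize at the half
#' intensity threshold on read and are written as 0/255.
#'
#' @param path PNG file path.
#' @return `read_image_png`: pixels in `[0, 1]`; `read_mask_png`: 0/1
#'   integer matrix.
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
  px
}

#' @rdname read_image_png
#' @param pixels image pixels in `[0, 1]`.
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(clamp(pixels, 0, 1), path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  px <- read_image_png(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  (px >= 128 / 255) * 1L
}

#' @rdname read_image_png
#' @param mask 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask >= 1, 1, 0), path)
  invisible(path)
}
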