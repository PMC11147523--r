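# Synthetic fixtures: canonical optimizer benchmark functions, labeled
# feature tables with a known informative/noise split (emulating the
# CNN-derived feature tables the classifier consumes), and image/mask
# segmentation tasks with blob-like lesions on textured backgrounds.

#' Catalogue of benchmark objective functions
#'
#' Six canonical test functions with their standard literature bounds and
#' known global minima: sphere, schwefel222 and rosenbrock (unimodal);
#' rastrigin, ackley and griewank (multimodal). All have global minimum 0.
#'
#' @param name optional single name; when given, only that entry is returned.
#' @return a named list; each entry has `fn` (vector -> scalar), `bounds`
#'   (lo, hi), `fmin` and `minimizer` (per-dimension coordinate).
#' @export
benchmark_suite <- function(name = NULL) {
  suite <- list(
    sphere = list(fn = function(x) sum(x^2),
                  bounds = c(-100, 100), fmin = 0, minimizer = 0),
    schwefel222 = list(fn = function(x) sum(abs(x)) + prod(abs(x)),
                       bounds = c(-10, 10), fmin = 0, minimizer = 0),
    rosenbrock = list(fn = function(x) {
      n <- length(x)
      if (n < 2) return((1 - x)^2)
      sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
    }, bounds = c(-30, 30), fmin = 0, minimizer = 1),
    rastrigin = list(fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
                     bounds = c(-5.12, 5.12), fmin = 0, minimizer = 0),
    ackley = list(fn = function(x) {
      n <- length(x)
      -20 * exp(-0.2 * sqrt(sum(x^2) / n)) - exp(sum(cos(2 * pi * x)) / n) +
        20 + exp(1)
    }, bounds = c(-32, 32), fmin = 0, minimizer = 0),
    griewank = list(fn = function(x) {
      sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
    }, bounds = c(-600, 600), fmin = 0, minimizer = 0)
  )
  if (is.null(name)) return(suite)
  if (!name %in% names(suite)) stop("unknown benchmark: ", name)
  suite[[name]]
}

#' Synthetic labeled feature table with known informative structure
#'
#' Balanced classes; each informative feature is class-conditionally Gaussian
#' with unit variance and class means `0, class_sep, 2 class_sep, ...` (so
#' adjacent classes are separated by `class_sep` standard deviations per
#' informative dimension); noise features are standard normal, independent of
#' the label. The informative column indices are recorded so feature-recovery
#' experiments can be scored exactly.
#'
#' @param n total samples (>= 10 per class).
#' @param k_informative number of informative features (>= 1).
#' @param k_noise number of pure-noise features.
#' @param class_sep per-dimension mean separation in units of sigma.
#' @param n_classes number of balanced classes.
#' @param seed integer seed.
#' @return a list of class `synthetic_classification_task`: `x`
#'   (`n x (k_informative + k_noise)` matrix, informative columns first),
#'   `y` (factor), `informative_indices`, `bayes_accuracy_floor` (two-class
#'   Gaussian error bound; `NA` for more classes) and the generator params.
#' @export
make_classification_data <- function(n, k_informative, k_noise = 0,
                                     class_sep = 2, n_classes = 2, seed = 1L) {
  if (k_informative < 1) stop("k_informative must be >= 1")
  if (n < 10 * n_classes) stop("need n >= 10 * n_classes")
  set.seed(seed)
  per <- n %/% n_classes
  n <- per * n_classes
  y <- factor(rep(paste0("c", seq_len(n_classes)), each = per))
  d <- k_informative + k_noise
  x <- matrix(stats::rnorm(n * d), n, d)
  for (c in seq_len(n_classes)) {
    rows <- which(as.integer(y) == c)
    x[rows, seq_len(k_informative)] <-
      x[rows, seq_len(k_informative)] + class_sep * (c - 1)
  }
  bayes <- if (n_classes == 2)
    stats::pnorm(class_sep * sqrt(k_informative) / 2) else NA_real_
  structure(list(x = x, y = y,
                 informative_indices = seq_len(k_informative),
                 bayes_accuracy_floor = bayes,
                 params = list(n = n, k_informative = k_informative,
                               k_noise = k_noise, class_sep = class_sep,
                               n_classes = n_classes, seed = seed)),
            class = "synthetic_classification_task")
}

#' Synthetic image/mask segmentation task
#'
#' Truth masks are unions of random disks (guaranteed nonempty); images place
#' the mask at a high intensity band over a smooth low-frequency background
#' texture, plus optional Gaussian pixel noise. With `noise_sd = 0` the
#' foreground and background bands do not overlap, so thresholding the image
#' at 0.5 recovers the truth mask exactly.
#'
#' @param n number of image/mask pairs.
#' @param size `(rows, cols)`, each >= 32.
#' @param blob_count_range integer range of disks per mask.
#' @param radius_range disk radius range in pixels.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed integer seed.
#' @return a list of class `synthetic_segmentation_task`: `images` (list of
#'   matrices in `[0, 1]`), `truths` (list of 0/1 matrices), `params`.
#' @export
make_segmentation_data <- function(n, size = c(64, 64),
                                   blob_count_range = c(1, 4),
                                   radius_range = c(4, 10),
                                   noise_sd = 0.02, seed = 1L) {
  if (any(size < 32)) stop("size must be >= 32x32")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  r <- size[1]; cc <- size[2]
  rowg <- matrix(seq_len(r), r, cc)
  colg <- matrix(seq_len(cc), r, cc, byrow = TRUE)
  images <- vector("list", n)
  truths <- vector("list", n)
  for (m in seq_len(n)) {
    mask <- matrix(0L, r, cc)
    nb <- sample(blob_count_range[1]:blob_count_range[2], 1)
    for (b in seq_len(nb)) {
      rad <- stats::runif(1, radius_range[1], radius_range[2])
      cy <- stats::runif(1, rad + 1, r - rad)
      cx <- stats::runif(1, rad + 1, cc - rad)
      mask[(rowg - cy)^2 + (colg - cx)^2 <= rad^2] <- 1L
    }
    # smooth background texture: a few random low-frequency sinusoids in [0,1]
    tex <- 0
    for (k in 1:3) {
      fr <- stats::runif(2, 0.5, 2)
      ph <- stats::runif(2, 0, 2 * pi)
      tex <- tex + sin(2 * pi * fr[1] * rowg / r + ph[1]) *
        cos(2 * pi * fr[2] * colg / cc + ph[2])
    }
    tex <- (tex - min(tex)) / (max(tex) - min(tex) + 1e-12)
    img <- ifelse(mask == 1L, 0.75, 0.25) + 0.2 * (tex - 0.5)
    if (noise_sd > 0) img <- img + stats::rnorm(r * cc, sd = noise_sd)
    images[[m]] <- clamp(img, 0, 1)
    truths[[m]] <- mask
  }
  structure(list(images = images, truths = truths,
                 params = list(n = n, size = size,
                               blob_count_range = blob_count_range,
                               radius_range = radius_range,
                               noise_sd = noise_sd, seed = seed)),
            class = "synthetic_segmentation_task")
}
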