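# Encoder-decoder segmentation-network hyperparameter search: a fixed
# 22-field architecture encoding (4 conv + 2 max-pool + 2 dropout on the
# encoder side; 2 upsampling + 4 transposed-conv on the decoder side), a
# smoothed mean-Jaccard fitness over mask pairs, and a G-GWO search loop
# against a pluggable evaluator. Actual network training stays behind the
# evaluator interface; the package ships a deterministic desk-scale
# surrogate so the loop is testable end to end.

# The 22 encoded fields in their fixed order, with kind and range.
# kinds: count -> round + clamp to [20,200]; ks -> snap to {3,5} (tie 3);
# ps -> snap to {2,3} (tie 2); dr -> clamp to [0.2,0.4].
fcedn_fields <- function() {
  data.frame(
    name = c("c1_nk", "c1_ks", "c2_nk", "c2_ks", "mp1_ps", "dl1_dr",
             "c3_nk", "c3_ks", "c4_nk", "c4_ks", "mp2_ps", "dl2_dr",
             "up1_ps", "tc1_nk", "tc1_ks", "tc2_nk", "tc2_ks", "up2_ps",
             "tc3_ks", "tc3_nk", "tc4_ks", "tc4_nk"),
    kind = c("count", "ks", "count", "ks", "ps", "dr",
             "count", "ks", "count", "ks", "ps", "dr",
             "ps", "count", "ks", "count", "ks", "ps",
             "ks", "count", "ks", "count"),
    stringsAsFactors = FALSE
  )
}

kind_range <- function(kind) switch(kind,
  count = c(20, 200), ks = c(3, 5), ps = c(2, 3), dr = c(0.2, 0.4))

#' Search-space bounds of the 22-field architecture encoding
#'
#' @return a 22 x 2 matrix of per-dimension (lo, hi), rows named by field.
#' @export
fcedn_bounds <- function() {
  f <- fcedn_fields()
  b <- t(vapply(f$kind, kind_range, numeric(2)))
  rownames(b) <- f$name
  b
}

#' Decode a 22-vector into architecture hyperparameters
#'
#' Kernel counts are rounded then clamped to `[20, 200]`; kernel sizes snap
#' to the nearest of `{3, 5}` (tie to 3); pooling/upsampling sizes snap to
#' `{2, 3}` (tie to 2); dropout rates clamp to `[0.2, 0.4]`. The field order
#' is fixed: C1, C2, MP1, DL1, C3, C4, MP2, DL2, UP1, TC1, TC2, UP2, TC3,
#' TC4 with per-layer (count, size) pairs, the last two transposed-conv
#' layers listed (size, count).
#'
#' @param vector numeric vector of length 22.
#' @return a named list of class `fcedn_hyperparams`.
#' @export
decode_hyperparams <- function(vector) {
  if (length(vector) != 22) stop("encoding vector must have length 22")
  f <- fcedn_fields()
  out <- mapply(function(v, kind) {
    r <- kind_range(kind)
    switch(kind,
      count = clamp(round(v), r[1], r[2]),
      ks = if (v < 4) 3 else if (v > 4) 5 else 3,
      ps = if (v < 2.5) 2 else if (v > 2.5) 3 else 2,
      dr = clamp(v, r[1], r[2]))
  }, vector, f$kind)
  names(out) <- f$name
  structure(as.list(out), class = "fcedn_hyperparams")
}

#' Encode architecture hyperparameters into a 22-vector
#'
#' Inverse of [decode_hyperparams()]; every field is validated against its
#' range before encoding, so `decode(encode(hp))` is the identity on valid
#' inputs.
#'
#' @param hp an `fcedn_hyperparams` list (or plain named list with the 22
#'   fields).
#' @return a numeric vector of length 22 in the fixed field order.
#' @export
encode_hyperparams <- function(hp) {
  f <- fcedn_fields()
  if (!all(f$name %in% names(hp))) stop("missing hyperparameter fields")
  v <- vapply(seq_len(nrow(f)), function(i) {
    val <- as.numeric(hp[[f$name[i]]])
    kind <- f$kind[i]; r <- kind_range(kind)
    ok <- switch(kind,
      count = val == round(val) && val >= r[1] && val <= r[2],
      ks = val %in% c(3, 5),
      ps = val %in% c(2, 3),
      dr = val >= r[1] && val <= r[2])
    if (!ok) stop("field ", f$name[i], " = ", val, " outside its valid range")
    val
  }, numeric(1))
  names(v) <- f$name
  v
}

#' @export
print.fcedn_hyperparams <- function(x, ...) {
  cat("encoder-decoder architecture hyperparameters:\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

#' Smoothed mean-Jaccard fitness of mask pairs
#'
#' Mean over mask pairs of the epsilon-smoothed Jaccard coefficient
#' `(eps + |y * yhat|) / ((eps + |y|) + (eps + |yhat|) - (eps + |y * yhat|))`.
#' Equals 1 iff every prediction matches its truth exactly; symmetric in
#' truth and prediction; as `eps -> 0` it approaches the classical
#' intersection-over-union.
#'
#' @param pairs list of mask pairs, each a list with binary matrices `truth`
#'   and `prediction` of identical shape.
#' @param eps smoothing constant in `(0, 1]`, default 1.
#' @return a scalar in `(0, 1]`.
#' @export
jaccard_fitness <- function(pairs, eps = 1) {
  if (length(pairs) < 1) stop("need at least one mask pair")
  if (eps <= 0) stop("eps must be > 0")
  vals <- vapply(pairs, function(p) {
    y <- p$truth; yh <- p$prediction
    if (!all(dim(y) == dim(yh))) stop("mask shape mismatch within a pair")
    inter <- sum(y * yh)
    (eps + inter) / ((eps + sum(y)) + (eps + sum(yh)) - (eps + inter))
  }, numeric(1))
  mean(vals)
}

#' Construct a desk-scale surrogate segmentation task
#'
#' Draws a task-specific optimal architecture `hp_star` uniformly inside the
#' 22-dimensional search box (then decoded) and a small set of synthetic
#' truth masks. The [surrogate_segmenter()] evaluated on this task has its
#' maximum smoothed-Jaccard fitness exactly at `hp_star`.
#'
#' @param seed integer task seed.
#' @param n_images number of truth masks.
#' @param size mask size (rows, cols).
#' @return a list of class `fcedn_surrogate_task` with `truths`, `hp_star`,
#'   `seed`.
#' @export
surrogate_task <- function(seed = 1L, n_images = 4, size = c(32, 32)) {
  b <- fcedn_bounds()
  set.seed(seed)
  raw <- b[, 1] + (b[, 2] - b[, 1]) * stats::runif(22)
  hp_star <- decode_hyperparams(raw)
  seg <- make_segmentation_data(n_images, size = size, noise_sd = 0,
                                seed = derive_seed(seed, "masks"))
  structure(list(truths = seg$truths, hp_star = hp_star, seed = seed),
            class = "fcedn_surrogate_task")
}

#' Deterministic surrogate segmenter
#'
#' Stands in for training the encoder-decoder network during architecture
#' search. Prediction quality is a smooth, unimodal, deterministic function
#' of the candidate architecture: let `d` be the normalized (per-dimension
#' range-scaled) root-mean-square distance between the candidate's encoding
#' and the task optimum `hp_star`; each predicted mask is the truth mask
#' with a fraction `d^2` of its pixels removed (in fixed scan order).
#' Fitness therefore peaks (at 1) exactly at `hp_star` and decays
#' monotonically along any ray away from it. Quadratic decay keeps the
#' objective informative near the optimum while a single mis-snapped
#' discrete field is not catastrophic.
#'
#' @param hp a valid `fcedn_hyperparams` candidate.
#' @param task a [surrogate_task()].
#' @return a list of mask pairs suitable for [jaccard_fitness()].
#' @export
surrogate_segmenter <- function(hp, task) {
  stopifnot(inherits(task, "fcedn_surrogate_task"))
  b <- fcedn_bounds()
  v <- encode_hyperparams(hp)
  v_star <- encode_hyperparams(task$hp_star)
  d <- sqrt(mean(((v - v_star) / (b[, 2] - b[, 1]))^2))
  lapply(task$truths, function(truth) {
    s <- sum(truth)
    k <- round(s * min(1, d^2))
    pred <- truth
    if (k > 0) {
      on <- which(pred == 1L)  # column-major scan order, deterministic
      pred[on[seq_len(k)]] <- 0L
    }
    list(truth = truth, prediction = pred)
  })
}

#' G-GWO architecture search over the 22-field encoding
#'
#' Maximizes the smoothed mean-Jaccard fitness of the masks an evaluator
#' produces for each decoded candidate architecture, using the
#' genetic-seeded grey wolf optimizer over the encoding box.
#'
#' @param evaluator function `fcedn_hyperparams -> list of mask pairs`
#'   (e.g. a closure over [surrogate_segmenter()] and a task, or a real
#'   network-training harness).
#' @param pop_size,max_iter optimizer size (defaults 8, 50).
#' @param eps Jaccard smoothing constant.
#' @param seed integer seed.
#' @return a list with `hp` (best decoded `fcedn_hyperparams`), `fitness`
#'   (best smoothed-Jaccard value) and `result` (the underlying
#'   `opt_result`; its history tracks the negated fitness).
#' @export
search_architecture <- function(evaluator, pop_size = 8, max_iter = 50,
                                eps = 1, seed = NULL) {
  b <- fcedn_bounds()
  objective <- function(position) {
    hp <- decode_hyperparams(position)
    pairs <- tryCatch(evaluator(hp), error = function(e)
      stop("evaluator failed on hp [",
           paste(signif(unlist(hp), 4), collapse = ", "), "]: ",
           conditionMessage(e)))
    -jaccard_fitness(pairs, eps)
  }
  res <- ggwo_optimize(objective, b, dims = 22, pop_size = pop_size,
                       max_iter = max_iter, seed = seed)
  list(hp = decode_hyperparams(res$best_position),
       fitness = -res$best_fitness, result = res)
}
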