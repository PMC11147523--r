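# The fused classifier: G-GWO drives binary feature selection and/or KELM
# hyperparameter tuning under a fitness that balances validation performance
# against subset size:  fitness = alpha * P + (1 - alpha) * (N - L) / N,
# where P is the validation score, L the number of selected features and N
# the total feature count.

#' Combine validation score and subset size into the selection fitness
#'
#' The scalar objective the wrapper search maximizes:
#' `alpha * p + (1 - alpha) * (n - l) / n` for validation score `p`,
#' selected-feature count `l` and total feature count `n`. With
#' `alpha = 0.99` it equals 0.99 exactly when `p = 1` and all features are
#' kept, and strictly decreases in `l` at fixed `p`.
#'
#' @param p validation score in `[0, 1]`.
#' @param l number of selected features, `1 <= l <= n`.
#' @param n total number of features.
#' @param alpha weight on the validation score.
#' @return the scalar fitness in `[0, 1)`.
#' @export
selection_fitness <- function(p, l, n, alpha = 0.99) {
  stopifnot(p >= 0, p <= 1, l >= 1, l <= n, alpha >= 0, alpha <= 1)
  alpha * p + (1 - alpha) * (n - l) / n
}

# Fit-and-score one candidate: KELM on the flagged training columns,
# validation score P on the holdout side. Returns the fitness components.
eval_candidate <- function(flags, x, y, train_idx, alpha, c_reg, gamma,
                           fitness_measure = "accuracy") {
  n_feat <- ncol(x)
  l <- sum(flags)
  xs <- x[, flags == 1L, drop = FALSE]
  ytr <- y[train_idx]; yva <- y[-train_idx]
  model <- kelm(xs[train_idx, , drop = FALSE], ytr, c_reg = c_reg, gamma = gamma)
  pred <- predict(model, xs[-train_idx, , drop = FALSE])
  p <- if (fitness_measure == "accuracy") {
    mean(pred == as.character(yva))
  } else {
    # positive-class precision (last class); macro precision for > 2 classes
    cls <- model$classes
    if (length(cls) == 2) {
      m <- classification_metrics(confusion_counts(as.character(yva), pred,
                                                   cls[length(cls)]))
      if (is.na(m["pre"])) 0 else unname(m["pre"])
    } else {
      rep <- one_vs_rest_report(as.character(yva), pred)
      v <- rep$pre[rep$class == "macro"]
      if (is.na(v)) 0 else v
    }
  }
  list(fitness = selection_fitness(p, l, n_feat, alpha), p = p, l = l)
}

#' Subset-size penalized fitness of a feature flag vector
#'
#' Fits a KELM on the flagged feature columns of the training side of a
#' stratified holdout split and returns
#' `alpha * P + (1 - alpha) * (N - L) / N`, where `P` is the validation
#' accuracy (fraction), `L` the number of selected features and `N` the
#' total. Higher is better; the value lies in `[0, 1)`.
#'
#' @param flags 0/1 vector of length `ncol(x)` with at least one 1.
#' @param x numeric feature matrix; `y` class labels.
#' @param y class labels (>= 2 classes).
#' @param alpha weight on validation performance (default 0.99).
#' @param c_reg,gamma KELM parameters (defaults C = 32, gamma = 0.5).
#' @param train_frac stratified training fraction (default 0.7).
#' @param split_seed seed of the holdout split (kept separate from any
#'   optimizer seed; the optimizer's random stream is not consumed).
#' @param fitness_measure `"accuracy"` (default) or `"precision"` for P.
#' @return the scalar fitness.
#' @export
subset_fitness <- function(flags, x, y, alpha = 0.99, c_reg = 32, gamma = 0.5,
                           train_frac = 0.7, split_seed = 1L,
                           fitness_measure = c("accuracy", "precision")) {
  fitness_measure <- match.arg(fitness_measure)
  x <- as.matrix(x)
  if (length(flags) != ncol(x)) stop("flags length must equal ncol(x)")
  if (sum(flags) == 0) stop("empty feature subset")
  idx <- stratified_split(y, train_frac, split_seed)
  if (length(unique(y[idx])) < length(unique(y)) ||
      length(unique(y[-idx])) < length(unique(y)))
    stop("a class is missing from one side of the split")
  eval_candidate(as.integer(flags), x, y, idx, alpha, c_reg, gamma,
                 fitness_measure)$fitness
}

#' Fit a G-GWO-tuned kernel extreme learning machine
#'
#' The package's central fitting routine. A genetic-algorithm-seeded grey
#' wolf optimizer searches, depending on `mode`:
#' \describe{
#'   \item{`"features"`}{a continuous position per feature on the domain
#'     `[-1, 2]`, stochastically binarized into a feature flag vector at each
#'     evaluation (a coordinate above a fresh uniform draw selects the
#'     feature); KELM parameters stay at `(c_reg, gamma)`.}
#'   \item{`"hyperparams"`}{`(log2 C, log2 gamma)` over
#'     `[log2 c_range] x [log2 gamma_range]`, with all features kept.}
#'   \item{`"joint"`}{both: the two hyperparameter coordinates appended to
#'     the per-feature coordinates.}
#' }
#' Each candidate is scored by the subset-size penalized validation fitness
#' (see [subset_fitness()]); candidates selecting no features receive a worst
#' sentinel fitness so the swarm can recover rather than aborting. The
#' best-ever candidate's flags and parameters are refitted on the training
#' side and returned with holdout metrics.
#'
#' @inheritParams subset_fitness
#' @param mode search mode, see above.
#' @param pop_size,max_iter optimizer size (defaults 8 wolves, 200
#'   iterations).
#' @param domain feature-selection box, default `c(-1, 2)`.
#' @param c_range,gamma_range hyperparameter search ranges (defaults
#'   `2^-5..2^15` and `2^-10..2^5`); degenerate `lo == hi` ranges collapse
#'   the search to that value.
#' @param ga_generations GA seeding generations (default 10).
#' @param seed master seed; the holdout split uses a child seed derived from
#'   it unless `split_seed` is given explicitly.
#' @return an object of class `ggwo_kelm`: list with `flags`, `n_selected`,
#'   `fitness`, `tuned_c`, `tuned_gamma`, `history`, `evaluations`,
#'   `holdout_accuracy`, `holdout_metrics` (one-vs-rest report), `model`
#'   (the refitted [kelm()]), `train_idx`, `mode`, `alpha`, `seed`.
#' @seealso [select_features()], [tune_hyperparameters()], [predict.ggwo_kelm()]
#' @export
ggwo_kelm <- function(x, y, mode = c("features", "hyperparams", "joint"),
                      pop_size = 8, max_iter = 200, alpha = 0.99,
                      domain = c(-1, 2), c_reg = 32, gamma = 0.5,
                      c_range = c(2^-5, 2^15), gamma_range = c(2^-10, 2^5),
                      train_frac = 0.7, split_seed = NULL,
                      ga_generations = 10,
                      fitness_measure = c("accuracy", "precision"),
                      seed = NULL) {
  mode <- match.arg(mode)
  fitness_measure <- match.arg(fitness_measure)
  x <- as.matrix(x)
  n_feat <- ncol(x)
  if (n_feat < 2 && mode != "hyperparams") stop("need >= 2 features")
  if (length(unique(y)) < 2) stop("need >= 2 classes")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(split_seed))
    split_seed <- if (is.null(seed)) 1L else derive_seed(seed, "split")
  idx <- stratified_split(y, train_frac, split_seed)
  if (length(unique(y[idx])) < length(unique(y)) ||
      length(unique(y[-idx])) < length(unique(y)))
    stop("a class is missing from one side of the split")

  hp_bounds <- rbind(log2(c_range), log2(gamma_range))
  bounds <- switch(mode,
    features = matrix(rep(domain, each = n_feat), ncol = 2),
    hyperparams = hp_bounds,
    joint = rbind(matrix(rep(domain, each = n_feat), ncol = 2), hp_bounds))
  dims <- nrow(bounds)

  best <- new.env(parent = emptyenv())
  best$fitness <- -Inf
  objective <- function(position) {
    if (mode == "hyperparams") {
      flags <- rep(1L, n_feat)
      cg <- 2^position
    } else {
      flags <- binarize_position(position[seq_len(n_feat)])
      cg <- if (mode == "joint") 2^position[n_feat + 1:2] else c(c_reg, gamma)
    }
    if (sum(flags) == 0) return(1)  # worst sentinel: real values are <= 0
    ev <- eval_candidate(flags, x, y, idx, alpha, cg[1], cg[2], fitness_measure)
    if (ev$fitness > best$fitness) {
      best$fitness <- ev$fitness
      best$flags <- flags
      best$c <- cg[1]; best$gamma <- cg[2]
    }
    -ev$fitness
  }

  res <- ggwo_optimize(objective, bounds, dims, pop_size, max_iter,
                       ga_generations = ga_generations, seed = seed)
  flags <- best$flags
  model <- kelm(x[idx, flags == 1L, drop = FALSE], y[idx],
                c_reg = best$c, gamma = best$gamma)
  pred <- predict(model, x[-idx, flags == 1L, drop = FALSE])
  holdout <- one_vs_rest_report(as.character(y[-idx]), pred)
  structure(list(flags = flags, n_selected = sum(flags),
                 fitness = best$fitness,
                 tuned_c = best$c, tuned_gamma = best$gamma,
                 history = -res$history, evaluations = res$evaluations,
                 holdout_accuracy = mean(pred == as.character(y[-idx])),
                 holdout_metrics = holdout,
                 model = model, train_idx = idx, mode = mode,
                 alpha = alpha, seed = seed, split_seed = split_seed),
            class = "ggwo_kelm")
}

#' G-GWO wrapper feature selection with a KELM classifier
#'
#' Convenience wrapper over [ggwo_kelm()] with `mode = "features"`: searches
#' binary feature subsets on the continuous domain `[-1, 2]` per feature
#' with fixed KELM parameters.
#'
#' @inheritParams ggwo_kelm
#' @param ... passed to [ggwo_kelm()].
#' @return a `ggwo_kelm` object.
#' @export
select_features <- function(x, y, pop_size = 8, max_iter = 200, alpha = 0.99,
                            domain = c(-1, 2), c_reg = 32, gamma = 0.5,
                            seed = NULL, ...) {
  ggwo_kelm(x, y, mode = "features", pop_size = pop_size, max_iter = max_iter,
            alpha = alpha, domain = domain, c_reg = c_reg, gamma = gamma,
            seed = seed, ...)
}

#' G-GWO tuning of KELM hyperparameters
#'
#' Convenience wrapper over [ggwo_kelm()]: searches `(log2 C, log2 gamma)`
#' continuously, either with all features (`mode = "hyperparams"`) or
#' jointly with the feature flags (`mode = "joint"`).
#'
#' @inheritParams ggwo_kelm
#' @param ... passed to [ggwo_kelm()].
#' @return a `ggwo_kelm` object.
#' @export
tune_hyperparameters <- function(x, y, mode = c("hyperparams", "joint"),
                                 c_range = c(2^-5, 2^15),
                                 gamma_range = c(2^-10, 2^5),
                                 pop_size = 8, max_iter = 200, seed = NULL,
                                 ...) {
  mode <- match.arg(mode)
  ggwo_kelm(x, y, mode = mode, c_range = c_range, gamma_range = gamma_range,
            pop_size = pop_size, max_iter = max_iter, seed = seed, ...)
}

#' @export
print.ggwo_kelm <- function(x, ...) {
  cat(sprintf("G-GWO KELM fit (mode = %s)\n", x$mode))
  cat(sprintf("  selected %d / %d features; fitness %.4f\n",
              x$n_selected, length(x$flags), x$fitness))
  cat(sprintf("  C = %.4g, gamma = %.4g; holdout accuracy %.3f\n",
              x$tuned_c, x$tuned_gamma, x$holdout_accuracy))
  invisible(x)
}

#' @export
summary.ggwo_kelm <- function(object, ...) {
  print(object)
  cat("  flags:", paste(object$flags, collapse = ""), "\n")
  cat("  holdout one-vs-rest metrics:\n")
  print(object$holdout_metrics, digits = 3)
  invisible(object)
}

#' @export
predict.ggwo_kelm <- function(object, newdata, type = c("class", "score"), ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$flags))
    stop("newdata must have the full original feature set")
  predict(object$model, newdata[, object$flags == 1L, drop = FALSE],
          type = match.arg(type))
}

#' @export
coef.ggwo_kelm <- function(object, ...) coef(object$model)

#' @export
plot.ggwo_kelm <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "iteration", ylab = "best fitness so far", ...)
  invisible(x)
}

#' SVD dimensionality reduction
#'
#' Projects a column-centered matrix onto its top right singular directions;
#' the returned transform (centers + rotation) applies the same projection
#' to new data via [svd_project()].
#'
#' @param x numeric matrix.
#' @param rank number of retained directions, `1 <= rank <= min(dim(x))`.
#' @return a list with `scores` (`nrow(x) x rank`) and `transform`
#'   (class `svd_reduction`: `center`, `rotation`, `d` singular values).
#' @export
svd_reduce <- function(x, rank) {
  x <- as.matrix(x)
  if (rank < 1 || rank > min(dim(x))) stop("rank out of range")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc, nu = 0, nv = rank)
  transform <- structure(list(center = center,
                              rotation = sv$v[, seq_len(rank), drop = FALSE],
                              d = sv$d[seq_len(rank)]),
                         class = "svd_reduction")
  list(scores = xc %*% transform$rotation, transform = transform)
}

#' @rdname svd_reduce
#' @param transform an `svd_reduction` transform record.
#' @param newdata matrix with the original feature dimension.
#' @export
svd_project <- function(transform, newdata) {
  stopifnot(inherits(transform, "svd_reduction"))
  sweep(as.matrix(newdata), 2, transform$center) %*% transform$rotation
}
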