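# Grey wolf optimizer (GWO) and its genetic-algorithm-seeded variant (G-GWO).
# The pack's three best-ever solutions (alpha, beta, delta) steer every
# wolf's position update; the control parameter `a` decays linearly from 2
# to 0 so the search shifts from exploration to exploitation.

#' GWO control parameter
#'
#' Decreases linearly from 2 (at `t = 0`) to 0 (at `t = max_iter`):
#' `a = 2 (1 - t / max_iter)`.
#'
#' @param t current iteration, `0 <= t <= max_iter`.
#' @param max_iter total iterations (>= 1).
#' @export
control_parameter <- function(t, max_iter) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (t < 0 || t > max_iter) stop("t out of range [0, max_iter]")
  2 * (1 - t / max_iter)
}

#' GWO coefficient vectors
#'
#' Per dimension, `N = 2 a l1 - a` and `Q = 2 l2` with `l1, l2 ~ U[0,1]`
#' drawn fresh; hence `N` ranges over `[-a, a]` and `Q` over `[0, 2]`.
#'
#' @param a control parameter in `[0, 2]`.
#' @param dims dimensionality.
#' @param l1,l2 optional forced uniform draws (testing hooks).
#' @return a list with vectors `N` and `Q` of length `dims`.
#' @export
coefficient_vectors <- function(a, dims, l1 = NULL, l2 = NULL) {
  stopifnot(a >= 0, a <= 2)
  if (is.null(l1)) l1 <- stats::runif(dims)
  if (is.null(l2)) l2 <- stats::runif(dims)
  list(N = 2 * a * l1 - a, Q = 2 * l2)
}

#' One grey-wolf position update
#'
#' For each leader (alpha, beta, delta) with fresh coefficient vectors:
#' `Y_l = |Q_l * M_l - M|` and candidate `M_l' = M_l - N_l * Y_l`; the new
#' position is the mean of the three candidates, clamped to the bounds.
#' With `a = 0` every `N_l` is zero, so a wolf is pulled exactly to the
#' leaders' mean.
#'
#' @param wolf current position vector.
#' @param leaders list of three position vectors `(alpha, beta, delta)`.
#' @param a control parameter.
#' @param bounds per-dimension box (see [decode_chromosome()] bounds format).
#' @return the updated, clamped position vector.
#' @export
gwo_position_update <- function(wolf, leaders, a, bounds) {
  dims <- length(wolf)
  if (any(vapply(leaders, length, 1L) != dims)) stop("dimension mismatch")
  b <- expand_bounds(bounds, dims)
  cand <- vapply(leaders, function(m) {
    cv <- coefficient_vectors(a, dims)
    y <- abs(cv$Q * m - wolf)
    m - cv$N * y
  }, numeric(dims))
  clamp(rowMeans(matrix(cand, nrow = dims)), b[, 1], b[, 2])
}

# Maintain the three best-ever (position, fitness) records.
update_leaders <- function(leaders, pos, fit) {
  for (i in seq_along(fit)) {
    f <- fit[i]
    if (f < leaders$fit[3]) {
      if (f < leaders$fit[1]) {
        leaders$pos <- rbind(pos[i, ], leaders$pos[1:2, , drop = FALSE])
        leaders$fit <- c(f, leaders$fit[1:2])
      } else if (f < leaders$fit[2]) {
        leaders$pos <- rbind(leaders$pos[1, , drop = FALSE], pos[i, ],
                             leaders$pos[2, , drop = FALSE])
        leaders$fit <- c(leaders$fit[1], f, leaders$fit[2])
      } else {
        leaders$pos[3, ] <- pos[i, ]
        leaders$fit[3] <- f
      }
    }
  }
  leaders
}

#' Grey wolf optimization of a continuous objective
#'
#' Minimizes `objective` over a box. The three best-ever evaluated positions
#' are kept as the alpha/beta/delta leaders (elitist bookkeeping); each
#' iteration every wolf moves by [gwo_position_update()] and is re-evaluated.
#'
#' @param objective function position -> finite scalar (minimized).
#' @param bounds per-dimension box.
#' @param dims dimensionality.
#' @param pop_size number of wolves (>= 3); default 8.
#' @param max_iter iterations; default 200.
#' @param seed optional integer seed (set before any randomness).
#' @param init_positions optional `pop_size x dims` starting positions (e.g.
#'   from [ga_seed_positions()]); uniform random inside the box otherwise.
#' @param extra_evaluations evaluation count to add to the accounting (used
#'   by [ggwo_optimize()] for the GA phase).
#' @return an object of class `opt_result`: list with `best_position`,
#'   `best_fitness`, `history` (best-so-far per iteration, non-increasing),
#'   `evaluations` (`pop_size * (max_iter + 1)` plus any extra) and `seed`.
#' @export
gwo_optimize <- function(objective, bounds, dims, pop_size = 8, max_iter = 200,
                         seed = NULL, init_positions = NULL,
                         extra_evaluations = 0L) {
  if (pop_size < 3) stop("pop_size must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  b <- expand_bounds(bounds, dims)
  if (is.null(init_positions)) {
    pos <- matrix(stats::runif(pop_size * dims), pop_size, dims)
    pos <- sweep(sweep(pos, 2, b[, 2] - b[, 1], "*"), 2, b[, 1], "+")
  } else {
    pos <- as.matrix(init_positions)
    stopifnot(nrow(pos) == pop_size, ncol(pos) == dims)
    pos <- t(apply(pos, 1, clamp, lo = b[, 1], hi = b[, 2]))
    if (dims == 1) pos <- matrix(as.numeric(pos), ncol = 1)
  }
  eval_all <- function(p) {
    f <- apply(p, 1, objective)
    if (any(!is.finite(f))) {
      i <- which(!is.finite(f))[1]
      stop("non-finite objective value at position [",
           paste(signif(p[i, ], 6), collapse = ", "), "]")
    }
    f
  }
  fit <- eval_all(pos)
  leaders <- list(pos = matrix(Inf, 3, dims), fit = rep(Inf, 3))
  leaders <- update_leaders(leaders, pos, fit)
  history <- numeric(max_iter)
  for (t in seq_len(max_iter)) {
    a <- control_parameter(t, max_iter)
    lead_list <- list(leaders$pos[1, ], leaders$pos[2, ], leaders$pos[3, ])
    for (i in seq_len(pop_size))
      pos[i, ] <- gwo_position_update(pos[i, ], lead_list, a, b)
    fit <- eval_all(pos)
    leaders <- update_leaders(leaders, pos, fit)
    history[t] <- leaders$fit[1]
  }
  structure(list(best_position = as.numeric(leaders$pos[1, ]),
                 best_fitness = leaders$fit[1],
                 history = history,
                 evaluations = pop_size * (max_iter + 1L) + extra_evaluations,
                 seed = seed),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("optimizer result: best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  cat("  best position:", paste(signif(x$best_position, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.opt_result <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "iteration", ylab = "best fitness so far", ...)
  invisible(x)
}

#' Genetic-seeded grey wolf optimization (G-GWO)
#'
#' Identical to [gwo_optimize()] except that the initial swarm is produced by
#' a short genetic-algorithm run ([ga_seed_positions()]) instead of uniform
#' random sampling; the reported evaluation count includes the GA phase.
#'
#' @inheritParams gwo_optimize
#' @param ga_generations,ga_crossover_rate,ga_mutation_rate GA-phase
#'   parameters (defaults 10 generations, crossover 0.8, mutation 0.01).
#' @return an `opt_result`; see [gwo_optimize()].
#' @export
ggwo_optimize <- function(objective, bounds, dims, pop_size = 8, max_iter = 200,
                          ga_generations = 10, ga_crossover_rate = 0.8,
                          ga_mutation_rate = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ga <- ga_seed_positions(objective, bounds, dims, pop_size,
                          generations = ga_generations,
                          crossover_rate = ga_crossover_rate,
                          mutation_rate = ga_mutation_rate)
  gwo_optimize(objective, bounds, dims, pop_size, max_iter,
               init_positions = ga$positions,
               extra_evaluations = ga$evaluations)
}

#' Binarize a continuous position into a feature flag vector
#'
#' Flag j is 1 when `position[j]` exceeds a fresh uniform draw on `[0, 1)`.
#' On the feature-selection domain `[-1, 2]`, a coordinate at the upper bound
#' is always selected and one at the lower bound never is.
#'
#' @param position numeric vector.
#' @return an integer 0/1 vector of the same length.
#' @export
binarize_position <- function(position) {
  as.integer(position > stats::runif(length(position)))
}
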