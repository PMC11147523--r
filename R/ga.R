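# Genetic-algorithm operators used to seed the grey wolf optimizer's initial
# population: binary chromosomes with a fixed-point decode map, roulette-wheel
# selection, single-point crossover, uniform bit mutation, and elitism.

#' Random initial chromosome population
#'
#' @param pop_size number of chromosomes (>= 2).
#' @param n_bits bits per chromosome.
#' @return a `pop_size x n_bits` 0/1 integer matrix, one chromosome per row.
#' @export
init_chromosomes <- function(pop_size, n_bits) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (n_bits < 1) stop("n_bits must be >= 1")
  matrix(sample(0:1, pop_size * n_bits, replace = TRUE),
         nrow = pop_size, ncol = n_bits)
}

#' Roulette-wheel selection
#'
#' Draws one index with probability proportional to its nonnegative weight.
#' Callers minimizing an objective must first transform fitnesses into
#' nonnegative selection weights (see [ga_seed_positions()], which uses rank
#' weights).
#'
#' @param fitness_weights nonnegative weights, sum > 0.
#' @return a single index in `seq_along(fitness_weights)`.
#' @export
roulette_select <- function(fitness_weights) {
  if (any(fitness_weights < 0)) stop("negative selection weight")
  s <- sum(fitness_weights)
  if (s <= 0) stop("all-zero selection weights")
  sample.int(length(fitness_weights), 1L, prob = fitness_weights / s)
}

#' Single-point crossover
#'
#' With probability `rate` a cut point in `1:(len-1)` is drawn and the two
#' parents exchange suffixes; otherwise the parents are returned unchanged.
#'
#' @param p1,p2 0/1 vectors of equal length >= 2.
#' @param rate crossover probability in `[0, 1]`.
#' @param cut optional forced cut point (testing hook).
#' @return a list of two child chromosomes.
#' @export
single_point_crossover <- function(p1, p2, rate = 0.8, cut = NULL) {
  if (length(p1) != length(p2)) stop("length mismatch")
  len <- length(p1)
  if (len < 2) stop("chromosomes must have length >= 2")
  if (is.null(cut)) {
    if (stats::runif(1) > rate) return(list(p1, p2))
    cut <- sample.int(len - 1L, 1L)
  }
  c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):len])
  c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):len])
  list(c1, c2)
}

#' Uniform bit mutation
#'
#' Flips each bit independently with probability `rate`.
#'
#' @param chrom 0/1 vector.
#' @param rate per-bit flip probability in `[0, 1]`.
#' @export
uniform_mutation <- function(chrom, rate = 0.01) {
  stopifnot(rate >= 0, rate <= 1)
  flip <- stats::runif(length(chrom)) < rate
  chrom[flip] <- 1L - chrom[flip]
  chrom
}

#' Decode a chromosome into a real position
#'
#' Each gene of `bits_per_gene` bits is read as an unsigned integer `v` and
#' mapped affinely to its dimension's box:
#' `lo + (hi - lo) * v / (2^bits_per_gene - 1)`.
#'
#' @param chrom 0/1 vector of length `dims * bits_per_gene`.
#' @param bounds a 2-column matrix (or length-2 vector recycled to all
#'   dimensions) of per-dimension `(lo, hi)`.
#' @param dims number of real coordinates.
#' @return a numeric vector of length `dims`, inside the bounds.
#' @export
decode_chromosome <- function(chrom, bounds, dims) {
  if (length(chrom) %% dims != 0) stop("chromosome length not divisible by dims")
  bpg <- length(chrom) %/% dims
  b <- expand_bounds(bounds, dims)
  g <- matrix(chrom, nrow = dims, byrow = TRUE)
  v <- as.numeric(g %*% 2^((bpg - 1):0))
  b[, 1] + (b[, 2] - b[, 1]) * v / (2^bpg - 1)
}

# Normalize bounds input into a dims x 2 matrix.
expand_bounds <- function(bounds, dims) {
  if (is.matrix(bounds)) {
    if (nrow(bounds) == 1) bounds <- bounds[rep(1, dims), , drop = FALSE]
    stopifnot(nrow(bounds) == dims, ncol(bounds) == 2)
    b <- bounds
  } else {
    stopifnot(length(bounds) == 2)
    b <- matrix(rep(as.numeric(bounds), each = dims), ncol = 2)
  }
  if (any(b[, 2] < b[, 1])) stop("bounds must satisfy lo <= hi")
  b
}

#' Genetic-algorithm seeding of an optimizer population
#'
#' Runs a short binary GA (rank-weight roulette selection on the minimization
#' objective, single-point crossover, uniform mutation, elitism of the single
#' best chromosome) and decodes the final population into real positions.
#' These positions seed the grey wolf optimizer's first swarm.
#'
#' @param objective function mapping a position vector to a scalar
#'   (minimized).
#' @param bounds per-dimension box, as in [decode_chromosome()].
#' @param dims number of real coordinates.
#' @param pop_size population size (>= 3).
#' @param generations GA generations; 0 returns decoded random chromosomes.
#' @param crossover_rate,mutation_rate GA operator rates.
#' @param bits_per_gene bits per coordinate in the encoding.
#' @return a list with `positions` (`pop_size x dims` matrix inside bounds)
#'   and `evaluations` (objective calls spent).
#' @export
ga_seed_positions <- function(objective, bounds, dims, pop_size = 8,
                              generations = 10, crossover_rate = 0.8,
                              mutation_rate = 0.01, bits_per_gene = 16) {
  if (pop_size < 3) stop("pop_size must be >= 3")
  pop <- init_chromosomes(pop_size, dims * bits_per_gene)
  decode_all <- function(p) t(apply(p, 1, decode_chromosome, bounds = bounds, dims = dims))
  evals <- 0L
  fit <- NULL
  for (g in seq_len(max(0L, generations))) {
    pos <- decode_all(pop)
    fit <- apply(pos, 1, objective)
    evals <- evals + pop_size
    # rank weights: best chromosome gets weight pop_size, worst gets 1
    w <- pop_size + 1 - rank(fit, ties.method = "first")
    elite <- pop[which.min(fit), ]
    nxt <- matrix(0L, pop_size, ncol(pop))
    nxt[1, ] <- elite
    i <- 2L
    while (i <= pop_size) {
      pa <- pop[roulette_select(w), ]
      pb <- pop[roulette_select(w), ]
      ch <- single_point_crossover(pa, pb, crossover_rate)
      nxt[i, ] <- uniform_mutation(ch[[1]], mutation_rate)
      if (i + 1L <= pop_size) nxt[i + 1L, ] <- uniform_mutation(ch[[2]], mutation_rate)
      i <- i + 2L
    }
    pop <- nxt
  }
  list(positions = decode_all(pop), evaluations = evals)
}
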