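#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# Used so that data-split seeds never perturb the optimizer's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a named child seed from a master seed
#'
#' One master seed fans out to independent, reproducible child seeds for the
#' sub-systems of a run (GA seeding, wolf updates, binarization, data splits,
#' augmentation sampling). The derivation is a small deterministic hash of the
#' name folded into the master seed, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param name character tag of the sub-system.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  # double arithmetic: products stay below 2^53, so this is exact
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 40503) %% 2147483587)
}

# Stratified holdout indices: for each class, round(train_frac * n_c) samples
# go to training (at least 1 per class on each side when n_c >= 2).
stratified_split <- function(y, train_frac = 0.7, seed = 1L) {
  y <- as.factor(y)
  with_seed(seed, {
    idx <- unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      n_tr <- max(1L, min(length(i) - 1L, round(train_frac * length(i))))
      sample(i, n_tr)
    }), use.names = FALSE)
  })
  sort(idx)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
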