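# Small fixtures built in code.

# Two well-separated 2-D Gaussian clusters.
two_cluster_data <- function(n_per = 20, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

# XOR: the classic non-linearly-separable four-point problem.
xor_data <- function() {
  list(x = rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
       y = c("0", "0", "1", "1"))
}

# Concentric rings: radially separable, not linearly separable; kernel-width
# sensitive by construction.
rings_data <- function(n_per = 60, r_inner = 1, r_outer = 3, seed = 2) {
  set.seed(seed)
  th <- runif(2 * n_per, 0, 2 * pi)
  r <- c(rep(r_inner, n_per), rep(r_outer, n_per)) + rnorm(2 * n_per, sd = 0.1)
  list(x = cbind(r * cos(th), r * sin(th)),
       y = rep(c("inner", "outer"), each = n_per))
}

# A random valid architecture hyperparameter list.
random_hp <- function() {
  b <- fcedn_bounds()
  raw <- b[, 1] + (b[, 2] - b[, 1]) * runif(nrow(b))
  decode_hyperparams(raw)
}

total_variation <- function(m) {
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}
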