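# Kernel extreme learning machine: a single regularized linear solve in
# kernel space. Training solves (Omega + I/C) beta = T where Omega is the
# kernel Gram matrix of the training inputs and T the one-hot class target
# matrix; prediction multiplies cross-kernels with the solved coefficients.

#' Gaussian (RBF) kernel value of two vectors
#'
#' `exp(-||x - y||^2 / (2 gamma^2))`. Values lie in (0, 1], equal to 1 iff
#' `x == y`.
#'
#' @param x,y numeric vectors of equal length.
#' @param gamma positive kernel width.
#' @return a scalar in (0, 1].
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("dimension mismatch")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  exp(-sum((x - y)^2) / (2 * gamma^2))
}

#' Kernel Gram / cross-kernel matrix
#'
#' Entry (i, j) is the kernel value of row i of `xa` with row j of `xb`.
#'
#' @param xa,xb numeric matrices with the same number of columns.
#' @param gamma positive RBF width (ignored for the linear kernel).
#' @param kernel `"rbf"` (default) or `"linear"` (inner product; the linear
#'   kernel exists mainly so KELM can be cross-checked against an explicit
#'   ridge solution).
#' @return an `nrow(xa) x nrow(xb)` matrix.
#' @export
kernel_matrix <- function(xa, xb, gamma, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (nrow(xa) == 0 || nrow(xb) == 0) stop("empty input")
  if (ncol(xa) != ncol(xb)) stop("feature dimension mismatch")
  if (kernel == "linear") return(tcrossprod(xa, xb))
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  exp(-d2 / (2 * gamma^2))
}

#' Fit a kernel extreme learning machine classifier
#'
#' Builds the one-hot target matrix T (1 for the true class, 0 elsewhere),
#' forms the kernel Gram matrix Omega of the training inputs, and solves the
#' symmetric positive-definite system `(Omega + I/C) coef = T` by Cholesky
#' factorization (with a least-squares fallback if the factorization fails at
#' extreme kernel widths). No iterative training is involved.
#'
#' @param x numeric matrix of training inputs (rows = samples).
#' @param y class labels, length `nrow(x)`, at least two distinct classes.
#' @param c_reg positive regularization parameter C; larger C means a weaker
#'   ridge penalty (closer interpolation of the targets).
#' @param gamma positive RBF kernel width.
#' @param kernel `"rbf"` or `"linear"`.
#' @return an object of class `kelm` with fields `x_train`, `t_matrix`,
#'   `c_reg`, `gamma`, `kernel`, `coef` and `classes`.
#' @seealso [predict.kelm()], [kelm_decision()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c("a", "b"), each = 20)
#' m <- kelm(x, y, c_reg = 32, gamma = 0.5)
#' mean(predict(m, x) == y)
#' @export
kelm <- function(x, y, c_reg = 32, gamma = 0.5, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite values in x")
  if (length(y) != nrow(x)) stop("x and y size mismatch")
  if (!is.numeric(c_reg) || c_reg <= 0) stop("c_reg must be > 0")
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (nrow(x) < 2) stop("need at least 2 samples")
  t_matrix <- outer(as.character(y), classes, "==") * 1
  colnames(t_matrix) <- classes
  omega <- kernel_matrix(x, x, gamma, kernel)
  a <- omega + diag(1 / c_reg, nrow(x))
  coef <- tryCatch({
    ch <- chol(a)
    backsolve(ch, forwardsolve(t(ch), t_matrix))
  }, error = function(e) qr.solve(a, t_matrix))
  colnames(coef) <- classes
  structure(list(x_train = x, t_matrix = t_matrix, c_reg = c_reg,
                 gamma = gamma, kernel = kernel, coef = coef,
                 classes = classes),
            class = "kelm")
}

#' Decision scores of a fitted KELM
#'
#' Score matrix `K(x_new, x_train) %*% coef`; one column per class.
#'
#' @param model a fitted [kelm()] object.
#' @param x_new numeric matrix of query points.
#' @return a `nrow(x_new) x length(classes)` score matrix.
#' @export
kelm_decision <- function(model, x_new) {
  stopifnot(inherits(model, "kelm"))
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != ncol(model$x_train)) stop("feature dimension mismatch")
  kernel_matrix(x_new, model$x_train, model$gamma, model$kernel) %*% model$coef
}

#' Predict class labels from a fitted KELM
#'
#' Argmax decoding of the decision scores; exact ties resolve to the first
#' class in the model's ordered `classes`.
#'
#' @param object a fitted [kelm()] object.
#' @param newdata numeric matrix of query points.
#' @param type `"class"` (labels) or `"score"` (the raw score matrix).
#' @param ... unused.
#' @export
predict.kelm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- kelm_decision(object, newdata)
  if (type == "score") return(s)
  object$classes[apply(s, 1, which.max)]
}

#' @export
print.kelm <- function(x, ...) {
  cat(sprintf("kernel ELM (%s kernel): %d training samples, %d features, %d classes\n",
              x$kernel, nrow(x$x_train), ncol(x$x_train), length(x$classes)))
  cat(sprintf("  C = %g, gamma = %g; classes: %s\n",
              x$c_reg, x$gamma, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
coef.kelm <- function(object, ...) object$coef

#' Serialize / restore a fitted KELM model
#'
#' Writes a JSON header (`C`, `gamma`, kernel, classes) beside two CSV blocks
#' holding the training inputs and the solved coefficient matrix; `read_kelm`
#' reverses the operation.
#'
#' @param model a fitted [kelm()] object.
#' @param path file prefix; `<path>.json`, `<path>_xtrain.csv` and
#'   `<path>_coef.csv` are written.
#' @return `path` invisibly (`write_kelm`); a `kelm` object (`read_kelm`).
#' @export
write_kelm <- function(model, path) {
  stopifnot(inherits(model, "kelm"))
  jsonlite::write_json(
    list(c_reg = model$c_reg, gamma = model$gamma, kernel = model$kernel,
         classes = model$classes),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$x_train, paste0(path, "_xtrain.csv"), row.names = FALSE)
  utils::write.csv(model$coef, paste0(path, "_coef.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_kelm
#' @export
read_kelm <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.csv(paste0(path, "_xtrain.csv")))
  coef <- as.matrix(utils::read.csv(paste0(path, "_coef.csv")))
  classes <- as.character(hdr$classes)
  colnames(coef) <- classes
  t_matrix <- NULL
  structure(list(x_train = unname(x) , t_matrix = t_matrix, c_reg = hdr$c_reg,
                 gamma = hdr$gamma, kernel = hdr$kernel, coef = coef,
                 classes = classes),
            class = "kelm")
}
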