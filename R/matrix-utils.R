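# Spectral matrix functions and covariance conditioning shared by the
# discriminant criteria and the Bayes classifier.

#' Apply a scalar function to the spectrum of a symmetric matrix
#'
#' Computes `f(M)` for a symmetric matrix `M` by symmetric eigendecomposition
#' `M = V diag(l) V'`, applying `f` to the eigenvalues and reassembling.
#' Eigenvalues are clipped from below at `floor` before `f` is applied, so
#' that square roots and logarithms of nearly singular covariance matrices
#' stay finite.
#'
#' @param M symmetric numeric matrix (asymmetry beyond `1e-8` in max norm is
#'   an error).
#' @param kind one of `"sqrt"`, `"inv_sqrt"`, `"log"`.
#' @param floor lower clip for the eigenvalues; must be positive for
#'   `"inv_sqrt"` and `"log"`.
#' @return a symmetric matrix of the same dimension.
#' @examples
#' matrix_function(diag(c(4, 9)), "sqrt")       # diag(2, 3)
#' matrix_function(diag(2), "log")              # zero matrix
#' @export
matrix_function <- function(M, kind = c("sqrt", "inv_sqrt", "log"),
                            floor = 1e-12) {
  kind <- match.arg(kind)
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) {
    stop("matrix_function() requires a square matrix")
  }
  if (max(abs(M - t(M))) > 1e-8) {
    stop("matrix_function() requires a symmetric matrix (max asymmetry ",
         format(max(abs(M - t(M)))), ")")
  }
  stopifnot(is.numeric(floor), floor >= 0)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-10 * max(1, abs(max(eig$values)))) {
    stop("matrix_function() requires a positive semi-definite matrix ",
         "(smallest eigenvalue ", format(min(eig$values)), ")")
  }
  l <- pmax(eig$values, floor)
  fl <- switch(kind,
    sqrt     = sqrt(l),
    inv_sqrt = 1 / sqrt(l),
    log      = log(l)
  )
  out <- eig$vectors %*% (fl * t(eig$vectors))
  (out + t(out)) / 2
}

#' Regularize a covariance matrix
#'
#' Adds a scaled ridge `lambda * tr(S)/n * I` so that inversion, square
#' roots and logarithms are well conditioned even when features are nearly
#' collinear (as cosine features routinely are).
#'
#' @param S symmetric covariance matrix.
#' @param lambda ridge multiplier (default `1e-6`).
#' @return the regularized matrix.
#' @export
regularize_cov <- function(S, lambda = 1e-6) {
  S <- as.matrix(S)
  n <- nrow(S)
  ridge <- lambda * sum(diag(S)) / n
  if (!is.finite(ridge) || ridge <= 0) {
    ridge <- lambda
  }
  S + diag(ridge, n)
}

# trace helper
tr <- function(M) sum(diag(as.matrix(M)))

# log-determinant of an SPD matrix via the clipped matrix logarithm; used by
# the Chernoff criterion where log terms of projected covariances appear.
logdet_spd <- function(M, floor = 1e-12, what = "matrix") {
  M <- as.matrix(M)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, abs(max(ev)))) {
    stop("projected ", what, " is not positive semi-definite; ",
         "increase the regularization lambda")
  }
  sum(log(pmax(ev, floor)))
}

# validate a numeric matrix of finite values
check_finite_matrix <- function(X, what = "input") {
  if (!all(is.finite(X))) {
    stop(what, " contains non-finite values")
  }
  invisible(X)
}
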