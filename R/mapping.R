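# Explicit feature maps: the exact degree-2 polynomial expansion and a
# randomized cosine (random Fourier feature) map approximating a Gaussian
# RBF kernel.  Both let linear discriminant criteria act on non-linearly
# separable data without the kernel trick.

#' Dimension of the degree-d polynomial feature map
#'
#' `C(n + degree, degree)`: the number of monomials of total degree at most
#' `degree` in `n` variables.
#'
#' @param n input dimension (>= 1).
#' @param degree polynomial degree (>= 1).
#' @return an integer.
#' @examples
#' poly_dim(3, 2)  # 10
#' @export
poly_dim <- function(n, degree = 2L) {
  stopifnot(n >= 1L, degree >= 1L)
  as.integer(round(choose(n + degree, degree)))
}

#' Degree-2 polynomial feature map specification
#'
#' Mirrors the polynomial kernel `K(x, y) = (gamma * x'y + r)^degree`.  Only
#' the canonical `degree = 2` expansion is implemented; `r` and `gamma` are
#' carried for provenance.  The expansion is used verbatim, i.e. without the
#' `sqrt(2)` weights of the exact kernel factorization: discriminant
#' criteria are invariant to that fixed diagonal rescaling, so classification
#' is unaffected (see the package vignette).
#'
#' @param degree polynomial degree; only 2 is supported.
#' @param r kernel offset (canonical value 1).
#' @param gamma kernel scale (canonical value 1).
#' @export
poly_map_spec <- function(degree = 2L, r = 1, gamma = 1) {
  if (degree != 2L) {
    stop("only the degree-2 polynomial map is implemented")
  }
  structure(list(degree = 2L, r = r, gamma = gamma), class = "poly_map_spec")
}

#' Apply the degree-2 polynomial map
#'
#' Maps `x = (x1, ..., xn)` to
#' `(1, x1, ..., xn, x1^2, ..., xn^2, x1 x2, x1 x3, ..., x(n-1) xn)`,
#' of length `C(n + 2, 2)`.
#'
#' @param x numeric vector (length >= 1).
#' @param spec a [poly_map_spec()].
#' @return numeric vector of length `poly_dim(length(x), 2)`.
#' @examples
#' poly_map(c(2, 3))  # 1 2 3 4 9 6
#' @export
poly_map <- function(x, spec = poly_map_spec()) {
  stopifnot(inherits(spec, "poly_map_spec"))
  x <- as.numeric(x)
  if (length(x) < 1L) stop("poly_map() requires a non-empty input vector")
  if (!all(is.finite(x))) stop("poly_map() input contains non-finite values")
  n <- length(x)
  cross <- if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    x[idx[1L, ]] * x[idx[2L, ]]
  } else {
    numeric(0)
  }
  c(1, x, x^2, cross)
}

#' @rdname poly_map
#' @param X numeric matrix, rows = samples.
#' @export
poly_transform <- function(X, spec = poly_map_spec()) {
  X <- as.matrix(X)
  out <- t(apply(X, 1L, poly_map, spec = spec))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- poly_feature_names(ncol(X))
  out
}

poly_feature_names <- function(n) {
  base <- paste0("x", seq_len(n))
  cross <- if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    paste0("x", idx[1L, ], "x", idx[2L, ])
  } else {
    character(0)
  }
  c("one", base, paste0(base, "sq"), cross)
}

#' Default output dimension of the RBF map
#'
#' The package default ties the number of random cosine features to the
#' input dimension as `m = n + 15`.
#'
#' @param n number of input features.
#' @return `n + 15L`.
#' @export
default_m <- function(n) {
  stopifnot(n >= 1L)
  as.integer(n) + 15L
}

#' Fit a randomized Fourier (RBF) feature map
#'
#' Draws frequencies `W[i, j] ~ N(0, 2 * gamma)` and phases
#' `b[i] ~ U[0, 2*pi)`; the induced transform
#' `z(x) = sqrt(2/m) * cos(W x + b)` satisfies
#' `E[z(x) . z(y)] = exp(-gamma * ||x - y||^2)`, the Gaussian RBF kernel.
#' The map is frozen: the same seed yields identical frequencies and phases.
#'
#' @param n input dimension.
#' @param gamma RBF width parameter (> 0; default 1.5).
#' @param m number of random features (default `default_m(n)`), the
#'   `nComponents` grid-search axis.
#' @param seed RNG seed for the draw.
#' @return an `rbf_feature_map` with fields `gamma`, `m`, `n`,
#'   `frequencies` (`m x n`), `phases` (length `m`), `seed`.
#' @export
rbf_fit <- function(n, gamma = 1.5, m = default_m(n), seed = 1L) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  if (m < 1L) stop("m must be at least 1")
  stopifnot(n >= 1L)
  n <- as.integer(n); m <- as.integer(m)
  draw <- withr::with_seed(as.integer(seed), list(
    frequencies = matrix(stats::rnorm(m * n, sd = sqrt(2 * gamma)), m, n),
    phases = stats::runif(m, 0, 2 * pi)
  ))
  structure(list(gamma = gamma, m = m, n = n,
                 frequencies = draw$frequencies, phases = draw$phases,
                 seed = as.integer(seed)),
            class = "rbf_feature_map")
}

#' @export
print.rbf_feature_map <- function(x, ...) {
  cat("RBF random-feature map: ", x$n, " -> ", x$m, " (gamma = ", x$gamma,
      ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Apply a randomized RBF feature map
#'
#' @param map an `rbf_feature_map` from [rbf_fit()].
#' @param X numeric matrix (rows = samples) or a single vector, with
#'   `map$n` columns.
#' @return matrix with `map$m` columns.
#' @export
rbf_transform <- function(map, X) {
  stopifnot(inherits(map, "rbf_feature_map"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != map$n) {
    stop("input has ", ncol(X), " columns but the map expects ", map$n)
  }
  check_finite_matrix(X, "mapping input")
  Z <- sqrt(2 / map$m) *
    cos(sweep(X %*% t(map$frequencies), 2L, map$phases, `+`))
  colnames(Z) <- paste0("rff", seq_len(map$m))
  Z
}
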