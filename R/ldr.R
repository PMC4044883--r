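# Two-class Gaussian modelling and linear dimensionality reduction.
#
# The positive class (pre-miRNA, label 1) is class 1 and the negative class
# (pseudo hairpins / other ncRNAs, label 0) is class 2 throughout.  Each
# class is modelled as x_i ~ N(m_i, S_i) with prior p_i; a d x n matrix A
# is sought that maximizes one of three separability criteria between the
# projected classes:
#
#   FDA:  J(A) = tr{ (A S_W A')^{-1} A S_E A' }
#   HDA:  J(A) = tr{ (A S_W A')^{-1} [ A S_E A'
#                 - A S_W^{1/2} (p1 log Sh1 + p2 log Sh2)/(p1 p2) S_W^{1/2} A' ] }
#   CDA:  J(A) = tr{ p1 p2 A S_E A' (A S_W A')^{-1} }
#                 + log|A S_W A'| - p1 log|A S1 A'| - p2 log|A S2 A'|
#
# with S_W = p1 S1 + p2 S2, S_E = (m1 - m2)(m1 - m2)' and
# Sh_i = S_W^{-1/2} S_i S_W^{-1/2}.  FDA and HDA are solved by
# eigendecomposition; CDA by gradient ascent on the Chernoff separability.

#' Two-class Gaussian statistics
#'
#' Estimates per-class mean vectors, covariance matrices and priors from a
#' feature matrix and a binary label vector.  Covariances use the biased
#' (1/N) estimator by default, matching the distributional class model; the
#' unbiased estimator is available via `cov_method`.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @param labels binary vector (1 = positive / pre-miRNA, 0 = negative);
#'   logicals and two-level factors are accepted.
#' @param prior_mode `"empirical"` (class fractions) or `"equal"` (0.5/0.5).
#' @param cov_method `"ml"` (divide by N) or `"unbiased"` (divide by N - 1).
#' @return a list of two `class_gaussian` objects, `pos` (class 1) and
#'   `neg` (class 2), each with fields `mean`, `cov`, `prior`, `n`.
#' @export
estimate_class_gaussians <- function(x, labels,
                                     prior_mode = c("empirical", "equal"),
                                     cov_method = c("ml", "unbiased")) {
  prior_mode <- match.arg(prior_mode)
  cov_method <- match.arg(cov_method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  check_finite_matrix(x, "feature matrix")
  labels <- as_binary_labels(labels)
  if (length(labels) != nrow(x)) {
    stop("labels length (", length(labels), ") does not match rows (",
         nrow(x), ")")
  }
  if (!all(c(0L, 1L) %in% labels)) {
    stop("labels must contain both classes")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 2L || n_neg < 2L) {
    stop("degenerate class: each class needs at least 2 samples (got ",
         n_pos, " positive, ", n_neg, " negative)")
  }
  priors <- switch(prior_mode,
    empirical = c(n_pos, n_neg) / (n_pos + n_neg),
    equal     = c(0.5, 0.5)
  )
  mk <- function(rows, prior) {
    xi <- x[rows, , drop = FALSE]
    m <- colMeans(xi)
    xc <- sweep(xi, 2L, m)
    denom <- if (cov_method == "ml") nrow(xi) else nrow(xi) - 1L
    S <- crossprod(xc) / denom
    class_gaussian(m, (S + t(S)) / 2, prior, n = nrow(xi))
  }
  list(pos = mk(labels == 1L, priors[1]),
       neg = mk(labels == 0L, priors[2]))
}

#' @rdname estimate_class_gaussians
#' @param mean numeric mean vector.
#' @param cov symmetric covariance matrix (eigenvalues >= -1e-10).
#' @param prior prior probability in (0, 1).
#' @param n optional sample count backing the estimate.
#' @export
class_gaussian <- function(mean, cov, prior, n = NA_integer_) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean)) {
    stop("covariance dimensions do not match the mean vector")
  }
  if (max(abs(cov - t(cov))) > 1e-8) {
    stop("covariance must be symmetric")
  }
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev)))) {
    stop("covariance must be positive semi-definite")
  }
  if (!is.numeric(prior) || prior <= 0 || prior >= 1) {
    stop("prior must lie strictly in (0, 1)")
  }
  structure(list(mean = mean, cov = cov, prior = prior, n = n),
            class = "class_gaussian")
}

#' @export
print.class_gaussian <- function(x, ...) {
  cat("Gaussian class model: ", length(x$mean), " features, prior ",
      format(x$prior, digits = 4), "\n", sep = "")
  invisible(x)
}

# normalize labels to integer 0/1
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- as.numeric(labels)
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0 = negative, 1 = positive)")
  }
  labels
}

#' Within- and between-class scatter matrices
#'
#' `S_W = p1 S1 + p2 S2` and `S_E = (m1 - m2)(m1 - m2)'`; `S_E` has rank at
#' most one for two classes.
#'
#' @param c1,c2 `class_gaussian` objects (positive and negative class).
#' @return a `scatter_pair` list with elements `within` and `between`.
#' @export
scatter_matrices <- function(c1, c2) {
  stopifnot(inherits(c1, "class_gaussian"), inherits(c2, "class_gaussian"))
  if (length(c1$mean) != length(c2$mean)) {
    stop("class dimensions do not match (", length(c1$mean), " vs ",
         length(c2$mean), ")")
  }
  dm <- c1$mean - c2$mean
  structure(list(
    within  = c1$prior * c1$cov + c2$prior * c2$cov,
    between = tcrossprod(dm)
  ), class = "scatter_pair")
}

# heteroscedastic correction term of the HDA criterion:
#   S_W^{1/2} (p1 log Sh1 + p2 log Sh2) / (p1 p2) S_W^{1/2}
# which vanishes when S1 = S2 (both normalized covariances become I).
hda_log_term <- function(c1, c2, lambda = 1e-6, floor = 1e-12) {
  sw <- regularize_cov(c1$prior * c1$cov + c2$prior * c2$cov, lambda)
  swi2 <- matrix_function(sw, "inv_sqrt", floor)
  sw2 <- matrix_function(sw, "sqrt", floor)
  lg <- function(S) {
    matrix_function(swi2 %*% regularize_cov(S, lambda) %*% swi2, "log", floor)
  }
  inner <- (c1$prior * lg(c1$cov) + c2$prior * lg(c2$cov)) /
    (c1$prior * c2$prior)
  out <- sw2 %*% inner %*% sw2
  (out + t(out)) / 2
}

#' Separability criterion value of a projection
#'
#' Evaluates the Fisher, heteroscedastic or Chernoff separability of the
#' class pair under a candidate `d x n` projection matrix.
#'
#' @param A numeric `d x n` projection matrix (or an `ldr_projection`).
#' @param c1,c2 `class_gaussian` objects.
#' @param criterion `"fda"`, `"hda"` or `"cda"`.
#' @param lambda covariance ridge used before inversions and logarithms.
#' @return the scalar criterion value.
#' @export
criterion_value <- function(A, c1, c2, criterion = c("fda", "hda", "cda"),
                            lambda = 1e-6) {
  criterion <- match.arg(criterion)
  if (inherits(A, "ldr_projection")) A <- A$matrix
  A <- rbind(A)  # keep 1 x n vectors as matrices
  storage.mode(A) <- "double"
  check_finite_matrix(A, "projection matrix")
  sc <- scatter_matrices(c1, c2)
  ASWA <- regularize_cov(A %*% sc$within %*% t(A), lambda)
  ASWA_inv <- tryCatch(solve(ASWA), error = function(e) {
    stop("projected within-class scatter A S_W A' is singular; ",
         "increase lambda or reduce d")
  })
  ASEA <- A %*% sc$between %*% t(A)
  switch(criterion,
    fda = tr(ASWA_inv %*% ASEA),
    hda = {
      corr <- A %*% hda_log_term(c1, c2, lambda) %*% t(A)
      tr(ASWA_inv %*% (ASEA - corr))
    },
    cda = {
      p1 <- c1$prior; p2 <- c2$prior
      AS1A <- regularize_cov(A %*% c1$cov %*% t(A), lambda)
      AS2A <- regularize_cov(A %*% c2$cov %*% t(A), lambda)
      p1 * p2 * tr(ASEA %*% ASWA_inv) +
        logdet_spd(ASWA, what = "A S_W A'") -
        p1 * logdet_spd(AS1A, what = "A S1 A'") -
        p2 * logdet_spd(AS2A, what = "A S2 A'")
    }
  )
}

# deterministic eigenvector sign: largest-magnitude component positive,
# ties broken by the earliest index (which.max is stable).
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# leading d eigenvectors of S_W^{-1} M for symmetric M, computed through the
# symmetric problem S_W^{-1/2} M S_W^{-1/2}; returns rows of A plus
# eigenvalues.  Equal eigenvalues keep the order eigen() returns (stable).
generalized_directions <- function(SW, M, d, lambda = 1e-6, floor = 1e-12) {
  n <- nrow(SW)
  if (d < 1L || d > n) {
    stop("reduced dimension d must satisfy 1 <= d <= ", n)
  }
  swi2 <- matrix_function(regularize_cov(SW, lambda), "inv_sqrt", floor)
  B <- swi2 %*% M %*% swi2
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- swi2 %*% eig$vectors[, seq_len(d), drop = FALSE]
  A <- t(apply(V, 2L, fix_sign))
  if (d == 1L) A <- matrix(A, nrow = 1L)
  list(A = A, values = eig$values[seq_len(d)])
}

new_projection <- function(A, criterion, objective, eigenvalues = NULL,
                           converged = NA, trace = NULL) {
  structure(list(matrix = A, criterion = criterion,
                 objective_value = objective, eigenvalues = eigenvalues,
                 converged = converged, trace = trace),
            class = "ldr_projection")
}

#' @export
print.ldr_projection <- function(x, ...) {
  cat(toupper(x$criterion), " projection: ", nrow(x$matrix), " x ",
      ncol(x$matrix), ", objective ", format(x$objective_value, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Fisher discriminant projection
#'
#' Rows of the returned matrix are the `d` leading eigenvectors of
#' `S_W^{-1} S_E` (descending eigenvalues; the largest-magnitude component
#' of each row is made positive for determinism).
#'
#' @param scatter a `scatter_pair` from [scatter_matrices()].
#' @param d reduced dimension, `1 <= d <= n`.
#' @param lambda covariance ridge.
#' @return an `ldr_projection` with fields `matrix`, `criterion`,
#'   `objective_value`, `eigenvalues`.
#' @export
fit_fda <- function(scatter, d = 1L, lambda = 1e-6) {
  stopifnot(inherits(scatter, "scatter_pair"))
  gd <- generalized_directions(scatter$within, scatter$between, d, lambda)
  ASWA <- regularize_cov(gd$A %*% scatter$within %*% t(gd$A), lambda)
  J <- tr(solve(ASWA) %*% (gd$A %*% scatter$between %*% t(gd$A)))
  new_projection(gd$A, "fda", J, eigenvalues = gd$values)
}

#' Heteroscedastic discriminant projection
#'
#' Eigendecomposition solution of the heteroscedastic criterion: the
#' between-class scatter is augmented by a matrix-logarithm term that
#' captures covariance differences and vanishes when `S1 = S2` (in which
#' case the projection coincides with Fisher's).
#'
#' @param c1,c2 `class_gaussian` objects.
#' @inheritParams fit_fda
#' @return an `ldr_projection`.
#' @export
fit_hda <- function(c1, c2, d = 1L, lambda = 1e-6) {
  sc <- scatter_matrices(c1, c2)
  M <- sc$between - hda_log_term(c1, c2, lambda)
  gd <- generalized_directions(sc$within, M, d, lambda)
  J <- criterion_value(gd$A, c1, c2, "hda", lambda)
  new_projection(gd$A, "hda", J, eigenvalues = gd$values)
}

#' Options for the Chernoff discriminant optimizer
#'
#' @param max_iterations iteration cap of the gradient ascent.
#' @param tolerance stop when the objective improves by less than this.
#' @param step_init initial step length of the backtracking line search.
#' @param seed seed for the random restarts.
#' @param restarts number of random initializations tried in addition to
#'   the Fisher and heteroscedastic starts.
#' @export
cda_options <- function(max_iterations = 500L, tolerance = 1e-8,
                        step_init = 1, seed = 1L, restarts = 3L) {
  stopifnot(max_iterations >= 1L, tolerance > 0, step_init > 0,
            restarts >= 0L)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, step_init = step_init,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "cda_options")
}

#' Chernoff discriminant projection
#'
#' Maximizes the Chernoff separability of the projected class pair by
#' gradient ascent (central-difference gradient, backtracking line search
#' that halves the step until the objective increases).  The ascent starts
#' from the Fisher solution and, additionally, from the heteroscedastic
#' solution and a few random matrices; the best final iterate is returned.
#' The per-iteration objective sequence of the winning run is available in
#' `$trace` and is non-decreasing by construction.
#'
#' @inheritParams fit_hda
#' @param opts a [cda_options()] object.
#' @return an `ldr_projection`; `$converged` is `FALSE` when the iteration
#'   cap was hit before the tolerance was met (the best iterate is still
#'   returned, never an error).
#' @export
fit_cda <- function(c1, c2, d = 1L, opts = cda_options(), lambda = 1e-6) {
  stopifnot(inherits(opts, "cda_options"))
  n <- length(c1$mean)
  if (d < 1L || d > n) stop("reduced dimension d must satisfy 1 <= d <= ", n)
  obj <- function(A) criterion_value(A, c1, c2, "cda", lambda)

  starts <- list(fit_fda(scatter_matrices(c1, c2), d, lambda)$matrix,
                 fit_hda(c1, c2, d, lambda)$matrix)
  if (opts$restarts > 0L) {
    rand <- withr::with_seed(opts$seed, lapply(seq_len(opts$restarts),
      function(i) matrix(stats::rnorm(d * n), d, n)))
    starts <- c(starts, rand)
  }

  ascend <- function(A) {
    J <- obj(A)
    trace <- J
    converged <- FALSE
    h <- 1e-6
    for (it in seq_len(opts$max_iterations)) {
      G <- matrix(0, d, n)
      for (i in seq_len(d)) for (j in seq_len(n)) {
        Ap <- A; Ap[i, j] <- Ap[i, j] + h
        Am <- A; Am[i, j] <- Am[i, j] - h
        G[i, j] <- (obj(Ap) - obj(Am)) / (2 * h)
      }
      gn <- sqrt(sum(G^2))
      if (gn < 1e-12) { converged <- TRUE; break }
      step <- opts$step_init / max(1, gn)
      improved <- FALSE
      for (bt in 1:40) {
        Anew <- A + step * G
        Jnew <- tryCatch(obj(Anew), error = function(e) -Inf)
        if (is.finite(Jnew) && Jnew > J) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      dJ <- Jnew - J
      A <- Anew; J <- Jnew
      trace <- c(trace, J)
      if (dJ < opts$tolerance) { converged <- TRUE; break }
    }
    list(A = A, J = J, trace = trace, converged = converged)
  }

  runs <- lapply(starts, ascend)
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "J"))]]
  A <- t(apply(best$A, 1L, fix_sign))
  if (d == 1L) A <- matrix(A, nrow = 1L)
  new_projection(A, "cda", best$J, converged = best$converged,
                 trace = best$trace)
}
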