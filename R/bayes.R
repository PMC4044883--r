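# Bayesian Gaussian classification in the LDR-reduced space: linear
# (pooled covariance) or quadratic (per-class covariance) discriminant.

#' Fit a Gaussian-Bayes classifier in the reduced space
#'
#' @param Y numeric matrix of reduced features (rows = samples, `d` columns).
#' @param labels binary labels (1 = positive, 0 = negative).
#' @param mode `"quadratic"` keeps per-class covariances; `"linear"` pools
#'   them as `p1 S1 + p2 S2`.
#' @param prior_mode `"empirical"` or `"equal"`.
#' @param lambda covariance ridge (same policy as the LDR criteria).
#' @return a `gaussian_bayes` model.
#' @export
fit_bayes <- function(Y, labels, mode = c("quadratic", "linear"),
                      prior_mode = c("empirical", "equal"), lambda = 1e-6) {
  mode <- match.arg(mode)
  prior_mode <- match.arg(prior_mode)
  cg <- estimate_class_gaussians(Y, labels, prior_mode)
  covs <- if (mode == "linear") {
    pooled <- regularize_cov(
      cg$pos$prior * cg$pos$cov + cg$neg$prior * cg$neg$cov, lambda)
    list(pos = pooled, neg = pooled)
  } else {
    list(pos = regularize_cov(cg$pos$cov, lambda),
         neg = regularize_cov(cg$neg$cov, lambda))
  }
  pre <- lapply(covs, function(S) {
    R <- tryCatch(chol(S), error = function(e) {
      stop("class covariance is singular after regularization; ",
           "increase lambda")
    })
    list(chol = R, logdet = 2 * sum(log(diag(R))))
  })
  structure(list(
    d = length(cg$pos$mean),
    mode = mode,
    means = list(pos = cg$pos$mean, neg = cg$neg$mean),
    covs = covs,
    priors = c(pos = cg$pos$prior, neg = cg$neg$prior),
    pre = pre,
    lambda = lambda
  ), class = "gaussian_bayes")
}

# log N(y; m, S) for rows of Y, using a precomputed Cholesky factor
mvn_logdens <- function(Y, mean, pre) {
  d <- length(mean)
  Yc <- sweep(Y, 2L, mean)
  # solve R' z = y_c  =>  quadratic form = ||z||^2
  z <- backsolve(pre$chol, t(Yc), transpose = TRUE)
  q <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + pre$logdet + q)
}

#' Predict with a Gaussian-Bayes model
#'
#' Assigns the class with the larger `log prior + log density`; exact ties
#' go to the negative (majority) class, which is conservative for
#' false-positive control.
#'
#' @param object a `gaussian_bayes` model.
#' @param Y reduced feature matrix (or a single `d`-vector).
#' @param ... unused.
#' @return a data.frame with columns `label` (0/1), `lp_pos`, `lp_neg`
#'   (unnormalized log-posteriors).
#' @export
predict.gaussian_bayes <- function(object, Y, ...) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  Y <- as.matrix(Y)
  if (ncol(Y) != object$d) {
    stop("input has ", ncol(Y), " columns but the model expects ", object$d)
  }
  check_finite_matrix(Y, "prediction input")
  lp_pos <- log(object$priors["pos"]) +
    mvn_logdens(Y, object$means$pos, object$pre$pos)
  lp_neg <- log(object$priors["neg"]) +
    mvn_logdens(Y, object$means$neg, object$pre$neg)
  data.frame(label = as.integer(lp_pos > lp_neg),
             lp_pos = unname(lp_pos), lp_neg = unname(lp_neg))
}

#' @export
print.gaussian_bayes <- function(x, ...) {
  cat("Gaussian-Bayes classifier (", x$mode, "), d = ", x$d,
      ", priors = (", format(x$priors["pos"], digits = 4), ", ",
      format(x$priors["neg"], digits = 4), ")\n", sep = "")
  invisible(x)
}
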