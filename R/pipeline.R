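# Pipeline assembly: feature subset -> (optional z-scoring) -> explicit
# map -> LDR projection -> Gaussian-Bayes.  `ldr_pipeline()` holds the
# settings; `pipeline_fit()`/`pipeline_predict()` are the single train and
# apply paths used by cross-validation, feature selection, grid search and
# the serialized model, so no stage can diverge between them.

#' Pipeline configuration
#'
#' The default configuration is the package's reference classifier: RBF
#' random-feature mapping (`gamma = 1.5`, `m = n + 15`) followed by the
#' heteroscedastic discriminant (`d = 1`) and a quadratic Gaussian-Bayes
#' rule with empirical priors.
#'
#' @param features character vector (or integer indices) of feature columns
#'   to use; `NULL` = all feature columns of the table.
#' @param mapping `"rbf"`, `"poly"` or `"none"`.
#' @param gamma RBF width (ignored unless `mapping = "rbf"`).
#' @param n_components RBF output dimension; `NULL` means `n + 15`,
#'   recomputed from the (sub)set size actually used.
#' @param map_seed seed of the frozen random map.
#' @param standardize z-score features using training-fold statistics
#'   before mapping; defaults to `TRUE` for the RBF map (where the scale of
#'   the inputs interacts with `gamma`) and `FALSE` otherwise.
#' @param criterion `"hda"`, `"fda"` or `"cda"`.
#' @param d reduced dimension (default 1; with two classes the Fisher
#'   between-class scatter has rank one, but the heteroscedastic and
#'   Chernoff target matrices may carry more directions).
#' @param classifier `"quadratic"` or `"linear"`.
#' @param prior_mode `"empirical"` or `"equal"`.
#' @param lambda covariance ridge shared by all stages.
#' @param folds number of cross-validation folds (default 10).
#' @param cda_opts a [cda_options()] object (used when `criterion = "cda"`).
#' @return an `ldr_pipeline` configuration object.
#' @export
ldr_pipeline <- function(features = NULL,
                         mapping = c("rbf", "poly", "none"),
                         gamma = 1.5, n_components = NULL, map_seed = 1L,
                         standardize = NULL,
                         criterion = c("hda", "fda", "cda"), d = 1L,
                         classifier = c("quadratic", "linear"),
                         prior_mode = c("empirical", "equal"),
                         lambda = 1e-6, folds = 10L,
                         cda_opts = cda_options()) {
  mapping <- match.arg(mapping)
  criterion <- match.arg(criterion)
  classifier <- match.arg(classifier)
  prior_mode <- match.arg(prior_mode)
  if (is.null(standardize)) standardize <- mapping == "rbf"
  stopifnot(is.logical(standardize), length(standardize) == 1L,
            d >= 1L, folds >= 1L, lambda > 0)
  structure(list(features = features, mapping = mapping, gamma = gamma,
                 n_components = n_components, map_seed = as.integer(map_seed),
                 standardize = standardize, criterion = criterion,
                 d = as.integer(d), classifier = classifier,
                 prior_mode = prior_mode, lambda = lambda,
                 folds = as.integer(folds), cda_opts = cda_opts),
            class = "ldr_pipeline")
}

#' @export
print.ldr_pipeline <- function(x, ...) {
  m <- if (x$mapping == "rbf") {
    paste0("rbf(gamma = ", x$gamma, ", m = ",
           if (is.null(x$n_components)) "n + 15" else x$n_components, ")")
  } else x$mapping
  cat("LDR pipeline: mapping ", m, " | ", toupper(x$criterion), " d = ",
      x$d, " | ", x$classifier, " Bayes (", x$prior_mode, " priors)\n",
      sep = "")
  invisible(x)
}

# resolve which feature columns of a table the pipeline uses
resolve_features <- function(table, pipeline) {
  feats <- feature_names(table)
  sel <- pipeline$features
  if (is.null(sel)) return(feats)
  if (is.numeric(sel)) {
    if (any(sel < 1L | sel > length(feats))) {
      stop("feature indices out of range 1..", length(feats))
    }
    return(feats[as.integer(sel)])
  }
  missing <- setdiff(sel, feats)
  if (length(missing)) {
    stop("features not present in the table: ",
         paste(missing, collapse = ", "))
  }
  as.character(sel)
}

# Fit every pipeline stage on training data only.  X is the raw feature
# matrix restricted to the selected columns.
pipeline_fit <- function(X, labels, pipeline) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n_raw <- ncol(X)

  center <- rep(0, n_raw); scale <- rep(1, n_raw)
  if (pipeline$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  } else {
    X <- X
  }

  map <- NULL
  Z <- switch(pipeline$mapping,
    none = X,
    poly = poly_transform(X),
    rbf = {
      m <- if (is.null(pipeline$n_components)) default_m(n_raw) else
        as.integer(pipeline$n_components)
      map <- rbf_fit(n_raw, pipeline$gamma, m, pipeline$map_seed)
      rbf_transform(map, X)
    }
  )

  cg <- estimate_class_gaussians(Z, labels, pipeline$prior_mode)
  proj <- switch(pipeline$criterion,
    fda = fit_fda(scatter_matrices(cg$pos, cg$neg), pipeline$d,
                  pipeline$lambda),
    hda = fit_hda(cg$pos, cg$neg, pipeline$d, pipeline$lambda),
    cda = fit_cda(cg$pos, cg$neg, pipeline$d, pipeline$cda_opts,
                  pipeline$lambda)
  )
  Y <- Z %*% t(proj$matrix)
  bayes <- fit_bayes(Y, labels, pipeline$classifier, pipeline$prior_mode,
                     pipeline$lambda)
  list(mapping = pipeline$mapping, center = center, scale = scale,
       map = map, projection = proj, bayes = bayes, n_raw = n_raw)
}

pipeline_apply <- function(fit, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != fit$n_raw) {
    stop("prediction input has ", ncol(X), " columns, expected ", fit$n_raw)
  }
  X <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, `/`)
  Z <- switch(fit$mapping,
    none = X,
    poly = poly_transform(X),
    rbf  = rbf_transform(fit$map, X)
  )
  Z %*% t(fit$projection$matrix)
}

pipeline_predict <- function(fit, X) {
  predict(fit$bayes, pipeline_apply(fit, X))
}
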