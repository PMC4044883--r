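# Trained pipeline models and their JSON serialization.  The serialized
# form carries the frozen random-map state, so a reloaded model reproduces
# training-time predictions.

MODEL_SCHEMA_VERSION <- "1"

#' Train a full pipeline model on a feature table
#'
#' @param table a feature table.
#' @param pipeline an [ldr_pipeline()] configuration.
#' @return a `pipeline_model` holding the feature subset, standardization
#'   parameters, frozen mapping, projection, Bayes model, seeds and schema
#'   version.
#' @export
train_pipeline <- function(table, pipeline = ldr_pipeline()) {
  stopifnot(inherits(pipeline, "ldr_pipeline"))
  table <- feature_table(table)
  feats <- resolve_features(table, pipeline)
  X <- as.matrix(table[, feats, drop = FALSE])
  y <- as_binary_labels(table$label)
  fit <- pipeline_fit(X, y, pipeline)
  structure(list(version = MODEL_SCHEMA_VERSION,
                 features = feats, pipeline = pipeline, fit = fit,
                 config_hash = rlang::hash(pipeline)),
            class = "pipeline_model")
}

#' Predict with a trained pipeline model
#'
#' @param object a `pipeline_model`.
#' @param table a feature table with (at least) the model's feature
#'   columns; a `label` column, if present, is ignored.
#' @param ... unused.
#' @return a data.frame with columns `id`, `label` (predicted), `lp_pos`,
#'   `lp_neg`.
#' @export
predict.pipeline_model <- function(object, table, ...) {
  table <- as.data.frame(table)
  missing <- setdiff(object$features, names(table))
  if (length(missing)) {
    stop("table lacks model feature column(s): ",
         paste(missing, collapse = ", "))
  }
  ids <- if ("id" %in% names(table)) as.character(table$id) else
    as.character(seq_len(nrow(table)))
  X <- as.matrix(table[, object$features, drop = FALSE])
  pred <- pipeline_predict(object$fit, X)
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), pred)
}

#' @export
print.pipeline_model <- function(x, ...) {
  cat("Trained pipeline model (schema ", x$version, "), ",
      length(x$features), " features: ",
      paste(utils::head(x$features, 8L), collapse = ", "),
      if (length(x$features) > 8L) ", ..." else "", "\n", sep = "")
  print(x$pipeline)
  invisible(x)
}

mat_to_json <- function(M) {
  list(dim = dim(M), data = as.numeric(M))
}

mat_from_json <- function(j) {
  matrix(as.numeric(j$data), j$dim[1], j$dim[2])
}

#' Save / load a trained pipeline model
#'
#' JSON with full floating-point precision; the random-map frequencies and
#' phases are stored verbatim, so `load_model()` followed by `predict()`
#' reproduces the in-memory predictions.  Loading checks the schema
#' version and fails on truncated or mismatched files without returning a
#' partial model.
#'
#' @param model a `pipeline_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pipeline_model"))
  fit <- model$fit
  pl <- unclass(model$pipeline)
  pl$cda_opts <- unclass(pl$cda_opts)
  payload <- list(
    schema_version = model$version,
    features = model$features,
    config_hash = model$config_hash,
    pipeline = pl,
    fit = list(
      mapping = fit$mapping,
      center = fit$center, scale = fit$scale, n_raw = fit$n_raw,
      map = if (is.null(fit$map)) NULL else list(
        gamma = fit$map$gamma, m = fit$map$m, n = fit$map$n,
        frequencies = mat_to_json(fit$map$frequencies),
        phases = fit$map$phases, seed = fit$map$seed),
      projection = list(
        matrix = mat_to_json(fit$projection$matrix),
        criterion = fit$projection$criterion,
        objective_value = fit$projection$objective_value),
      bayes = list(
        d = fit$bayes$d, mode = fit$bayes$mode,
        mean_pos = fit$bayes$means$pos, mean_neg = fit$bayes$means$neg,
        cov_pos = mat_to_json(fit$bayes$covs$pos),
        cov_neg = mat_to_json(fit$bayes$covs$neg),
        priors = as.numeric(fit$bayes$priors),
        lambda = fit$bayes$lambda)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the reconstructed `pipeline_model`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot read model file '", path, "': ",
                             conditionMessage(e))
                      })
  if (is.null(payload$schema_version) ||
      !identical(as.character(payload$schema_version),
                 MODEL_SCHEMA_VERSION)) {
    stop("model schema version mismatch: file has '",
         payload$schema_version %||% "<none>", "', package expects '",
         MODEL_SCHEMA_VERSION, "'")
  }
  pj <- payload$pipeline
  pipeline <- ldr_pipeline(
    features = payload$features, mapping = pj$mapping, gamma = pj$gamma,
    n_components = pj$n_components, map_seed = pj$map_seed,
    standardize = pj$standardize, criterion = pj$criterion, d = pj$d,
    classifier = pj$classifier, prior_mode = pj$prior_mode,
    lambda = pj$lambda, folds = pj$folds)
  fj <- payload$fit
  map <- NULL
  if (!is.null(fj$map) && length(fj$map)) {
    map <- structure(list(gamma = fj$map$gamma, m = as.integer(fj$map$m),
                          n = as.integer(fj$map$n),
                          frequencies = mat_from_json(fj$map$frequencies),
                          phases = as.numeric(fj$map$phases),
                          seed = as.integer(fj$map$seed)),
                     class = "rbf_feature_map")
  }
  proj <- new_projection(mat_from_json(fj$projection$matrix),
                         fj$projection$criterion,
                         fj$projection$objective_value)
  bayes <- rebuild_bayes(fj$bayes)
  fit <- list(mapping = fj$mapping, center = as.numeric(fj$center),
              scale = as.numeric(fj$scale), map = map, projection = proj,
              bayes = bayes, n_raw = as.integer(fj$n_raw))
  structure(list(version = MODEL_SCHEMA_VERSION,
                 features = payload$features, pipeline = pipeline,
                 fit = fit, config_hash = payload$config_hash),
            class = "pipeline_model")
}

rebuild_bayes <- function(bj) {
  covs <- list(pos = mat_from_json(bj$cov_pos),
               neg = mat_from_json(bj$cov_neg))
  pre <- lapply(covs, function(S) {
    R <- chol(S)
    list(chol = R, logdet = 2 * sum(log(diag(R))))
  })
  structure(list(d = as.integer(bj$d), mode = bj$mode,
                 means = list(pos = as.numeric(bj$mean_pos),
                              neg = as.numeric(bj$mean_neg)),
                 covs = covs,
                 priors = c(pos = bj$priors[1], neg = bj$priors[2]),
                 pre = pre, lambda = bj$lambda),
            class = "gaussian_bayes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
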