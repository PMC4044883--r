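# Wrapper feature selection: beam search of width B over growing feature
# subsets scored by cross-validated Gm, and (gamma, nComponents) grid
# search for the RBF map.  All subset evaluations go through a cache keyed
# by a fingerprint of (subset, mapping parameters, seeds, CV config, data
# hash), so repeated selection rounds never recompute a score.

#' Beam-search configuration
#'
#' @param beam_width number of best subsets retained per size (default 10).
#' @param max_size largest subset size evaluated (default 12).
#' @param pipeline the [ldr_pipeline()] used to score subsets; its
#'   `n_components` is left `NULL` so the RBF dimension is recomputed as
#'   `n + 15` from each subset's size.
#' @param fold_seed fold-shuffle seed, frozen across all evaluations so
#'   scores are comparable.
#' @param min_improvement optional early stop: halt when the best mean Gm
#'   of a size improves on the previous size by less than this (default
#'   `NULL` = off, i.e. run to `max_size`).
#' @param cache a [score_cache()] (default: fresh in-memory cache).
#' @export
beam_config <- function(beam_width = 10L, max_size = 12L,
                        pipeline = ldr_pipeline(), fold_seed = 1L,
                        min_improvement = NULL, cache = score_cache()) {
  stopifnot(beam_width >= 1L, max_size >= 2L,
            inherits(pipeline, "ldr_pipeline"),
            inherits(cache, "score_cache"))
  structure(list(beam_width = as.integer(beam_width),
                 max_size = as.integer(max_size), pipeline = pipeline,
                 fold_seed = as.integer(fold_seed),
                 min_improvement = min_improvement, cache = cache),
            class = "beam_config")
}

#' In-memory / single-file score cache
#'
#' A key-value store of subset evaluations keyed by fingerprint hash.  When
#' `path` is given, the cache is loaded from that JSON file if present (a
#' corrupted file is discarded with a warning and rebuilt) and
#' [cache_save()] writes it back.
#'
#' @param path optional JSON file backing the cache.
#' @return a `score_cache` environment with hit/miss counters.
#' @export
score_cache <- function(path = NULL) {
  cache <- new.env(parent = emptyenv())
  cache$store <- new.env(parent = emptyenv())
  cache$hits <- 0L
  cache$misses <- 0L
  cache$path <- path
  class(cache) <- "score_cache"
  if (!is.null(path) && file.exists(path)) {
    loaded <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                       error = function(e) NULL)
    if (is.null(loaded) || !is.list(loaded)) {
      warning("corrupted cache file '", path, "'; rebuilding")
    } else {
      for (k in names(loaded)) assign(k, loaded[[k]], envir = cache$store)
    }
  }
  cache
}

#' @rdname score_cache
#' @param cache a `score_cache`.
#' @param key fingerprint string.
#' @param value record to store.
#' @export
cache_store <- function(cache, key, value) {
  stopifnot(inherits(cache, "score_cache"))
  assign(key, value, envir = cache$store)
  invisible(cache)
}

#' @rdname score_cache
#' @return `cache_lookup()` returns the stored record or `NULL` on a miss.
#' @export
cache_lookup <- function(cache, key) {
  stopifnot(inherits(cache, "score_cache"))
  if (exists(key, envir = cache$store, inherits = FALSE)) {
    cache$hits <- cache$hits + 1L
    get(key, envir = cache$store, inherits = FALSE)
  } else {
    cache$misses <- cache$misses + 1L
    NULL
  }
}

#' @rdname score_cache
#' @export
cache_save <- function(cache) {
  stopifnot(inherits(cache, "score_cache"))
  if (is.null(cache$path)) stop("cache has no backing file")
  jsonlite::write_json(as.list(cache$store), cache$path, auto_unbox = TRUE,
                       digits = NA)
  invisible(cache$path)
}

# fingerprint of one subset evaluation; covers everything that can change
# the score
subset_fingerprint <- function(subset, pipeline, fold_seed, data_hash) {
  rlang::hash(list(
    # string key: immune to integer representation differences
    subset = paste(sort(as.integer(subset)), collapse = ","),
    mapping = pipeline$mapping, gamma = pipeline$gamma,
    n_components = pipeline$n_components, map_seed = pipeline$map_seed,
    standardize = pipeline$standardize, criterion = pipeline$criterion,
    d = pipeline$d, classifier = pipeline$classifier,
    prior_mode = pipeline$prior_mode, lambda = pipeline$lambda,
    folds = pipeline$folds, fold_seed = fold_seed, data = data_hash
  ))
}

# evaluate one subset through the cache; returns the scored record
evaluate_subset <- function(table, subset, config, data_hash) {
  key <- subset_fingerprint(subset, config$pipeline, config$fold_seed,
                            data_hash)
  hit <- cache_lookup(config$cache, key)
  if (!is.null(hit)) return(hit)
  pl <- config$pipeline
  pl$features <- feature_names(table)[subset]
  cv <- cross_validate(table, pl, config$fold_seed)
  rec <- list(subset = sort(as.integer(subset)),
              mean_gm = unname(cv$mean["Gm"]),
              mean_se = unname(cv$mean["SE"]),
              mean_sp = unname(cv$mean["SP"]),
              sd_gm = unname(cv$sd["Gm"]),
              fold_gm = cv$folds$Gm,
              fingerprint = key)
  cache_store(config$cache, key, rec)
  rec
}

# order records by descending Gm, ties by lexicographically smallest subset
order_records <- function(recs) {
  gm <- vapply(recs, `[[`, numeric(1), "mean_gm")
  keys <- vapply(recs, function(r) {
    paste(sprintf("%06d", r$subset), collapse = ",")
  }, character(1))
  order(-gm, keys)
}

#' Beam search over feature subsets
#'
#' Size-2 stage: every pair of features is cross-validated and the best
#' `beam_width` pairs are kept.  Each later stage extends every beam member
#' by every unused feature (deduplicating identical subsets), scores the
#' candidates, and again keeps the best `beam_width`, until `max_size`.
#' Ties break toward the lexicographically smallest subset.  With
#' `beam_width = 1` this reduces to plain greedy forward selection.
#'
#' @param table a feature table.
#' @param config a [beam_config()].
#' @return a `beam_result`: list with `stages` (per size, the ranked
#'   records), `best` (top record of the largest size reached),
#'   `evaluations` (number of cross-validations actually run).
#' @export
beam_search <- function(table, config = beam_config()) {
  stopifnot(inherits(config, "beam_config"))
  table <- feature_table(table)
  feats <- feature_names(table)
  n <- length(feats)
  if (n < 2L) stop("beam search needs at least 2 features")
  max_size <- config$max_size
  if (max_size > n) {
    warning("max_size ", max_size, " exceeds the ", n,
            " available features; truncating")
    max_size <- n
  }
  data_hash <- rlang::hash(table)
  miss0 <- config$cache$misses

  pairs <- utils::combn(n, 2L, simplify = FALSE)
  recs <- lapply(pairs, evaluate_subset, table = table, config = config,
                 data_hash = data_hash)
  beam <- recs[order_records(recs)][seq_len(min(config$beam_width,
                                                length(recs)))]
  stages <- list(`2` = beam)
  prev_best <- beam[[1L]]$mean_gm

  size <- 2L
  while (size < max_size) {
    size <- size + 1L
    cand_sets <- list()
    for (b in stages[[as.character(size - 1L)]]) {
      for (f in setdiff(seq_len(n), b$subset)) {
        s <- sort(c(b$subset, f))
        cand_sets[[paste(s, collapse = ",")]] <- s
      }
    }
    recs <- lapply(cand_sets, evaluate_subset, table = table,
                   config = config, data_hash = data_hash)
    beam <- recs[order_records(recs)][seq_len(min(config$beam_width,
                                                  length(recs)))]
    names(beam) <- NULL
    stages[[as.character(size)]] <- beam
    if (!is.null(config$min_improvement) &&
        beam[[1L]]$mean_gm - prev_best < config$min_improvement) {
      break
    }
    prev_best <- max(prev_best, beam[[1L]]$mean_gm)
  }
  structure(list(stages = stages,
                 best = stages[[length(stages)]][[1L]],
                 features = feats,
                 evaluations = config$cache$misses - miss0),
            class = "beam_result")
}

#' @export
print.beam_result <- function(x, ...) {
  cat("Beam search over", length(x$features), "features;",
      x$evaluations, "cross-validations run\n")
  for (sz in names(x$stages)) {
    top <- x$stages[[sz]][[1L]]
    cat(sprintf("  size %2s: best {%s}  Gm = %.4f\n", sz,
                paste(x$features[top$subset], collapse = ", "),
                top$mean_gm))
  }
  invisible(x)
}

#' Export a beam result as delimited text
#'
#' @param result a `beam_result`.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_beam_report <- function(result, path, sep = "\t") {
  stopifnot(inherits(result, "beam_result"))
  rows <- list()
  for (sz in names(result$stages)) {
    st <- result$stages[[sz]]
    for (r in seq_along(st)) {
      rec <- st[[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        size = as.integer(sz), rank = r,
        features = paste(result$features[rec$subset], collapse = ","),
        mean_Gm = rec$mean_gm, mean_SE = rec$mean_se,
        mean_SP = rec$mean_sp, sd_Gm = rec$sd_gm)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Grid search over RBF parameters
#'
#' Cross-validates one fixed feature subset for every `(gamma, m)` cell
#' with a frozen fold seed, returning the Gm matrix (rows = gammas,
#' columns = m values) and the best cell.  A failing cell is recorded as
#' `NA` with a warning rather than aborting the grid.
#'
#' @param table a feature table.
#' @param subset feature names or indices to use.
#' @param gammas,ms parameter grids (non-empty).
#' @param pipeline base [ldr_pipeline()]; its `gamma`/`n_components` are
#'   overridden cell by cell.
#' @param fold_seed frozen fold seed.
#' @return a `grid_result` with `gm` (matrix), `se`, `sp`, `best`
#'   (list with `gamma`, `m`, `gm`), `gammas`, `ms`.
#' @export
grid_search <- function(table, subset = NULL, gammas, ms,
                        pipeline = ldr_pipeline(), fold_seed = 1L) {
  stopifnot(length(gammas) >= 1L, length(ms) >= 1L)
  table <- feature_table(table)
  gm <- se <- sp <- matrix(NA_real_, length(gammas), length(ms),
                           dimnames = list(paste0("gamma=", gammas),
                                           paste0("m=", ms)))
  for (i in seq_along(gammas)) {
    for (j in seq_along(ms)) {
      pl <- pipeline
      pl$features <- subset
      pl$mapping <- "rbf"
      pl$gamma <- gammas[i]
      pl$n_components <- as.integer(ms[j])
      cv <- tryCatch(cross_validate(table, pl, fold_seed),
                     error = function(e) {
                       warning("grid cell gamma=", gammas[i], ", m=", ms[j],
                               " failed: ", conditionMessage(e))
                       NULL
                     })
      if (!is.null(cv)) {
        gm[i, j] <- cv$mean["Gm"]
        se[i, j] <- cv$mean["SE"]
        sp[i, j] <- cv$mean["SP"]
      }
    }
  }
  best_idx <- which(gm == max(gm, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  structure(list(gm = gm, se = se, sp = sp,
                 gammas = gammas, ms = as.integer(ms),
                 best = list(gamma = gammas[best_idx[1L]],
                             m = as.integer(ms[best_idx[2L]]),
                             gm = gm[best_idx[1L], best_idx[2L]]),
                 fold_seed = as.integer(fold_seed)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("Grid search (", length(x$gammas), " gammas x ", length(x$ms),
      " m values); best Gm = ", sprintf("%.4f", x$best$gm),
      " at gamma = ", x$best$gamma, ", m = ", x$best$m, "\n", sep = "")
  print(round(x$gm, 4))
  invisible(x)
}

#' Export a grid-search Gm matrix for heatmap plotting
#'
#' Writes the matrix as delimited text with gamma row names and m column
#' names.
#'
#' @param result a `grid_result`.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_grid_matrix <- function(result, path, sep = "\t") {
  stopifnot(inherits(result, "grid_result"))
  df <- data.frame(gamma = result$gammas, result$gm, check.names = FALSE)
  colnames(df) <- c("gamma", result$ms)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
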