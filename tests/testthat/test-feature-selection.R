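# Beam search, grid search and the evaluation cache.

# small, fast scoring pipeline used throughout this file
fast_pipeline <- function(...) {
  ldr_pipeline(mapping = "none", criterion = "fda", classifier = "linear",
               folds = 5L, ...)
}

test_that("the size-2 stage is exhaustive and the beam stays sorted", {
  tab <- planted_table(n_features = 6, informative = c(2, 5), seed = 1)
  cfg <- beam_config(beam_width = 3L, max_size = 3L,
                     pipeline = fast_pipeline(), fold_seed = 2)
  res <- beam_search(tab, cfg)
  # all C(6,2) = 15 pairs plus at most B * (n - 2) = 12 triples
  expect_gte(res$evaluations, 15L)
  expect_lte(res$evaluations, 15L + 12L)
  gm2 <- vapply(res$stages[["2"]], `[[`, numeric(1), "mean_gm")
  expect_true(all(diff(gm2) <= 0))
  expect_equal(res$stages[["2"]][[1L]]$subset, c(2L, 5L))
})

test_that("beam contents are exactly the best evaluated subsets", {
  tab <- planted_table(n_features = 6, informative = c(1, 4),
                       separation = 2, seed = 3)
  cfg <- beam_config(beam_width = 4L, max_size = 2L,
                     pipeline = fast_pipeline(), fold_seed = 2)
  res <- beam_search(tab, cfg)
  # exhaustive re-evaluation of every pair through plain cross_validate
  pairs <- combn(6, 2, simplify = FALSE)
  direct <- vapply(pairs, function(s) {
    pl <- fast_pipeline(features = paste0("f", s))
    cross_validate(tab, pl, fold_seed = 2)$mean[["Gm"]]
  }, numeric(1))
  ord <- order(-direct, vapply(pairs, paste, character(1), collapse = ","))
  beam_sets <- lapply(res$stages[["2"]], `[[`, "subset")
  expect_equal(beam_sets, pairs[ord[1:4]])
  expect_equal(vapply(res$stages[["2"]], `[[`, numeric(1), "mean_gm"),
               direct[ord[1:4]], tolerance = 1e-12)
})

test_that("width-1 beam reduces to greedy forward selection", {
  tab <- planted_table(n_features = 6, informative = c(3, 6), seed = 5)
  cfg <- beam_config(beam_width = 1L, max_size = 4L,
                     pipeline = fast_pipeline(), fold_seed = 4)
  res <- beam_search(tab, cfg)

  # independently coded greedy forward search seeded with the best pair
  score <- function(s) {
    cross_validate(tab, fast_pipeline(features = paste0("f", sort(s))),
                   fold_seed = 4)$mean[["Gm"]]
  }
  pairs <- combn(6, 2, simplify = FALSE)
  ps <- vapply(pairs, score, numeric(1))
  current <- pairs[[order(-ps, vapply(pairs, paste, character(1),
                                      collapse = ","))[1]]]
  for (size in 3:4) {
    cands <- setdiff(1:6, current)
    cs <- vapply(cands, function(f) score(c(current, f)), numeric(1))
    keys <- vapply(cands, function(f) {
      paste(sprintf("%06d", sort(c(current, f))), collapse = ",")
    }, character(1))
    current <- sort(c(current, cands[order(-cs, keys)[1]]))
    expect_equal(res$stages[[as.character(size)]][[1L]]$subset, current)
  }
})

test_that("beam search recovers a planted pair and is deterministic", {
  tab <- planted_table(n_features = 8, informative = c(4, 7),
                       n_pos = 69, n_neg = 431, separation = 3, seed = 9)
  cfg <- function() beam_config(beam_width = 10L, max_size = 2L,
                                pipeline = fast_pipeline(), fold_seed = 6)
  r1 <- beam_search(tab, cfg())
  r2 <- beam_search(tab, cfg())
  expect_equal(r1$stages[["2"]][[1L]]$subset, c(4L, 7L))
  expect_equal(lapply(r1$stages[["2"]], `[[`, "subset"),
               lapply(r2$stages[["2"]], `[[`, "subset"))
  expect_equal(vapply(r1$stages[["2"]], `[[`, numeric(1), "mean_gm"),
               vapply(r2$stages[["2"]], `[[`, numeric(1), "mean_gm"))
})

test_that("the cache answers repeats and invalidates on changed inputs", {
  cache <- score_cache()
  rec <- list(subset = c(1L, 2L), mean_gm = 0.9)
  cache_store(cache, "k1", rec)
  expect_equal(cache_lookup(cache, "k1"), rec)
  expect_null(cache_lookup(cache, "k-other"))

  # fingerprints respond to gamma and data changes
  pl1 <- ldr_pipeline(gamma = 1.5)
  pl2 <- ldr_pipeline(gamma = 2.0)
  f1 <- mildrem:::subset_fingerprint(c(1, 2), pl1, 1L, "hashA")
  expect_identical(f1, mildrem:::subset_fingerprint(c(2, 1), pl1, 1L,
                                                    "hashA"))
  expect_false(identical(f1, mildrem:::subset_fingerprint(c(1, 2), pl2,
                                                          1L, "hashA")))
  expect_false(identical(f1, mildrem:::subset_fingerprint(c(1, 2), pl1,
                                                          1L, "hashB")))

  # a second identical beam run performs zero new evaluations
  tab <- planted_table(n_features = 5, seed = 2)
  shared <- score_cache()
  cfg1 <- beam_config(beam_width = 2L, max_size = 3L,
                      pipeline = fast_pipeline(), fold_seed = 3,
                      cache = shared)
  first <- beam_search(tab, cfg1)
  expect_gt(first$evaluations, 0L)
  second <- beam_search(tab, cfg1)
  expect_equal(second$evaluations, 0L)
  expect_equal(lapply(second$stages, function(s) s[[1L]]$subset),
               lapply(first$stages, function(s) s[[1L]]$subset))
})

test_that("a file-backed cache survives a round-trip and rejects garbage", {
  path <- withr::local_tempfile(fileext = ".json")
  cache <- score_cache(path)
  cache_store(cache, "key", list(subset = c(1L, 3L), mean_gm = 0.75))
  cache_save(cache)
  reloaded <- score_cache(path)
  hit <- cache_lookup(reloaded, "key")
  expect_equal(hit$mean_gm, 0.75)
  writeLines("{not json", path)
  expect_warning(score_cache(path), "corrupted")
})

test_that("grid search enumerates cells and degenerates to a single CV", {
  tab <- planted_table(n_features = 3, informative = c(1, 2),
                       n_pos = 40, n_neg = 200, separation = 3, seed = 4)
  pl <- ldr_pipeline(folds = 5L)

  g <- grid_search(tab, subset = c("f1", "f2"), gammas = c(0.5, 1, 2),
                   ms = c(10, 17), pipeline = pl, fold_seed = 8)
  expect_equal(dim(g$gm), c(3L, 2L))
  expect_true(all(g$gm >= 0 & g$gm <= 1))
  best_direct <- max(g$gm)
  expect_equal(g$best$gm, best_direct)

  # 1 x 1 grid equals the direct call bit for bit
  g1 <- grid_search(tab, subset = c("f1", "f2"), gammas = 1.5, ms = 17,
                    pipeline = pl, fold_seed = 8)
  pl_direct <- pl
  pl_direct$features <- c("f1", "f2")
  pl_direct$mapping <- "rbf"
  pl_direct$gamma <- 1.5
  pl_direct$n_components <- 17L
  direct <- cross_validate(tab, pl_direct, fold_seed = 8)
  expect_identical(unname(g1$gm[1, 1]), unname(direct$mean[["Gm"]]))

  # duplicated gamma rows are exactly equal under identical map seeds
  g2 <- grid_search(tab, subset = c("f1", "f2"), gammas = c(1, 1),
                    ms = c(10, 17), pipeline = pl, fold_seed = 8)
  expect_identical(unname(g2$gm[1, ]), unname(g2$gm[2, ]))

  # matrix export for heatmap rendering
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_matrix(g, path)
  mat <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  expect_equal(dim(mat), c(3L, 3L))
  expect_equal(mat$gamma, c(0.5, 1, 2))
})

test_that("beam reports export one ranked row per kept subset", {
  tab <- planted_table(n_features = 4, informative = c(1, 3), seed = 6)
  res <- beam_search(tab, beam_config(beam_width = 2L, max_size = 3L,
                                      pipeline = fast_pipeline(),
                                      fold_seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beam_report(res, path)
  rep_ <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(rep_), 4L)  # 2 sizes x beam width 2
  expect_true(all(rep_$size %in% c(2L, 3L)))
})
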