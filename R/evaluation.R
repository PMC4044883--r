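# Imbalance-aware evaluation: confusion counts, sensitivity/specificity,
# their geometric mean, stratified folds and cross-validation.
#
# With a positive:negative ratio near 1:13, raw accuracy rewards the
# always-negative classifier; the geometric mean Gm = sqrt(SE * SP)
# collapses to zero as soon as either class is ignored, which is why it is
# the headline score everywhere in this package.

#' Confusion counts for binary predictions
#'
#' Positive class = pre-miRNA (label 1).
#'
#' @param truth,predicted binary vectors of equal length.
#' @return a `confusion_counts` list with fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, predicted) {
  truth <- as_binary_labels(truth)
  predicted <- as_binary_labels(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ (", length(truth), " vs ",
         length(predicted), ")")
  }
  structure(list(
    TP = sum(truth == 1L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP =", x$TP, " TN =", x$TN, " FP =", x$FP, " FN =", x$FN, "\n")
  invisible(x)
}

#' Sensitivity, specificity and geometric mean
#'
#' `SE = TP / (TP + FN)`, `SP = TN / (TN + FP)`,
#' `Gm = sqrt(SE * SP)`.  A zero denominator yields 0 with a warning.
#'
#' @param c a `confusion_counts` object.
#' @return a fraction in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  den <- c$TP + c$FN
  if (den == 0) {
    warning("no positive samples; sensitivity reported as 0")
    return(0)
  }
  c$TP / den
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  den <- c$TN + c$FP
  if (den == 0) {
    warning("no negative samples; specificity reported as 0")
    return(0)
  }
  c$TN / den
}

#' @rdname sensitivity
#' @param se,sp sensitivity and specificity fractions.
#' @export
geometric_mean <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  sqrt(se * sp)
}

#' Stratified fold assignment
#'
#' Partitions samples into `k` folds so that per-fold class counts differ
#' from perfect proportionality by at most one per class.
#'
#' @param labels binary label vector.
#' @param k number of folds (each class must have at least `k` samples).
#' @param seed shuffling seed.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as_binary_labels(labels)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  for (cls in c(0L, 1L)) {
    if (sum(labels == cls) < k) {
      stop("class ", cls, " has fewer samples (", sum(labels == cls),
           ") than folds (", k, ")")
    }
  }
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified cross-validation of an LDR pipeline
#'
#' For each fold the full pipeline (standardization, explicit map,
#' discriminant projection, Bayes classifier) is fitted on the training
#' folds only and applied to the held-out fold.  Per-fold SE/SP/Gm are
#' reported with their mean and standard deviation across folds (the
#' headline aggregate), alongside metrics from the pooled confusion counts.
#'
#' @param table a feature table (see [feature_table()]).
#' @param pipeline an [ldr_pipeline()] configuration.
#' @param fold_seed seed of the stratified fold shuffle.
#' @return a `cv_summary` with fields `folds` (per-fold data.frame including
#'   a fingerprint of each fitted model), `mean`, `sd`, `pooled`,
#'   `fold_seed`, `config_hash`, `pipeline`.
#' @export
cross_validate <- function(table, pipeline, fold_seed = 1L) {
  stopifnot(inherits(pipeline, "ldr_pipeline"))
  table <- feature_table(table)
  feats <- resolve_features(table, pipeline)
  X <- as.matrix(table[, feats, drop = FALSE])
  y <- as_binary_labels(table$label)
  k <- pipeline$folds
  fold <- stratified_folds(y, k, fold_seed)

  rows <- vector("list", k)
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(k)) {
    test <- fold == f
    train <- !test
    if (k == 1L) { test <- rep(TRUE, length(y)); train <- test }
    fit <- tryCatch(
      pipeline_fit(X[train, , drop = FALSE], y[train], pipeline),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    pred <- pipeline_predict(fit, X[test, , drop = FALSE])
    cc <- confusion(y[test], pred$label)
    se <- suppressWarnings(sensitivity(cc))
    sp <- suppressWarnings(specificity(cc))
    rows[[f]] <- data.frame(fold = f, TP = cc$TP, TN = cc$TN, FP = cc$FP,
                            FN = cc$FN, SE = se, SP = sp,
                            Gm = geometric_mean(se, sp),
                            model_hash = rlang::hash(fit))
    pooled <- Map(`+`, pooled, cc[c("TP", "TN", "FP", "FN")])
  }
  folds_df <- do.call(rbind, rows)
  pc <- structure(pooled, class = "confusion_counts")
  pse <- suppressWarnings(sensitivity(pc))
  psp <- suppressWarnings(specificity(pc))
  structure(list(
    folds = folds_df,
    mean = c(SE = mean(folds_df$SE), SP = mean(folds_df$SP),
             Gm = mean(folds_df$Gm)),
    sd = c(SE = stats::sd(folds_df$SE), SP = stats::sd(folds_df$SP),
           Gm = stats::sd(folds_df$Gm)),
    pooled = c(SE = pse, SP = psp, Gm = geometric_mean(pse, psp)),
    fold_seed = as.integer(fold_seed),
    config_hash = rlang::hash(pipeline),
    pipeline = pipeline
  ), class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  k <- nrow(x$folds)
  cat(k, "-fold stratified cross-validation (fold seed ", x$fold_seed,
      ", config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat(sprintf("  mean   SE = %.4f  SP = %.4f  Gm = %.4f (sd %.4f)\n",
              x$mean["SE"], x$mean["SP"], x$mean["Gm"], x$sd["Gm"]))
  cat(sprintf("  pooled SE = %.4f  SP = %.4f  Gm = %.4f\n",
              x$pooled["SE"], x$pooled["SP"], x$pooled["Gm"]))
  invisible(x)
}

#' Write a cross-validation report
#'
#' One row per fold plus `mean`, `sd` and `pooled` summary rows, as
#' delimited text.
#'
#' @param cv a `cv_summary`.
#' @param path output file.
#' @param sep field delimiter (default tab).
#' @export
write_cv_report <- function(cv, path, sep = "\t") {
  stopifnot(inherits(cv, "cv_summary"))
  df <- cv$folds[, c("fold", "TP", "TN", "FP", "FN", "SE", "SP", "Gm")]
  df$fold <- as.character(df$fold)
  extra <- data.frame(fold = c("mean", "sd", "pooled"),
                      TP = NA, TN = NA, FP = NA, FN = NA,
                      SE = c(cv$mean["SE"], cv$sd["SE"], cv$pooled["SE"]),
                      SP = c(cv$mean["SP"], cv$sd["SP"], cv$pooled["SP"]),
                      Gm = c(cv$mean["Gm"], cv$sd["Gm"], cv$pooled["Gm"]))
  out <- rbind(df, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fold_seed=", cv$fold_seed,
                    " config_hash=", cv$config_hash), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
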