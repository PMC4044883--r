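# Synthetic two-class fixtures emulating the hairpin-classification
# problem: heavy class imbalance (about 1:13), ~48 features of which only
# a few are informative, with homoscedastic-Gaussian, heteroscedastic, or
# XOR-like (non-linearly separable) structure.

#' Simulation specification
#'
#' Defaults give a desk-scale miniature of the reference benchmark: 69
#' positives vs 925 negatives (about 1:13.4), 48 features of which two are
#' informative.  `sim_spec_full()` is the full-scale profile (691 vs
#' 9,248).
#'
#' @param n_pos,n_neg class sample counts.
#' @param n_features total number of feature columns (default 48).
#' @param informative indices of the informative columns.
#' @param structure `"gaussian_homo"` (mean shift under shared covariance),
#'   `"gaussian_hetero"` (equal means, covariance ratio `separation`), or
#'   `"xor"` (two diagonal blobs per class at `(+-a, +-a)`,
#'   `a = separation/2`, so single-Gaussian class fits fail).
#' @param separation mean shift in Mahalanobis units (gaussian_homo),
#'   variance ratio (gaussian_hetero), or blob-center spread (xor).
#' @param noise_sd standard deviation of both the informative-dimension
#'   noise and the uninformative columns.
#' @param seed generator seed; same seed, same table, byte for byte.
#' @export
sim_spec <- function(n_pos = 69L, n_neg = 925L, n_features = 48L,
                     informative = c(1L, 2L),
                     structure = c("gaussian_homo", "gaussian_hetero",
                                   "xor"),
                     separation = 3, noise_sd = 1, seed = 1L) {
  structure_ <- match.arg(structure)
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  n_features <- as.integer(n_features)
  informative <- sort(unique(as.integer(informative)))
  if (n_pos < 1L || n_neg < 1L) stop("class counts must be >= 1")
  if (length(informative) < 1L || any(informative < 1L) ||
      any(informative > n_features)) {
    stop("informative indices must lie in 1..n_features")
  }
  if (structure_ == "xor" && length(informative) < 2L) {
    stop("the xor structure needs at least two informative features")
  }
  if (!is.numeric(separation) || separation < 0) {
    stop("separation must be non-negative")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be positive")
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, n_features = n_features,
                 informative = informative, structure = structure_,
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @rdname sim_spec
#' @param ... overrides passed to [sim_spec()].
#' @export
sim_spec_full <- function(...) {
  args <- utils::modifyList(list(n_pos = 691L, n_neg = 9248L), list(...))
  do.call(sim_spec, args)
}

# class-conditional mean(s) of the informative block; for xor, the blob
# centres per class
sim_centers <- function(spec) {
  ni <- length(spec$informative)
  switch(spec$structure,
    gaussian_homo = list(
      pos = rep(spec$separation * spec$noise_sd / sqrt(ni), ni),
      neg = rep(0, ni)),
    gaussian_hetero = list(pos = rep(0, ni), neg = rep(0, ni)),
    xor = {
      a <- spec$separation / 2
      list(pos = rbind(c(a, a), c(-a, -a)),
           neg = rbind(c(a, -a), c(-a, a)))
    })
}

#' Generate a synthetic feature table
#'
#' Labels are exactly `n_pos` ones followed by `n_neg` zeros; informative
#' columns carry the structure of the spec, all other columns are i.i.d.
#' `N(0, noise_sd^2)` in both classes.
#'
#' @param spec a [sim_spec()].
#' @return a feature table data.frame with columns `id`, `f1..fK`, `label`.
#' @export
simulate_features <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_pos + spec$n_neg
  p <- spec$n_features
  ni <- length(spec$informative)
  centers <- sim_centers(spec)

  X <- withr::with_seed(spec$seed, {
    M <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    pos <- seq_len(spec$n_pos)
    neg <- spec$n_pos + seq_len(spec$n_neg)
    if (spec$structure == "gaussian_homo") {
      M[pos, spec$informative] <-
        sweep(M[pos, spec$informative, drop = FALSE], 2L, centers$pos, `+`)
    } else if (spec$structure == "gaussian_hetero") {
      M[pos, spec$informative] <-
        M[pos, spec$informative, drop = FALSE] * sqrt(spec$separation)
    } else {  # xor on the first two informative columns
      xy <- spec$informative[1:2]
      quad_pos <- sample(1:2, spec$n_pos, replace = TRUE)
      quad_neg <- sample(1:2, spec$n_neg, replace = TRUE)
      M[pos, xy] <- M[pos, xy, drop = FALSE] + centers$pos[quad_pos, ]
      M[neg, xy] <- M[neg, xy, drop = FALSE] + centers$neg[quad_neg, ]
    }
    M
  })
  colnames(X) <- paste0("f", seq_len(p))
  df <- data.frame(id = sprintf("s%05d", seq_len(n)), X,
                   label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)),
                   stringsAsFactors = FALSE)
  feature_table(df)
}

# class-conditional log density of the informative block under the true
# generative model
sim_logdens <- function(spec, Xi, class = c("pos", "neg")) {
  class <- match.arg(class)
  centers <- sim_centers(spec)
  s <- spec$noise_sd
  ni <- ncol(Xi)
  if (spec$structure == "xor") {
    cs <- centers[[class]]
    comp <- function(center) {
      rowSums(stats::dnorm(Xi[, 1:2, drop = FALSE],
                           mean = matrix(center, nrow(Xi), 2, byrow = TRUE),
                           sd = s, log = TRUE))
    }
    lp <- cbind(comp(cs[1, ]), comp(cs[2, ]))
    m <- pmax(lp[, 1], lp[, 2])
    mix <- m + log(0.5 * exp(lp[, 1] - m) + 0.5 * exp(lp[, 2] - m))
    rest <- if (ni > 2L) {
      rowSums(stats::dnorm(Xi[, -(1:2), drop = FALSE], sd = s, log = TRUE))
    } else 0
    mix + rest
  } else {
    sd_i <- if (spec$structure == "gaussian_hetero" && class == "pos") {
      s * sqrt(spec$separation)
    } else s
    mu <- centers[[class]]
    rowSums(stats::dnorm(Xi,
                         mean = matrix(mu, nrow(Xi), ni, byrow = TRUE),
                         sd = sd_i, log = TRUE))
  }
}

#' Monte-Carlo Bayes-rule performance ceiling
#'
#' Draws `n_mc` samples from the true generative mixture of a [sim_spec()]
#' and scores the optimal (true-density, true-prior) Bayes rule, giving the
#' SE/SP/Gm ceiling that any trained pipeline on matched data should
#' approach but not exceed.  Standard errors are binomial (delta method for
#' Gm).
#'
#' @param spec a [sim_spec()].
#' @param n_mc number of Monte-Carlo draws.
#' @param mc_seed seed of the Monte-Carlo draw (independent of the table
#'   seed by default).
#' @return a list with `se`, `sp`, `gm`, their standard errors `se_se`,
#'   `sp_se`, `gm_se`, and the realized class draw sizes.
#' @export
bayes_gm_oracle <- function(spec, n_mc = 100000L, mc_seed = spec$seed + 1000L) {
  stopifnot(inherits(spec, "sim_spec"), n_mc >= 100L)
  p_pos <- spec$n_pos / (spec$n_pos + spec$n_neg)
  ni <- length(spec$informative)
  res <- withr::with_seed(as.integer(mc_seed), {
    lab <- stats::rbinom(n_mc, 1L, p_pos)
    n1 <- sum(lab == 1L)
    Xi <- matrix(stats::rnorm(n_mc * ni, sd = spec$noise_sd), n_mc, ni)
    centers <- sim_centers(spec)
    if (spec$structure == "gaussian_homo") {
      Xi[lab == 1L, ] <- sweep(Xi[lab == 1L, , drop = FALSE], 2L,
                               centers$pos, `+`)
    } else if (spec$structure == "gaussian_hetero") {
      Xi[lab == 1L, ] <- Xi[lab == 1L, , drop = FALSE] *
        sqrt(spec$separation)
    } else {
      quad1 <- sample(1:2, n1, replace = TRUE)
      quad0 <- sample(1:2, n_mc - n1, replace = TRUE)
      Xi[lab == 1L, 1:2] <- Xi[lab == 1L, 1:2, drop = FALSE] +
        centers$pos[quad1, ]
      Xi[lab == 0L, 1:2] <- Xi[lab == 0L, 1:2, drop = FALSE] +
        centers$neg[quad0, ]
    }
    list(lab = lab, Xi = Xi)
  })
  lp1 <- log(p_pos) + sim_logdens(spec, res$Xi, "pos")
  lp0 <- log(1 - p_pos) + sim_logdens(spec, res$Xi, "neg")
  pred <- as.integer(lp1 > lp0)  # ties to the majority class
  cc <- confusion(res$lab, pred)
  se <- suppressWarnings(sensitivity(cc))
  sp <- suppressWarnings(specificity(cc))
  gm <- geometric_mean(se, sp)
  n1 <- cc$TP + cc$FN
  n0 <- cc$TN + cc$FP
  se_se <- sqrt(se * (1 - se) / max(n1, 1L))
  sp_se <- sqrt(sp * (1 - sp) / max(n0, 1L))
  gm_se <- if (gm > 0) {
    sqrt((sp / (2 * gm))^2 * se_se^2 + (se / (2 * gm))^2 * sp_se^2)
  } else {
    # degenerate: fall back to the conservative half-width of a binomial
    0.5 * sqrt(se_se^2 + sp_se^2)
  }
  list(se = se, sp = sp, gm = gm,
       se_se = se_se, sp_se = sp_se, gm_se = gm_se,
       n_pos_drawn = n1, n_neg_drawn = n0, n_mc = n_mc)
}
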