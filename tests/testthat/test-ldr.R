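# Two-class Gaussian estimation, scatter matrices and the three
# discriminant criteria.

test_that("class statistics match hand-computed and brute-force values", {
  x <- rbind(c(0, 0), c(2, 0), c(10, 0), c(12, 0))
  cg <- estimate_class_gaussians(x, c(1, 1, 0, 0))
  expect_equal(cg$pos$mean, c(1, 0))
  expect_equal(cg$neg$mean, c(11, 0))
  expect_equal(cg$pos$prior, 0.5)

  # imbalance of the reference benchmark: empirical priors are fractions
  y <- rep(c(1L, 0L), c(691L, 9248L))
  x2 <- cbind(stats::rnorm(9939), stats::rnorm(9939))
  cg2 <- estimate_class_gaussians(x2, y)
  expect_equal(cg2$pos$prior, 691 / 9939)
  expect_equal(cg2$neg$prior, 9248 / 9939)
  expect_equal(cg2$pos$prior + cg2$neg$prior, 1)

  # biased covariance equals the direct double-loop estimator
  X <- withr::with_seed(7, matrix(rnorm(200 * 4), 200, 4))
  lab <- rep(c(1L, 0L), each = 100L)
  cg3 <- estimate_class_gaussians(X, lab)
  Xp <- X[1:100, ]
  m <- colMeans(Xp)
  S <- matrix(0, 4, 4)
  for (i in 1:100) S <- S + tcrossprod(Xp[i, ] - m)
  expect_equal(cg3$pos$cov, S / 100, tolerance = 1e-10)
})

test_that("degenerate and invalid inputs error cleanly", {
  expect_error(estimate_class_gaussians(diag(3), c(1, 0, 0)),
               "degenerate class")
  expect_error(estimate_class_gaussians(matrix(c(1, NA, 2, 3), 2),
                                        c(1, 0)), "non-finite")
  expect_error(estimate_class_gaussians(diag(4), rep(1, 4)),
               "both classes")
})

test_that("scatter matrices follow their definitions", {
  c1 <- class_gaussian(c(0, 0), diag(2), 0.5)
  c2 <- class_gaussian(c(2, 0), diag(2), 0.5)
  sc <- scatter_matrices(c1, c2)
  expect_equal(sc$within, diag(2))
  expect_equal(sc$between, matrix(c(4, 0, 0, 0), 2))

  # between-class scatter has rank one for any class pair
  for (seed in 1:5) {
    g <- rand_gauss_pair(4, seed)
    ev <- eigen(scatter_matrices(g$c1, g$c2)$between,
                symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(ev[2]), 1e-10 * max(ev[1], 1))
  }
  expect_error(scatter_matrices(c1, class_gaussian(0, diag(1), 0.5)),
               "dimensions")
})

test_that("criterion values match independent term-by-term oracles", {
  # Fisher criterion on an axis-aligned instance: J = 4
  c1 <- class_gaussian(c(1, 0), diag(2), 0.5)
  c2 <- class_gaussian(c(-1, 0), diag(2), 0.5)
  expect_equal(criterion_value(rbind(c(1, 0)), c1, c2, "fda"), 4,
               tolerance = 1e-4)

  for (seed in 1:10) {
    g <- rand_gauss_pair(3, seed, hetero = TRUE)
    A1 <- withr::with_seed(seed + 100, matrix(rnorm(3), 1))
    A2 <- withr::with_seed(seed + 200, matrix(rnorm(6), 2))
    # homoscedastic collapse: the HDA log term vanishes when S1 = S2
    gh <- rand_gauss_pair(3, seed, hetero = FALSE)
    expect_equal(criterion_value(A1, gh$c1, gh$c2, "hda"),
                 criterion_value(A1, gh$c1, gh$c2, "fda"),
                 tolerance = 1e-6)
    # Chernoff criterion vs an independently coded evaluation
    expect_equal(criterion_value(A2, g$c1, g$c2, "cda", lambda = 1e-12),
                 oracle_cda(A2, g$c1, g$c2), tolerance = 1e-8)
    expect_equal(criterion_value(A1, g$c1, g$c2, "fda", lambda = 1e-12),
                 oracle_fda(A1, g$c1, g$c2), tolerance = 1e-8)
  }
})

test_that("Fisher projection solves the generalized eigenproblem", {
  c1 <- class_gaussian(c(1, 0), diag(2), 0.5)
  c2 <- class_gaussian(c(-1, 0), diag(2), 0.5)
  f <- fit_fda(scatter_matrices(c1, c2), 1)
  expect_equal(abs_cosine(f$matrix, c(1, 0)), 1, tolerance = 1e-8)
  expect_equal(f$eigenvalues[1], 4, tolerance = 1e-4)

  # leading direction is proportional to S_W^{-1} (m1 - m2)
  c3 <- class_gaussian(c(0, 0), diag(c(1, 4)), 0.5)
  c4 <- class_gaussian(c(0, 3), diag(c(1, 4)), 0.5)
  f2 <- fit_fda(scatter_matrices(c3, c4), 1)
  expect_equal(abs_cosine(f2$matrix, solve(diag(c(1, 4)), c(0, -3))), 1,
               tolerance = 1e-6)
  expect_error(fit_fda(scatter_matrices(c3, c4), 3), "d must satisfy")
})

test_that("the Fisher criterion is invariant to invertible row mixing", {
  for (seed in 1:10) {
    g <- rand_gauss_pair(4, seed)
    A <- withr::with_seed(seed, matrix(rnorm(8), 2))
    T_ <- withr::with_seed(seed + 50, {
      repeat {
        M <- matrix(rnorm(4), 2)
        if (abs(det(M)) > 0.1) break
      }
      M
    })
    expect_equal(criterion_value(T_ %*% A, g$c1, g$c2, "fda",
                                 lambda = 1e-12),
                 criterion_value(A, g$c1, g$c2, "fda", lambda = 1e-12),
                 tolerance = 1e-8)
  }
})

test_that("fitted Fisher projection beats random projections", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      n <- sample(2:6, 1)
      d <- sample(1:2, 1)
      g <- rand_gauss_pair(n, rep, hetero = FALSE, p1 = runif(1, .2, .8))
      sc <- scatter_matrices(g$c1, g$c2)
      J_fit <- criterion_value(fit_fda(sc, d)$matrix, g$c1, g$c2, "fda",
                               lambda = 1e-12)
      J_rand <- replicate(200, {
        criterion_value(matrix(rnorm(d * n), d), g$c1, g$c2, "fda",
                        lambda = 1e-12)
      })
      expect_gte(J_fit, max(J_rand) - 1e-8)
    }
  })
})

test_that("heteroscedastic projection finds variance-borne structure", {
  # all discriminative information in the axis-1 variance ratio
  c1 <- class_gaussian(c(0, 0), diag(c(1, 1)), 0.5)
  c2 <- class_gaussian(c(0, 0), diag(c(9, 1)), 0.5)
  h <- fit_hda(c1, c2, 1)
  expect_equal(abs_cosine(h$matrix, c(1, 0)), 1, tolerance = 1e-8)

  # 1-D scan oracle: axis 1 maximizes the Chernoff separability over a
  # dense set of directions
  th <- seq(0, pi, length.out = 721)
  Jscan <- vapply(th, function(t) {
    criterion_value(rbind(c(cos(t), sin(t))), c1, c2, "cda")
  }, numeric(1))
  expect_equal(abs_cosine(c(cos(th[which.max(Jscan)]),
                            sin(th[which.max(Jscan)])), c(1, 0)), 1,
               tolerance = 1e-4)

  # homoscedastic collapse to the Fisher direction
  for (seed in 1:8) {
    gh <- rand_gauss_pair(4, seed, hetero = FALSE)
    f <- fit_fda(scatter_matrices(gh$c1, gh$c2), 1)
    h2 <- fit_hda(gh$c1, gh$c2, 1)
    expect_gt(abs_cosine(f$matrix, h2$matrix), 1 - 1e-6)
  }

  # HDA never scores below the Fisher solution on its own criterion
  for (seed in 11:20) {
    g <- rand_gauss_pair(3, seed, hetero = TRUE)
    f <- fit_fda(scatter_matrices(g$c1, g$c2), 1)
    h3 <- fit_hda(g$c1, g$c2, 1)
    expect_gte(criterion_value(h3$matrix, g$c1, g$c2, "hda"),
               criterion_value(f$matrix, g$c1, g$c2, "hda") - 1e-10)
  }
})

test_that("Chernoff ascent is monotone and recovers known optima", {
  # ascent property and homoscedastic equivalence with Fisher
  for (seed in 1:5) {
    gh <- rand_gauss_pair(3, seed, hetero = FALSE)
    f <- fit_fda(scatter_matrices(gh$c1, gh$c2), 1)
    cd <- fit_cda(gh$c1, gh$c2, 1)
    expect_true(all(diff(cd$trace) >= 0))
    expect_gte(cd$objective_value,
               criterion_value(f$matrix, gh$c1, gh$c2, "cda") - 1e-10)
    expect_gt(abs_cosine(f$matrix, cd$matrix), 0.999)
  }

  # heteroscedastic d = 1: no direction among 2,000 random ones beats it
  for (seed in 1:3) {
    g <- rand_gauss_pair(3, seed + 30, hetero = TRUE)
    cd <- fit_cda(g$c1, g$c2, 1)
    R <- withr::with_seed(seed, matrix(rnorm(3 * 2000), 3))
    Jr <- apply(R, 2, function(v) {
      criterion_value(rbind(v), g$c1, g$c2, "cda")
    })
    expect_gte(cd$objective_value, max(Jr) - 1e-6)
  }
})
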