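# Shared fixture builders: everything is generated in code, no data files.

# random symmetric positive-definite matrix
rand_spd <- function(n, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(n * n), n)
    crossprod(M) + diag(0.5, n)
  })
}

# random pair of class Gaussians in n dimensions
rand_gauss_pair <- function(n, seed = 1, hetero = TRUE, p1 = NULL) {
  withr::with_seed(seed, {
    if (is.null(p1)) p1 <- runif(1, 0.2, 0.8)
    m1 <- rnorm(n)
    m2 <- rnorm(n)
    S1 <- crossprod(matrix(rnorm(n * n), n)) + diag(0.5, n)
    S2 <- if (hetero) crossprod(matrix(rnorm(n * n), n)) + diag(0.5, n)
          else S1
    list(c1 = mildrem::class_gaussian(m1, S1, p1),
         c2 = mildrem::class_gaussian(m2, S2, 1 - p1))
  })
}

# absolute cosine between two direction vectors
abs_cosine <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# independent, term-by-term implementations of the criteria used as
# oracles; deliberately built from scratch (base solve/eigen only)
oracle_logm <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% diag(log(e$values), nrow(M)) %*% t(e$vectors)
}
oracle_powm <- function(M, p) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% diag(e$values^p, nrow(M)) %*% t(e$vectors)
}
oracle_cda <- function(A, c1, c2) {
  A <- rbind(A)
  p1 <- c1$prior; p2 <- c2$prior
  SW <- p1 * c1$cov + p2 * c2$cov
  SE <- tcrossprod(c1$mean - c2$mean)
  ASWA <- A %*% SW %*% t(A)
  sum(diag(p1 * p2 * (A %*% SE %*% t(A)) %*% solve(ASWA))) +
    sum(diag(oracle_logm(ASWA))) -
    p1 * sum(diag(oracle_logm(A %*% c1$cov %*% t(A)))) -
    p2 * sum(diag(oracle_logm(A %*% c2$cov %*% t(A))))
}
oracle_fda <- function(A, c1, c2) {
  A <- rbind(A)
  SW <- c1$prior * c1$cov + c2$prior * c2$cov
  SE <- tcrossprod(c1$mean - c2$mean)
  sum(diag(solve(A %*% SW %*% t(A)) %*% (A %*% SE %*% t(A))))
}

# small labelled feature table with planted Gaussian signal, for selection
# tests
planted_table <- function(n_features = 6, informative = c(2, 5),
                          n_pos = 40, n_neg = 200, separation = 2.5,
                          seed = 1) {
  spec <- mildrem::sim_spec(n_pos = n_pos, n_neg = n_neg,
                            n_features = n_features,
                            informative = informative,
                            structure = "gaussian_homo",
                            separation = separation, seed = seed)
  mildrem::simulate_features(spec)
}

# write a FASTA file from named sequences, return the path
write_tmp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
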