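test_that("whitening retains the rank at threshold 1 and matches the 2x2 closed form", {
  # rank-3 noiseless matrix
  set.seed(31)
  A <- matrix(rnorm(40 * 3), 40, 3)
  S <- matrix(rnorm(3 * 60), 3, 60)
  X <- A %*% S
  dimnames(X) <- list(sprintf("G%02d", 1:40), sprintf("S%02d", 1:60))
  b <- whiten(X, var_threshold = 1.0)
  expect_identical(ncol(b$loadings), 3L)

  # 2-gene toy: eigenvalues of the 2x2 gene covariance in closed form
  Y <- random_expression(2, 50, seed = 32)
  C <- cov(t(Y))
  disc <- sqrt((C[1, 1] - C[2, 2])^2 + 4 * C[1, 2]^2)
  lam <- c((C[1, 1] + C[2, 2] + disc) / 2, (C[1, 1] + C[2, 2] - disc) / 2)
  b2 <- whiten(Y, var_threshold = 1.0)
  expect_equal(b2$eigenvalues, lam, tolerance = 1e-10)

  expect_identical(formals(whiten)$var_threshold, 0.90)
  expect_error(whiten(Y, var_threshold = 0), "var_threshold")
  expect_error(whiten(Y, var_threshold = 1.2), "var_threshold")
})

test_that("whitened variables are centered, unit variance and decorrelated", {
  X <- random_expression(60, 80, seed = 33)
  b <- whiten(X, var_threshold = 0.95)
  Z <- b$whitened
  expect_lt(max(abs(rowMeans(Z))), 1e-8)
  expect_lt(max(abs(cov(t(Z)) - diag(nrow(Z)))), 1e-6)
  # loadings orthonormal
  G <- crossprod(b$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # retained variance reaches the threshold with the fewest axes
  expect_gte(sum(b$explained_fraction), 0.95 - 1e-12)
  expect_lt(sum(b$explained_fraction[-length(b$explained_fraction)]), 0.95)
})

test_that("a single-run consensus is the run itself with credibility 1", {
  sim <- generate_expression(n_genes = 100, n_samples = 200, k = 3,
                             set_size = 15, seed = 34)
  b <- whiten(sim$X)
  cres <- run_consensus_ica(b, n_runs = 1, min_match_runs = 1, seed = 7)
  expect_identical(unname(cres$credibility),
                   rep(1, nrow(cres$sources)))
  expect_identical(cres$report$n_runs, 1L)
})

test_that("credibility filtering retains at 13/25 runs and drops at 12/25", {
  set.seed(35)
  n <- 100
  stable <- rnorm(n)
  flaky <- rnorm(n)
  make_runs <- function(n_flaky_runs) {
    lapply(1:25, function(r) {
      comps <- rbind(stable + rnorm(n, sd = 0.01), rnorm(n))
      if (r <= n_flaky_runs)
        comps <- rbind(comps, flaky + rnorm(n, sd = 0.01))
      comps
    })
  }
  res13 <- consensus_match(make_runs(13), n_runs = 25, match_r = 0.98,
                           min_match_runs = 13)
  expect_identical(nrow(res13$sources), 2L)
  expect_true(any(abs(res13$credibility - 0.52) < 1e-12))

  res12 <- consensus_match(make_runs(12), n_runs = 25, match_r = 0.98,
                           min_match_runs = 13)
  expect_identical(nrow(res12$sources), 1L)   # only the stable component
  expect_identical(unname(res12$credibility), 1)
  expect_identical(res12$report$n_dropped, res12$report$n_clusters - 1L)
})

test_that("consensus recovers planted Laplace sources with matched mixing columns", {
  # low-noise fixture: every planted source should be recovered near-exactly
  sim <- generate_expression(n_genes = 200, n_samples = 400, k = 4,
                             noise_sd = 0.01, set_size = 20, seed = 39)
  b <- whiten(sim$X)
  cres <- run_consensus_ica(b, n_runs = 25, seed = 39)
  R <- abs(cor(t(sim$truth$true_sources), t(cres$sources)))
  best <- apply(R, 1, max)
  expect_true(all(best > 0.99))
  expect_identical(length(unique(apply(R, 1, which.max))), 4L)
  expect_true(all(cres$credibility == 1))

  # at the default study scale (noise sd 0.1): distinct matches above 0.95
  fx <- planted_fixture()
  expect_gte(nrow(fx$cres$sources), 6L)
  Rm <- abs(cor(fx$sim$truth$true_mixing, fx$MM$weights))
  expect_true(all(apply(Rm, 1, max) >= 0.95))
  expect_identical(length(unique(apply(Rm, 1, which.max))), 6L)
})

test_that("mixing recomputation inverts a noiseless factorization", {
  set.seed(36)
  k <- 4
  A <- matrix(rnorm(80 * k), 80, k)
  S <- matrix(rnorm(k * 120), k, 120)
  S <- S - rowMeans(S)
  X <- A %*% S
  dimnames(X) <- list(sprintf("G%02d", 1:80), sprintf("S%03d", 1:120))
  rownames(S) <- paste0("TC", 1:k)
  MM <- recompute_mixing(X, S)
  expect_lt(max(abs(MM$weights - A)), 1e-8)

  # duplicating a sample leaves the projection unchanged
  X2 <- cbind(X, X[, 1, drop = FALSE])
  colnames(X2)[121] <- "S999"
  S2 <- cbind(S, S[, 1])
  MM2 <- recompute_mixing(X2, S2)
  expect_lt(max(abs(MM2$weights - MM$weights)), 1e-8)

  # orthonormal zero-mean sources: weights equal Xc %*% t(S)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(120 * k), 120, k))))[, -1]
  So <- t(Q)
  rownames(So) <- paste0("TC", 1:k)
  colnames(So) <- colnames(X)
  MMo <- recompute_mixing(X, So)
  Xc <- X - rowMeans(X)
  expect_lt(max(abs(MMo$weights - Xc %*% t(So))), 1e-8)
})

test_that("rank-deficient sources fall back to the pseudo-inverse with a warning", {
  X <- random_expression(30, 40, seed = 37)
  S <- matrix(rnorm(40), 1, 40)[c(1, 1), ]
  S <- S - rowMeans(S)
  colnames(S) <- colnames(X)
  expect_warning(MM <- recompute_mixing(X, S), "rank deficient")
  expect_true(all(is.finite(MM$weights)))
})

test_that("consensus ICA is deterministic under a fixed seed and equivariant to gene order", {
  sim <- generate_expression(n_genes = 120, n_samples = 240, k = 3,
                             set_size = 15, seed = 38)
  b1 <- whiten(sim$X)
  c1 <- run_consensus_ica(b1, n_runs = 5, min_match_runs = 3, seed = 55)
  c1b <- run_consensus_ica(b1, n_runs = 5, min_match_runs = 3, seed = 55)
  expect_identical(c1$sources, c1b$sources)

  set.seed(1)
  perm <- sample(nrow(sim$X))
  Xp <- sim$X[perm, ]
  b2 <- whiten(Xp)
  c2 <- run_consensus_ica(b2, n_runs = 5, min_match_runs = 3, seed = 55)
  expect_equal(c2$sources, c1$sources, tolerance = 1e-6)
  M1 <- recompute_mixing(sim$X, c1)
  M2 <- recompute_mixing(Xp, c2)
  expect_equal(M2$weights[rownames(M1$weights), ], M1$weights,
               tolerance = 1e-6)
})

test_that("mixing matrix TSV round-trips with credibility", {
  fx <- planted_fixture()
  path <- tempfile(fileext = ".tsv")
  write_mixing(fx$MM, path)
  MM2 <- read_mixing(path)
  expect_equal(MM2$weights, fx$MM$weights, tolerance = 1e-12)
  expect_equal(MM2$credibility, fx$MM$credibility, tolerance = 1e-12)
})
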