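test_that("set barcodes: member means and Welch T profiles", {
  W <- matrix(c(1, 3, 5,
                3, 1, 2,
                2, 2, 8,
                0, 4, 1), 4, 3, byrow = TRUE,
              dimnames = list(paste0("G", 1:4), paste0("TC", 1:3)))
  MM <- mixing_matrix(W)
  expect_equal(unname(set_barcode(MM, "G3")[1:3]), c(2, 2, 8))
  expect_equal(unname(set_barcode(MM, c("G1", "G2"))[1:2]), c(2, 2))
  expect_error(set_barcode(MM, c("G1", "GX")), "unknown gene")

  # Welch T barcode vs the textbook formula and t.test
  L <- matrix(rnorm(25), 5, 5,
              dimnames = list(paste0("G", 1:5), paste0("PC", 1:5)))
  basis <- structure(list(loadings = L), class = "whitened_basis")
  bc <- set_barcode(MM = NULL, members = c("G1", "G2"),
                    method = "pca_welch_t", basis = basis)
  expect_equal(as.numeric(bc), unname(oracle_welch_t(L[1:2, ], L[3:5, ])),
               tolerance = 1e-10)
  tt <- sapply(1:5, function(j)
    t.test(L[1:2, j], L[3:5, j], var.equal = FALSE)$statistic)
  expect_equal(as.numeric(bc), unname(tt), tolerance = 1e-10)
})

test_that("distance correlation handles exact dependence, degeneracy, and matches the oracle", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9)
  expect_equal(distance_correlation(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_identical(distance_correlation(rep(1, 5), x), 0)
  expect_equal(distance_correlation(c(1, 2, 3, 4), c(1, 3, 2, 5)),
               oracle_dcor(c(1, 2, 3, 4), c(1, 3, 2, 5)),
               tolerance = 1e-12)
  expect_error(distance_correlation(1:3, 1:4), "equal length")

  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(distance_correlation(x, y), oracle_dcor(x, y),
                 tolerance = 1e-12)
  }
})

test_that("permutation nulls stay in range and degenerate gracefully", {
  MM <- random_mixing(60, 8, seed = 42)
  x <- MM$weights[1, ]
  null <- build_null(x, MM, set_size = 10, n_perm = 200, seed = 5)
  expect_true(all(null$samples >= 0 & null$samples <= 1))
  expect_gt(null$kde_bandwidth, 0)
  expect_error(build_null(x, MM, 10, n_perm = 50, seed = 5), "at least 100")

  # exhaustive set: every permutation draws the whole universe
  null_all <- build_null(x, MM, set_size = 60, n_perm = 100, seed = 5)
  expect_lt(diff(range(null_all$samples)), 1e-12)
  expect_true(is.finite(prediction_score(0.5, null_all)))
})

test_that("null samples match an independent re-simulation distributionally", {
  MM <- random_mixing(150, 10, seed = 43)
  x <- MM$weights[7, ]
  null <- build_null(x, MM, set_size = 15, n_perm = 1000, seed = 9)
  # independent oracle: fresh draws with a different seed, naive computation
  set.seed(4242)
  resim <- replicate(1000, {
    idx <- sample(150, 15)
    oracle_dcor(x, colMeans(MM$weights[idx, ]))
  })
  expect_gt(suppressWarnings(ks.test(null$samples, resim)$p.value), 0.01)
})

test_that("prediction scores are calibrated at the median, signed in the tail, and match the mixture oracle", {
  # symmetric null around its median: Z at the median is ~0
  samples <- c(seq(0.2, 0.4, length.out = 500),
               rev(seq(0.2, 0.4, length.out = 500)))
  null <- structure(list(samples = samples, kde_bandwidth = 0.01,
                         n_perm = 1000L, set_size = 10L, seed = 1L,
                         statistic = "dcor"), class = "null_distribution")
  expect_lt(abs(prediction_score(median(samples), null)), 0.05)
  expect_lt(prediction_score(0.05, null), 0)

  # closed-form Gaussian mixture tail on {0.1, 0.2, 0.3}
  s3 <- c(0.1, 0.2, 0.3)
  bw <- bw.nrd0(s3)
  null3 <- structure(list(samples = s3, kde_bandwidth = bw, n_perm = 100L,
                          set_size = 3L, seed = 1L, statistic = "dcor"),
                     class = "null_distribution")
  p_impl <- pnorm(prediction_score(0.25, null3), lower.tail = FALSE)
  expect_equal(p_impl, oracle_kde_tail(0.25, s3, bw), tolerance = 1e-10)

  # strictly monotone in the observed statistic
  obs <- seq(0, 1, by = 0.05)
  z <- prediction_score(obs, null3)
  expect_true(all(diff(z) > 0))
  expect_true(all(is.finite(prediction_score(c(-50, 50), null3))))
})

test_that("planted set members outscore nonmembers on the ICA path", {
  fx <- planted_fixture()
  coll <- planted_collection(fx$sim$truth)
  tab <- score_all(fx$MM, coll, method = "ica", n_perm = 300, seed = 77)
  Z <- tab$scores
  for (nm in names(coll$sets)) {
    members <- coll$sets[[nm]]
    nonmembers <- setdiff(rownames(Z), members)
    expect_true(all(Z[members, nm] >
                      quantile(Z[nonmembers, nm], 0.95)))
  }
})

test_that("scores are invariant to consistent gene relabeling and to set grouping", {
  MM <- random_mixing(40, 6, seed = 44)
  coll <- generate_random_collection(MM$gene_ids, n_sets = 4,
                                     size_range = c(5, 8), seed = 3)
  tab <- score_all(MM, coll, method = "ica", n_perm = 150, seed = 10)

  set.seed(45)
  perm <- sample(40)
  MMp <- mixing_matrix(MM$weights[perm, ])
  tabp <- score_all(MMp, coll, method = "ica", n_perm = 150, seed = 10)
  expect_equal(tabp$scores[rownames(tab$scores), ], tab$scores,
               tolerance = 1e-12)

  # per-set scoring equals jointly cached scoring
  single <- sapply(names(coll$sets), function(nm) {
    sub <- gene_set_collection(coll$sets[nm], coll$universe,
                               size_bounds = coll$size_bounds)
    score_all(MM, sub, method = "ica", n_perm = 150, seed = 10)$scores[, 1]
  })
  expect_equal(unname(single), unname(tab$scores), tolerance = 1e-12)
})

test_that("PCA path: parametric zero at orthogonality and permutation mode runs", {
  sim <- generate_expression(n_genes = 80, n_samples = 160, k = 3,
                             set_size = 10, seed = 46)
  basis <- whiten(sim$X)
  cres <- run_consensus_ica(basis, n_runs = 3, min_match_runs = 2, seed = 2)
  MM <- recompute_mixing(sim$X, cres)
  coll <- planted_collection(sim$truth)
  tab_par <- score_all(MM, coll, method = "pca", basis = basis,
                       seed = 4, p_mode = "parametric")
  expect_true(all(is.finite(tab_par$scores)))
  tab_perm <- score_all(MM, coll, method = "pca", basis = basis,
                        n_perm = 150, seed = 4)
  expect_true(all(is.finite(tab_perm$scores)))

  # parametric Z is 0 when the gene loading row is uncorrelated with the
  # set barcode (r = 0 -> one-sided p = 0.5): orthogonalize a nonmember
  # gene's loading row against the set barcode (iterating, because the
  # Welch barcode itself depends weakly on that row) and rescore it
  g <- tail(rownames(basis$loadings), 1)
  basis2 <- basis
  sub <- gene_set_collection(coll$sets[1], coll$universe,
                             size_bounds = coll$size_bounds)
  for (it in 1:30) {
    bc <- set_barcode(MM, sub$sets[[1]], method = "pca_welch_t",
                      basis = basis2)
    x <- basis2$loadings[g, ]
    bcc <- bc - mean(bc)
    basis2$loadings[g, ] <-
      (x - mean(x)) - sum((x - mean(x)) * bcc) / sum(bcc^2) * bcc
  }
  tab0 <- score_all(MM, sub, method = "pca", basis = basis2, seed = 4,
                    p_mode = "parametric", genes = g)
  expect_lt(abs(tab0$scores[g, 1]), 1e-8)
  # parametric mode never touches the RNG stream
  expect_identical(tab_par$scores,
                   score_all(MM, coll, method = "pca", basis = basis,
                             seed = 99, p_mode = "parametric")$scores)
})

test_that("score tables round-trip through TSV with their JSON sidecar", {
  MM <- random_mixing(20, 5, seed = 47)
  coll <- generate_random_collection(MM$gene_ids, 3, c(4, 6), seed = 1)
  tab <- score_all(MM, coll, method = "ica", n_perm = 120, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_scores(tab, path)
  tab2 <- read_scores(path)
  expect_equal(tab2$scores, tab$scores, tolerance = 1e-12)
  expect_identical(tab2$method_tag, "ica")
  expect_identical(tab2$n_perm, 120L)
})

test_that("null calibration is honest on a structure-free mixing matrix", {
  MM <- random_mixing(150, 10, seed = 48)
  cal <- null_calibration(MM, n_pairs = 300, set_size = 15, n_perm = 300,
                          seed = 6)
  expect_gt(cal$ks_p, 0.01)
  expect_lt(abs(cal$mean_z), 0.15)   # 300 pairs: se of the mean ~ 0.06
})
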