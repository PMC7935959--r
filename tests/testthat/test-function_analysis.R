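test_that("multifunctionality matches the weighted-sum formula", {
  universe <- sprintf("G%03d", 1:100)
  sets <- list(A = universe[1:10], B = universe[c(1, 11:29)])
  coll <- gene_set_collection(sets, universe, size_bounds = c(1, 100))
  mf <- multifunctionality(coll)
  # G001 is in a 10-set and a 20-set over a 100-gene universe
  expect_equal(unname(mf$scores["G001"]), 1 / (10 * 90) + 1 / (20 * 80),
               tolerance = 1e-15)
  expect_identical(unname(mf$scores["G050"]), 0)
  expect_equal(unname(mf$scores), unname(oracle_multifun(sets, universe)),
               tolerance = 1e-15)

  # all genes in one common 50-set: members 1/2500, others 0
  half <- gene_set_collection(list(H = universe[1:50]), universe,
                              size_bounds = c(1, 100))
  mfh <- multifunctionality(half)
  expect_true(all(mfh$scores[universe[1:50]] == 1 / 2500))
  expect_true(all(mfh$scores[universe[51:100]] == 0))

  whole <- gene_set_collection(list(W = universe), universe,
                               size_bounds = c(1, 100))
  expect_error(multifunctionality(whole), "N_out = 0")
})

test_that("multifunctionality is invariant to set and gene order", {
  universe <- sprintf("G%03d", 1:60)
  set.seed(51)
  sets <- lapply(setNames(1:8, paste0("S", 1:8)),
                 function(i) sample(universe, sample(5:20, 1)))
  c1 <- gene_set_collection(sets, universe, size_bounds = c(1, 60))
  c2 <- gene_set_collection(rev(sets), rev(universe), size_bounds = c(1, 60))
  m1 <- multifunctionality(c1)$scores
  m2 <- multifunctionality(c2)$scores
  expect_equal(m1[universe], m2[universe], tolerance = 1e-15)
})

test_that("pan-collection multifunctionality is additive over collections", {
  universe <- sprintf("G%03d", 1:50)
  ca <- gene_set_collection(list(A = universe[1:10]), universe,
                            size_bounds = c(1, 50))
  cb <- gene_set_collection(list(B = universe[5:24]), universe,
                            size_bounds = c(1, 50))
  single <- pan_collection_multifunctionality(list(ca))
  expect_equal(single$scores, multifunctionality(ca)$scores)
  doubled <- pan_collection_multifunctionality(list(ca, ca))
  expect_equal(doubled$scores, 2 * multifunctionality(ca)$scores)
  both <- pan_collection_multifunctionality(list(ca, cb))
  expect_equal(both$scores[universe],
               multifunctionality(ca)$scores[universe] +
                 multifunctionality(cb)$scores[universe])
  cc <- gene_set_collection(list(C = "X1"), c("X1", "X2"),
                            size_bounds = c(1, 2))
  expect_error(pan_collection_multifunctionality(list(ca, cc)),
               "inconsistent")
})

test_that("Mann-Whitney AUC handles separation, identity, ties, and complements", {
  expect_identical(member_nonmember_auc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_identical(member_nonmember_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  expect_equal(member_nonmember_auc(a, b)$auc, oracle_auc(a, b),
               tolerance = 1e-12)

  set.seed(52)
  for (i in 1:20) {
    x <- sample(1:10, 8, replace = TRUE)
    y <- sample(1:10, 5, replace = TRUE)
    res <- member_nonmember_auc(x, y)
    expect_equal(res$auc, oracle_auc(x, y), tolerance = 1e-12)
    expect_identical(res$auc + member_nonmember_auc(y, x)$auc, 1)
    # p agrees with the uncorrected normal-approximation Mann-Whitney test
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(res$p, w$p.value, tolerance = 1e-10)
  }
  expect_error(member_nonmember_auc(numeric(0), 1:3), "non-empty")
})

make_score_table <- function(S, method = "ica", collection = "toy") {
  structure(list(scores = S, method_tag = method,
                 collection_name = collection, n_perm = 100L, seed = 1L,
                 p_mode = "permutation", bandwidth_rule = "silverman"),
            class = "prediction_score_table")
}

test_that("per-set member/nonmember medians match hand computation", {
  S <- matrix(c(3, 4, 0, -1,
                1, 5, 0.5, 0), 4, 2,
              dimnames = list(paste0("G", 1:4), c("SA", "SB")))
  coll <- gene_set_collection(list(SA = c("G1", "G2"), SB = "G2"),
                              paste0("G", 1:4), size_bounds = c(1, 4))
  ev <- evaluate_collection(make_score_table(S), coll)
  expect_equal(ev$per_set$member_median,
               c(median(c(3, 4)), 5))
  # nonmembers of the collection: G3, G4
  expect_equal(ev$per_set$nonmember_median,
               c(median(c(0, -1)), median(c(0.5, 0))))
  expect_true(all(ev$per_set$member_median > ev$per_set$nonmember_median))

  const <- make_score_table(matrix(2, 4, 2,
                                   dimnames = dimnames(S)))
  evc <- evaluate_collection(const, coll)
  expect_true(all(evc$per_set$member_median ==
                    evc$per_set$nonmember_median))
  expect_identical(evc$auc, 0.5)

  all_used <- gene_set_collection(list(SA = paste0("G", 1:2),
                                       SB = paste0("G", 3:4)),
                                  paste0("G", 1:4), size_bounds = c(1, 4))
  expect_error(evaluate_collection(make_score_table(S), all_used),
               "nonmember")
})

test_that("improvement deltas classify sets by sign of the member-median difference", {
  S <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  coll <- gene_set_collection(list(S1 = c("G1", "G2"), S2 = c("G2", "G3"),
                                   S3 = c("G1", "G4")),
                              paste0("G", 1:4), size_bounds = c(1, 4))
  tied <- improvement_delta(make_score_table(S), make_score_table(S), coll)
  expect_true(all(tied$class == "tied"))
  up <- improvement_delta(make_score_table(S + 1), make_score_table(S), coll)
  expect_true(all(up$class == "ica-improved"))
  expect_true(all(abs(up$delta - 1) < 1e-12))
  # hand-computed deltas
  Sp <- S; Sp[, 2] <- Sp[, 2] - 3
  d <- improvement_delta(make_score_table(S), make_score_table(Sp), coll)
  expect_equal(d$delta[d$set == "S2"], 3, tolerance = 1e-12)
})

test_that("version update evaluation isolates the genes added between versions", {
  genes <- paste0("G", 1:10)
  old <- gene_set_collection(list(SA = genes[1:4]), genes,
                             size_bounds = c(1, 10))
  new <- gene_set_collection(list(SA = genes[c(1:4, 9, 10)]), genes,
                             size_bounds = c(1, 10))
  S <- matrix(seq_len(10), 10, 1, dimnames = list(genes, "SA"))
  t_old <- make_score_table(S)
  t_new <- make_score_table(S + 0.5)
  res <- version_update_eval(t_old, t_new, old, new)
  expect_identical(res$set, "SA")
  expect_identical(res$n_updated, 2L)
  expect_equal(res$median_old, median(c(9, 10)))
  expect_equal(res$median_new, median(c(9, 10)) + 0.5)

  expect_warning(empty <- version_update_eval(t_old, t_new, old, old),
                 "no gene set gained")
  expect_identical(nrow(empty), 0L)
})

test_that("multifunctionality association is near zero on structure-free data", {
  # enough genes that the small-sample bias of the distance correlation
  # (O(n^-1/2) for independent data) sits well below the 0.1 bound
  MM <- random_mixing(400, 8, seed = 53)
  coll <- generate_random_collection(MM$gene_ids, n_sets = 8,
                                     size_range = c(10, 25), seed = 4)
  tab <- score_all(MM, coll, method = "ica", n_perm = 200, seed = 9)
  mf <- multifunctionality(coll)
  assoc <- multifunctionality_association(tab, mf)
  expect_true(all(assoc >= 0 & assoc <= 1))
  expect_lt(median(assoc), 0.1)
})
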