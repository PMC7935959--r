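# Synthetic expression data with planted independent sources, known mixing
# structure, and planted gene sets, so every pipeline stage has ground truth.

# Unit-variance Laplace deviates (scale 1/sqrt(2)) by inverse-CDF.
rlaplace_unit <- function(n) {
  u <- stats::runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# Unit-variance two-component Gaussian scale mixture (super-Gaussian):
# sd 2 with probability 0.2, sd 0.5 with probability 0.8.
rmixture_unit <- function(n) {
  wide <- stats::runif(n) < 0.2
  stats::rnorm(n, sd = ifelse(wide, 2, 0.5))
}

#' Generate a synthetic expression matrix with planted structure
#'
#' Builds `X = A S + noise`: `k` independent, unit-variance latent sources
#' (super-Gaussian by default, as independent component estimation
#' requires) mixed into genes through a block-structured mixing matrix `A`.
#' Each block is a planted gene set: its members carry elevated positive
#' loadings on one designated source (drawn uniformly in
#' `loading_block * [0.8, 1.2]`), on top of small dense background loadings
#' (`N(0, background_sd^2)`) that every gene carries on every source.
#' Gaussian measurement noise with standard deviation `noise_sd` is added.
#' Multifunctional genes can be emulated by letting blocks overlap via
#' `overlap`.
#'
#' A `"gaussian"` source distribution is available as a negative control:
#' with Gaussian sources the independent components are not identifiable,
#' so consensus filtering should discard unstable components.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param k number of latent sources; must satisfy
#'   `k <= min(n_genes, n_samples) / 10`.
#' @param source_dist `"laplace"` (default), `"mixture"`, or `"gaussian"`.
#' @param loading_block block loading magnitude (default 1); must exceed
#'   `background_sd`.
#' @param background_sd standard deviation of dense background loadings
#'   (default 0.05).
#' @param noise_sd measurement noise standard deviation (default 0.1).
#' @param set_size genes per planted block (default 20).
#' @param overlap number of genes each block shares with the next
#'   (default 0).
#' @param seed integer seed; the same seed reproduces the data exactly.
#' @return list with `X` (expression matrix, genes x samples) and `truth`
#'   (class `planted_ground_truth`): `true_mixing`, `true_sources`,
#'   `planted_sets` (member ids and designated source column per set),
#'   `noise_sd`, `seed`, and the generator parameters.
#' @export
generate_expression <- function(n_genes = 300L, n_samples = 600L, k = 6L,
                                source_dist = c("laplace", "mixture",
                                                "gaussian"),
                                loading_block = 1, background_sd = 0.05,
                                noise_sd = 0.1, set_size = 20L,
                                overlap = 0L, seed) {
  source_dist <- match.arg(source_dist)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (k < 1L || k > min(n_genes, n_samples) / 10)
    stop("k must satisfy 1 <= k <= min(n_genes, n_samples)/10",
         call. = FALSE)
  if (loading_block <= background_sd)
    stop("loading_block must exceed background_sd", call. = FALSE)
  if (set_size * k - overlap * (k - 1L) > n_genes)
    stop("planted blocks do not fit into n_genes", call. = FALSE)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  with_seed(seed, {
    S <- matrix(switch(source_dist,
                       laplace = rlaplace_unit(k * n_samples),
                       mixture = rmixture_unit(k * n_samples),
                       gaussian = stats::rnorm(k * n_samples)),
                k, n_samples)
    A <- matrix(stats::rnorm(n_genes * k, sd = background_sd), n_genes, k)
    planted <- list()
    start <- 1L
    for (j in seq_len(k)) {
      idx <- start:(start + set_size - 1L)
      A[idx, j] <- stats::runif(set_size, 0.8, 1.2) * loading_block
      planted[[paste0("SET", j)]] <- list(members = gene_ids[idx],
                                          column = j)
      start <- start + set_size - overlap
    }
    X <- A %*% S
    if (noise_sd > 0)
      X <- X + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                      n_genes, n_samples)
    dimnames(X) <- list(gene_ids, sample_ids)
    dimnames(A) <- list(gene_ids, paste0("SRC", seq_len(k)))
    dimnames(S) <- list(paste0("SRC", seq_len(k)), sample_ids)
    truth <- structure(list(true_mixing = A, true_sources = S,
                            planted_sets = planted, noise_sd = noise_sd,
                            seed = seed,
                            params = list(n_genes = n_genes,
                                          n_samples = n_samples, k = k,
                                          source_dist = source_dist,
                                          loading_block = loading_block,
                                          background_sd = background_sd,
                                          set_size = set_size,
                                          overlap = overlap)),
                       class = "planted_ground_truth")
    list(X = X, truth = truth)
  })
}

#' Planted gene sets as a collection
#'
#' Wraps the planted blocks of a [generate_expression()] ground truth as a
#' [gene_set_collection()] over the full gene universe, ready for scoring.
#'
#' @param truth a `planted_ground_truth`.
#' @param name collection label.
#' @return a `gene_set_collection`.
#' @export
planted_collection <- function(truth, name = "planted") {
  stopifnot(inherits(truth, "planted_ground_truth"))
  sets <- lapply(truth$planted_sets, `[[`, "members")
  sizes <- range(lengths(sets))
  gene_set_collection(sets, universe = rownames(truth$true_mixing),
                      name = name, size_bounds = sizes)
}

#' Simulated annotation-update experiment
#'
#' Emulates a gene set collection version update on synthetic data with
#' known ground truth. In each replicate a planted expression matrix is
#' generated and decomposed; the first planted set is then annotated in an
#' "old" version containing only a fraction (`keep_fraction`) of its true
#' members and a "new" version containing all of them. The held-out true
#' members (the "updated members") are scored against the set under both
#' versions of the barcode. A method that exploits updated membership
#' information should score the updated members at least as high under the
#' fuller (new-version) barcode.
#'
#' @param n_replicates number of independent replicates (default 20).
#' @param n_genes,n_samples,k,set_size,noise_sd generator settings for each
#'   replicate (see [generate_expression()]).
#' @param keep_fraction fraction of true members present in the old
#'   version (default 0.6).
#' @param n_runs,min_match_runs consensus ICA restarts per replicate.
#' @param n_perm permutations per null.
#' @param method `"ica"` or `"pca"` scoring path.
#' @param seed integer seed; replicate seeds derive from it.
#' @return data frame with one row per replicate: `median_old`,
#'   `median_new` (updated members' median Z under each barcode version),
#'   and `improved` (`median_new >= median_old`).
#' @export
simulate_version_update <- function(n_replicates = 20L, n_genes = 150L,
                                    n_samples = 300L, k = 4L,
                                    set_size = 20L, noise_sd = 0.1,
                                    keep_fraction = 0.6, n_runs = 5L,
                                    min_match_runs = 3L, n_perm = 300L,
                                    method = c("ica", "pca"), seed) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, 100L, r)
    sim <- generate_expression(n_genes = n_genes, n_samples = n_samples,
                               k = k, set_size = set_size,
                               noise_sd = noise_sd, seed = rep_seed)
    basis <- whiten(sim$X)
    cres <- run_consensus_ica(basis, n_runs = n_runs,
                              min_match_runs = min_match_runs,
                              seed = derive_seed(rep_seed, 1L))
    MM <- recompute_mixing(sim$X, cres)
    members <- sim$truth$planted_sets[[1L]]$members
    n_old <- max(2L, ceiling(keep_fraction * length(members)))
    old_members <- members[seq_len(n_old)]
    updated <- setdiff(members, old_members)
    universe <- rownames(sim$X)
    bounds <- c(min(n_old, length(members)), max(n_old, length(members)))
    coll_old <- gene_set_collection(list(SET1 = old_members), universe,
                                    name = "old", size_bounds = bounds)
    coll_new <- gene_set_collection(list(SET1 = members), universe,
                                    name = "new", size_bounds = bounds)
    score_seed <- derive_seed(rep_seed, 2L)
    t_old <- score_all(MM, coll_old, method = method, basis = basis,
                       n_perm = n_perm, seed = score_seed, genes = updated)
    t_new <- score_all(MM, coll_new, method = method, basis = basis,
                       n_perm = n_perm, seed = score_seed, genes = updated)
    vu <- version_update_eval(t_old, t_new, coll_old, coll_new)
    rows[[r]] <- data.frame(replicate = r,
                            n_updated = vu$n_updated[1L],
                            median_old = vu$median_old[1L],
                            median_new = vu$median_new[1L])
  }
  out <- do.call(rbind, rows)
  out$improved <- out$median_new >= out$median_old
  out
}

#' Generate a structure-free random gene set collection
#'
#' Uniform random memberships over a universe: set sizes are drawn
#' uniformly from `size_range` and members uniformly without replacement.
#' Used as a null collection for calibration tests.
#'
#' @param universe gene identifiers.
#' @param n_sets number of sets (0 gives an empty collection).
#' @param size_range inclusive integer range of set sizes.
#' @param seed integer seed.
#' @param name collection label.
#' @return a `gene_set_collection`.
#' @export
generate_random_collection <- function(universe, n_sets,
                                       size_range = c(10L, 50L), seed,
                                       name = "random") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (size_range[1L] < 1L || size_range[2L] > length(universe))
    stop("size_range must lie within [1, length(universe)]", call. = FALSE)
  with_seed(seed, {
    sets <- list()
    if (n_sets > 0L) {
      sizes <- sample(seq(size_range[1L], size_range[2L]), n_sets,
                      replace = TRUE)
      sets <- lapply(sizes, function(s) sample(universe, s))
      names(sets) <- sprintf("RAND%04d", seq_len(n_sets))
    }
    gene_set_collection(sets, universe = universe, name = name,
                        size_bounds = size_range)
  })
}
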