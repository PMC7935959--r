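# Transcriptional regulatory barcodes, distance-correlation similarity,
# KDE-smoothed permutation nulls, and gene x gene-set prediction scores.

# ---- distance correlation (V-statistic) ------------------------------------

# Double-centered absolute-difference matrix of a numeric vector.
dc_center <- function(x) {
  d <- abs(outer(x, x, "-"))
  rm <- rowMeans(d)
  d - outer(rm, rm, "+") + mean(d)
}

#' Sample distance correlation of two vectors
#'
#' The classical (biased, V-statistic) sample distance correlation:
#' pairwise absolute-difference matrices of `x` and `y` are double-centered
#' and the normalized inner product of the centered matrices is returned.
#' It lies in \[0, 1\], is zero (in the population) iff the variables are
#' independent, and is sensitive to nonlinear association. Degenerate input
#' (zero distance variance, e.g. a constant vector) returns 0 by convention.
#'
#' @param x,y numeric vectors of equal length, at least 2.
#' @return distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  stopifnot_finite(x, "x"); stopifnot_finite(y, "y")
  A <- dc_center(x)
  B <- dc_center(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  dcov2 <- max(mean(A * B), 0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# Distance correlation of a fixed vector x against each row of matrix Y,
# vectorized over rows. Workhorse of the permutation null.
#
# Uses the identity that the inner product of a double-centered matrix with
# any matrix equals its inner product with the raw distance matrix (row and
# column sums of the centered matrix vanish), so only the upper-triangular
# pairwise distances of each row of Y are ever materialized — one
# n_perm x n_pairs block and a single matrix product.
dcor_profile <- function(x, Y) {
  k <- length(x)
  m <- nrow(Y)
  A <- dc_center(x)
  dvx <- mean(A * A)
  if (dvx <= 0) return(numeric(m))
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  P <- abs(Y[, pairs[, 1L], drop = FALSE] - Y[, pairs[, 2L], drop = FALSE])
  RS <- matrix(0, m, k)                       # row sums of each distance matrix
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    RS[, i] <- RS[, i] + P[, p]
    RS[, j] <- RS[, j] + P[, p]
  }
  g <- rowSums(RS) / k^2                      # grand means
  sumD2 <- 2 * rowSums(P^2)
  dvy <- (sumD2 - 2 * rowSums(RS^2) / k + k^2 * g^2) / k^2
  dcov2 <- as.vector(P %*% (2 * A[upper.tri(A)])) / k^2
  out <- numeric(m)
  ok <- dvy > 0
  out[ok] <- sqrt(pmax(dcov2[ok], 0) / sqrt(dvx * dvy[ok]))
  pmin(out, 1)
}

# Pairwise distance-correlation matrix between the rows of M.
# Each row's centered matrix is flattened once, after which all pairwise
# dCov^2 values are a single cross-product.
dcor_matrix <- function(M) {
  n <- nrow(M)
  k <- ncol(M)
  flat <- t(vapply(seq_len(n), function(i) as.vector(dc_center(M[i, ])),
                   numeric(k * k)))
  G <- tcrossprod(flat) / (k * k)     # dCov^2 for every pair
  dv <- diag(G)
  denom <- sqrt(outer(dv, dv))
  R <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  ok <- denom > 0
  R[ok] <- sqrt(pmax(G[ok], 0) / denom[ok])
  R[R > 1] <- 1
  diag(R)[dv > 0] <- 1
  R
}

# ---- barcodes --------------------------------------------------------------

#' Transcriptional regulatory barcode of a gene set
#'
#' A gene's barcode is its row of the mixing matrix. For a gene set the
#' barcode is built in one of two ways:
#' \describe{
#'   \item{`ica_mean`}{component-wise mean of the member genes' mixing
#'     weights (the independent-component path).}
#'   \item{`pca_welch_t`}{per-component Welch T statistic comparing member
#'     genes' principal-axis loadings against all nonmember genes' loadings
#'     (the PCA comparator path, as used by eigenvector-based
#'     guilt-by-association methods). Requires `basis`.}
#' }
#'
#' @param MM a [recompute_mixing()] result.
#' @param members character vector of member gene ids.
#' @param method `"ica_mean"` or `"pca_welch_t"`.
#' @param basis [whiten()] result; required for `pca_welch_t`.
#' @return named numeric vector over components, with attribute `origin`.
#' @export
set_barcode <- function(MM, members, method = c("ica_mean", "pca_welch_t"),
                        basis = NULL) {
  method <- match.arg(method)
  if (method == "ica_mean") {
    W <- MM$weights
    unknown <- setdiff(members, rownames(W))
    if (length(unknown))
      stop("unknown gene id(s): ", paste(utils::head(unknown, 5L),
                                         collapse = ", "), call. = FALSE)
    if (length(members) < 1L) stop("need at least one member", call. = FALSE)
    bc <- colMeans(W[members, , drop = FALSE])
    attr(bc, "origin") <- "set-mean"
  } else {
    if (is.null(basis)) stop("pca_welch_t needs the whitened basis",
                             call. = FALSE)
    L <- basis$loadings
    unknown <- setdiff(members, rownames(L))
    if (length(unknown))
      stop("unknown gene id(s): ", paste(utils::head(unknown, 5L),
                                         collapse = ", "), call. = FALSE)
    bc <- welch_t_barcode(L, rownames(L) %in% members)
    attr(bc, "origin") <- "set-welch-t"
  }
  bc
}

# Vectorized per-column Welch T statistic, member rows vs nonmember rows.
welch_t_barcode <- function(L, is_member) {
  n1 <- sum(is_member)
  n2 <- sum(!is_member)
  if (n1 < 2L || n2 < 2L)
    stop("Welch T barcode needs >= 2 members and >= 2 nonmembers",
         call. = FALSE)
  M1 <- L[is_member, , drop = FALSE]
  M2 <- L[!is_member, , drop = FALSE]
  m1 <- colMeans(M1); m2 <- colMeans(M2)
  v1 <- colSums(sweep(M1, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(M2, 2L, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  if (any(se2 == 0)) {
    warning("zero-variance component(s) in Welch T barcode set to 0",
            call. = FALSE)
    t[se2 == 0] <- 0
  }
  t
}

# Welch T barcode from precomputed totals: colSums/colSums of squares over
# all genes, and the member submatrix. Avoids touching all nonmember rows in
# every permutation.
welch_t_from_totals <- function(M1, tot_sum, tot_sumsq, n_total) {
  n1 <- nrow(M1)
  n2 <- n_total - n1
  s1 <- colSums(M1)
  q1 <- colSums(M1^2)
  m1 <- s1 / n1
  m2 <- (tot_sum - s1) / n2
  v1 <- pmax(q1 - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax((tot_sumsq - q1) - n2 * m2^2, 0) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  t[se2 == 0] <- 0
  t
}

# ---- permutation null + KDE tail ------------------------------------------

#' Permutation null distribution for one gene and one set size
#'
#' Draws `n_perm` random gene sets of the given size uniformly without
#' replacement from the mixing-matrix gene universe, builds each random
#' set's barcode, and records its similarity to the query gene's profile
#' (distance correlation on the ICA path, Pearson correlation on the PCA
#' path). A Gaussian kernel density estimator with Silverman's
#' rule-of-thumb bandwidth is fitted to the samples; tail probabilities are
#' later read off the analytic mixture, so they are smooth and never
#' exactly 0 or 1.
#'
#' The null depends only on the query gene and the set size, never on the
#' actual membership, so it can be cached across all sets of one size.
#'
#' @param gene_profile the query gene's barcode (ICA path: mixing-matrix
#'   row) or loading row (PCA path).
#' @param MM [recompute_mixing()] result supplying the gene universe.
#' @param set_size size of the random sets.
#' @param n_perm number of permutations, at least 100 (default 1000).
#' @param seed integer seed for the draw.
#' @param method `"ica"` or `"pca"`.
#' @param basis whitened basis, required for the PCA path.
#' @return object of class `null_distribution`: list with `samples`,
#'   `kde_bandwidth`, `n_perm`, `set_size`, `seed`, `statistic`.
#' @export
build_null <- function(gene_profile, MM, set_size, n_perm = 1000L, seed,
                       method = c("ica", "pca"), basis = NULL) {
  method <- match.arg(method)
  if (n_perm < 100L)
    stop("n_perm must be at least 100 (tail too unstable below)",
         call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  W <- if (method == "ica") MM$weights else basis$loadings
  n_genes <- nrow(W)
  if (set_size < 1L || set_size > n_genes)
    stop("set_size must be in [1, number of genes]", call. = FALSE)
  # draw over the id-sorted gene order, so the same seed picks the same
  # gene identities whatever the row order of the mixing matrix
  canon <- order(rownames(W))
  idx <- with_seed(seed, replicate(n_perm,
                                   canon[sample.int(n_genes, set_size)],
                                   simplify = FALSE))
  if (method == "ica") {
    B <- rowsum(W[unlist(idx), , drop = FALSE],
                group = rep(seq_len(n_perm), each = set_size),
                reorder = FALSE) / set_size
    samples <- dcor_profile(as.numeric(gene_profile), B)
  } else {
    tot_sum <- colSums(W)
    tot_sumsq <- colSums(W^2)
    x <- as.numeric(gene_profile)
    samples <- vapply(idx, function(i) {
      b <- welch_t_from_totals(W[i, , drop = FALSE], tot_sum, tot_sumsq,
                               n_genes)
      r <- suppressWarnings(stats::cor(x, b))
      if (is.na(r)) 0 else r
    }, numeric(1L))
  }
  bw <- tryCatch(stats::bw.nrd0(samples), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0)
    bw <- max(abs(samples[1L]) * 1e-8, 1e-8)   # degenerate null
  structure(list(samples = samples, kde_bandwidth = bw,
                 n_perm = as.integer(n_perm), set_size = as.integer(set_size),
                 seed = seed, statistic = if (method == "ica") "dcor"
                 else "pearson"),
            class = "null_distribution")
}

#' Prediction score: KDE tail probability transformed to a Z-score
#'
#' The p-value is the survival probability of the observed similarity under
#' the Gaussian-mixture density implied by the KDE (each null sample
#' contributes a Gaussian of the fitted bandwidth), evaluated analytically
#' rather than by counting. The prediction score is the standard-normal
#' quantile `Z = qnorm(1 - p)`: strictly increasing in the observed
#' statistic and finite for any finite input.
#'
#' @param observed observed similarity statistic(s); vectorized.
#' @param null a [build_null()] result.
#' @return numeric Z-score(s), same length as `observed`.
#' @export
prediction_score <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  p <- kde_tail_p(observed, null$samples, null$kde_bandwidth)
  stats::qnorm(p, lower.tail = FALSE)
}

# Analytic survival function of the KDE mixture, clamped away from 0 and 1
# so the normal quantile stays finite.
kde_tail_p <- function(observed, samples, bw) {
  p <- vapply(observed, function(o)
    mean(stats::pnorm(o, mean = samples, sd = bw, lower.tail = FALSE)),
    numeric(1L))
  pmin(pmax(p, 1e-300), 1 - 1e-16)
}

#' Calibration of the permutation null on a given mixing matrix
#'
#' Scores `n_pairs` independent (gene, random set) pairs: pair `i` takes
#' gene `i` (cycling through the mixing-matrix universe) and a freshly
#' drawn random set of `set_size` genes, computes the observed similarity,
#' and converts it to a p-value and Z-score under the gene's permutation
#' null. On a structure-free mixing matrix (e.g. i.i.d. Gaussian weights)
#' the p-values must be uniform on (0, 1) and the Z-scores centered at
#' zero; systematic deviation reveals miscalibration of the null or of the
#' KDE tail. Each pair uses its own random set, so pairs are independent
#' up to reuse of one cached null per gene.
#'
#' @param MM a `mixing_matrix`.
#' @param n_pairs number of (gene, set) pairs (default 2000).
#' @param set_size random set size (default 20).
#' @param n_perm permutations per null (default 1000).
#' @param seed integer seed.
#' @param method `"ica"` or `"pca"`; `basis` as in [score_all()].
#' @param basis whitened basis for the PCA path.
#' @return list with `p` (p-values), `z` (Z-scores), `mean_z`, and
#'   `ks_p` (Kolmogorov-Smirnov uniformity p-value).
#' @export
null_calibration <- function(MM, n_pairs = 2000L, set_size = 20L,
                             n_perm = 1000L, seed,
                             method = c("ica", "pca"), basis = NULL) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  W <- if (method == "ica") MM$weights else basis$loadings
  n_genes <- nrow(W)
  nulls <- vector("list", n_genes)
  p <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    gi <- (i - 1L) %% n_genes + 1L
    x <- W[gi, ]
    if (is.null(nulls[[gi]]))
      nulls[[gi]] <- build_null(x, MM, set_size, n_perm = n_perm,
                                seed = derive_seed(seed, gi, set_size),
                                method = method, basis = basis)
    members <- with_seed(derive_seed(seed, 2L, i),
                         sample.int(n_genes, set_size))
    if (method == "ica") {
      bc <- colMeans(W[members, , drop = FALSE])
      obs <- distance_correlation(x, bc)
    } else {
      is_mem <- logical(n_genes); is_mem[members] <- TRUE
      bc <- welch_t_barcode(W, is_mem)
      obs <- suppressWarnings(stats::cor(x, bc))
      if (is.na(obs)) obs <- 0
    }
    p[i] <- kde_tail_p(obs, nulls[[gi]]$samples,
                       nulls[[gi]]$kde_bandwidth)
  }
  z <- stats::qnorm(p, lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(p = p, z = z, mean_z = mean(z), ks_p = ks$p.value)
}

# ---- full score table ------------------------------------------------------

#' Score every gene against every gene set
#'
#' For each (gene, set) pair the observed similarity between the gene's
#' profile and the set's barcode is compared against a permutation null for
#' that gene and set size, and the tail probability is expressed as a
#' Z-score (the prediction score). Two method paths are available:
#' \describe{
#'   \item{`ica`}{gene barcode = mixing-matrix row; set barcode = member
#'     mean; similarity = distance correlation; permutation p-values.}
#'   \item{`pca`}{gene profile = principal-axis loading row; set barcode =
#'     per-component Welch T; similarity = Pearson correlation; p-values
#'     from permutation (default, comparable to the ICA path) or from the
#'     parametric one-sided correlation test (`p_mode = "parametric"`).}
#' }
#' Permutation nulls are cached per (gene, set size) with seeds derived
#' deterministically from the global seed, a hash of the gene identifier,
#' and the set size — so results depend neither on how sets are grouped nor
#' on the order of gene rows.
#'
#' @param MM [recompute_mixing()] result.
#' @param collection [gene_set_collection()] harmonized to the mixing-matrix
#'   gene universe.
#' @param method `"ica"` or `"pca"`.
#' @param basis whitened basis (required for `method = "pca"`).
#' @param n_perm permutations per null (default 1000).
#' @param seed integer seed.
#' @param p_mode `"permutation"` or `"parametric"` (PCA path only).
#' @param genes optional subset of gene ids to score (rows of the result);
#'   nulls are still drawn from the full universe.
#' @param leave_one_out if `TRUE`, a member gene's own weight is removed
#'   from its set's barcode before computing the observed similarity
#'   (sensitivity analysis; the default keeps members in, and nulls always
#'   use the nominal set size).
#' @return object of class `prediction_score_table`: list with `scores`
#'   (genes x sets Z-score matrix), `method_tag`, `collection_name`, and
#'   provenance (`n_perm`, `seed`, `p_mode`, `bandwidth_rule`).
#' @export
score_all <- function(MM, collection, method = c("ica", "pca"), basis = NULL,
                      n_perm = 1000L, seed,
                      p_mode = c("permutation", "parametric"),
                      genes = NULL, leave_one_out = FALSE) {
  method <- match.arg(method)
  p_mode <- match.arg(p_mode)
  stopifnot(inherits(MM, "mixing_matrix"),
            inherits(collection, "gene_set_collection"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!length(collection$sets)) stop("empty gene set collection",
                                     call. = FALSE)
  if (p_mode == "parametric" && method != "pca")
    stop("parametric p-values are only defined for the PCA path",
         call. = FALSE)
  if (method == "pca" && is.null(basis))
    stop("the PCA path needs the whitened basis", call. = FALSE)
  P <- if (method == "ica") MM$weights else basis$loadings
  bad <- unlist(lapply(collection$sets, setdiff, y = rownames(P)),
                use.names = FALSE)
  if (length(bad))
    stop("collection is not harmonized to the mixing-matrix universe; ",
         "unknown gene(s): ", paste(utils::head(unique(bad), 5L),
                                    collapse = ", "), call. = FALSE)
  if (is.null(genes)) genes <- rownames(P)
  if (!all(genes %in% rownames(P)))
    stop("unknown gene id(s) in 'genes'", call. = FALSE)

  set_names <- names(collection$sets)
  barcodes <- lapply(collection$sets, set_barcode, MM = MM,
                     method = if (method == "ica") "ica_mean"
                     else "pca_welch_t", basis = basis)
  sizes <- lengths(collection$sets)
  Z <- matrix(NA_real_, length(genes), length(set_names),
              dimnames = list(genes, set_names))

  if (p_mode == "parametric") {
    k <- ncol(P)
    df <- k - 2L
    if (df < 1L) stop("parametric p-values need at least 3 components",
                      call. = FALSE)
    for (g in genes) {
      x <- P[g, ]
      for (s in set_names) {
        r <- suppressWarnings(stats::cor(x, barcodes[[s]]))
        if (is.na(r)) r <- 0
        r <- max(min(r, 1 - 1e-15), -1 + 1e-15)
        tstat <- r * sqrt(df / (1 - r^2))
        p <- stats::pt(tstat, df, lower.tail = FALSE)
        Z[g, s] <- stats::qnorm(p, lower.tail = FALSE)
      }
    }
  } else {
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      x <- P[g, ]
      nulls <- list()
      for (s in set_names) {
        sz <- sizes[[s]]
        key <- as.character(sz)
        if (is.null(nulls[[key]]))
          nulls[[key]] <- build_null(x, MM, sz, n_perm = n_perm,
                                     seed = derive_seed(seed,
                                                        gene_tag(g), sz),
                                     method = method, basis = basis)
        bc <- barcodes[[s]]
        if (leave_one_out && g %in% collection$sets[[s]] &&
            method == "ica" && sizes[[s]] > 1L) {
          others <- setdiff(collection$sets[[s]], g)
          bc <- colMeans(MM$weights[others, , drop = FALSE])
        }
        obs <- if (method == "ica") distance_correlation(x, as.numeric(bc))
        else {
          r <- suppressWarnings(stats::cor(x, as.numeric(bc)))
          if (is.na(r)) 0 else r
        }
        Z[g, s] <- prediction_score(obs, nulls[[key]])
      }
    }
  }
  structure(list(scores = Z, method_tag = method,
                 collection_name = collection$name,
                 n_perm = if (p_mode == "permutation") as.integer(n_perm)
                 else NA_integer_,
                 seed = seed, p_mode = p_mode,
                 bandwidth_rule = "silverman"),
            class = "prediction_score_table")
}

#' @export
print.prediction_score_table <- function(x, ...) {
  cat(sprintf(
    "Prediction scores (%s path, %s p): %d genes x %d sets, collection '%s'\n",
    x$method_tag, x$p_mode, nrow(x$scores), ncol(x$scores),
    x$collection_name))
  invisible(x)
}

#' Write / read a prediction score table
#'
#' Scores are written as a genes x sets TSV; method, permutation count,
#' seed, bandwidth rule, and collection provenance go into a JSON sidecar
#' at `<path>.json`.
#'
#' @param tab a `prediction_score_table`.
#' @param path TSV path.
#' @param extra named list merged into the JSON sidecar (e.g. a pipeline
#'   configuration hash).
#' @rdname score_io
#' @export
write_scores <- function(tab, path, extra = NULL) {
  stopifnot(inherits(tab, "prediction_score_table"))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(paste(c("gene_id", colnames(tab$scores)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(tab$scores)), function(i)
    paste(c(rownames(tab$scores)[i],
            format(tab$scores[i, ], digits = 17, trim = TRUE)),
          collapse = "\t"), character(1L))
  writeLines(body, con)
  close(con)
  meta <- c(list(method = tab$method_tag, collection = tab$collection_name,
                 n_perm = tab$n_perm, seed = tab$seed, p_mode = tab$p_mode,
                 bandwidth_rule = tab$bandwidth_rule), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname score_io
#' @export
read_scores <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  genes <- vapply(fields, `[[`, character(1L), 1L)
  S <- t(vapply(fields, function(f) as.numeric(f[-1L]),
                numeric(length(header) - 1L)))
  dimnames(S) <- list(genes, header[-1L])
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  else list()
  structure(list(scores = S,
                 method_tag = meta$method %||% "unknown",
                 collection_name = meta$collection %||% "unknown",
                 n_perm = meta$n_perm %||% NA_integer_,
                 seed = meta$seed %||% NA_integer_,
                 p_mode = meta$p_mode %||% "permutation",
                 bandwidth_rule = meta$bandwidth_rule %||% "silverman"),
            class = "prediction_score_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
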