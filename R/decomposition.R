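# PCA whitening of the gene covariance, multi-restart FastICA, consensus
# component matching with credibility filtering, and mixing-matrix
# recomputation.

#' Whiten an expression matrix by PCA on the gene covariance
#'
#' The observed variables are the genes. Each gene is centered across
#' samples, the gene-gene covariance is eigendecomposed (via the SVD of the
#' centered matrix), and the smallest number of leading principal axes whose
#' cumulative explained-variance fraction reaches `var_threshold` is
#' retained. The retained axes give decorrelated, unit-variance whitened
#' variables that feed independent component analysis; they are also the
#' transcriptional components of the PCA comparator path.
#'
#' Eigenvector signs are fixed so that the largest-magnitude gene loading of
#' each axis is positive, which makes the basis deterministic and invariant
#' (up to row permutation) to gene ordering.
#'
#' @param X expression matrix (genes x samples).
#' @param var_threshold fraction of total variance to retain, in (0, 1];
#'   default 0.90.
#' @return an object of class `whitened_basis` with elements:
#'   \describe{
#'     \item{loadings}{genes x n_pc orthonormal matrix of principal axes;
#'       row `g` is gene `g`'s profile over the whitened variables.}
#'     \item{explained_fraction}{variance fraction of each retained axis.}
#'     \item{whitened}{n_pc x samples matrix; rows have zero mean and unit
#'       variance and are mutually uncorrelated.}
#'     \item{eigenvalues}{full positive eigenvalue spectrum of the gene
#'       covariance.}
#'     \item{var_threshold}{the threshold applied.}
#'   }
#' @export
whiten <- function(X, var_threshold = 0.90) {
  validate_expression(X)
  if (!is.numeric(var_threshold) || length(var_threshold) != 1L ||
      var_threshold <= 0 || var_threshold > 1)
    stop("var_threshold must be in (0, 1]", call. = FALSE)
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)                      # gene-covariance eigenvalues
  pos <- eig > max(eig[1L], 0) * 1e-12
  if (!any(pos)) stop("expression matrix has rank 0 after centering",
                      call. = FALSE)
  eig <- eig[pos]
  frac <- eig / sum(eig)
  cum <- cumsum(frac)
  n_pc <- which(cum >= var_threshold - 1e-12)[1L]
  U <- sv$u[, seq_len(n_pc), drop = FALSE]
  V <- sv$v[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {                   # deterministic sign convention
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  Z <- sqrt(n - 1) * t(V)                      # unit-variance whitened rows
  pc_ids <- paste0("PC", seq_len(n_pc))
  dimnames(U) <- list(rownames(X), pc_ids)
  dimnames(Z) <- list(pc_ids, colnames(X))
  structure(list(loadings = U, explained_fraction = frac[seq_len(n_pc)],
                 whitened = Z, eigenvalues = eig,
                 var_threshold = var_threshold),
            class = "whitened_basis")
}

#' @export
print.whitened_basis <- function(x, ...) {
  cat(sprintf("Whitened basis: %d axes over %d genes, %.1f%% variance retained (threshold %.0f%%)\n",
              ncol(x$loadings), nrow(x$loadings),
              100 * sum(x$explained_fraction), 100 * x$var_threshold))
  invisible(x)
}

# One FastICA run (fixed-point, log-cosh contrast, symmetric/parallel
# extraction) on an already-whitened matrix Z (variables x samples).
# Returns the estimated source matrix (n_comp x samples) and a convergence
# flag. Deflation mode extracts components one at a time.
fastica_run <- function(Z, n_comp, seed, fun_alpha = 1, max_iter = 200L,
                        tol = 1e-6, mode = c("parallel", "deflation")) {
  mode <- match.arg(mode)
  n_pc <- nrow(Z)
  n <- ncol(Z)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                       nrow = length(e$values)) %*% t(e$vectors) %*% W
  }
  W0 <- with_seed(seed, matrix(stats::rnorm(n_comp * n_pc), n_comp, n_pc))
  converged <- TRUE
  if (mode == "parallel") {
    W <- sym_decorrelate(W0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      U <- W %*% Z
      G <- tanh(fun_alpha * U)
      gprime <- fun_alpha * rowMeans(1 - G^2)
      W_new <- (G %*% t(Z)) / n - gprime * W
      W_new <- sym_decorrelate(W_new)
      delta <- max(abs(abs(rowSums(W_new * W)) - 1))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
    }
  } else {
    W <- matrix(0, n_comp, n_pc)
    for (p in seq_len(n_comp)) {
      w <- W0[p, ]
      if (p > 1L) {
        proj <- t(W[seq_len(p - 1L), , drop = FALSE]) %*%
          (W[seq_len(p - 1L), , drop = FALSE] %*% w)
        w <- w - as.vector(proj)
      }
      w <- w / sqrt(sum(w^2))
      comp_ok <- FALSE
      for (it in seq_len(max_iter)) {
        u <- as.vector(w %*% Z)
        g <- tanh(fun_alpha * u)
        w_new <- as.vector(Z %*% g) / n - fun_alpha * mean(1 - g^2) * w
        if (p > 1L) {
          proj <- t(W[seq_len(p - 1L), , drop = FALSE]) %*%
            (W[seq_len(p - 1L), , drop = FALSE] %*% w_new)
          w_new <- w_new - as.vector(proj)
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        delta <- abs(abs(sum(w_new * w)) - 1)
        w <- w_new
        if (delta < tol) { comp_ok <- TRUE; break }
      }
      if (!comp_ok) converged <- FALSE
      W[p, ] <- w
    }
  }
  list(S = W %*% Z, W = W, converged = converged)
}

#' Match independent components across restarts into consensus clusters
#'
#' Components from successive runs are matched greedily one-to-one against
#' the clusters seeded by earlier runs: a run component joins the existing
#' cluster with which its absolute Pearson correlation (across samples) is
#' highest, provided it exceeds `match_r`; each cluster accepts at most one
#' component per run, and unmatched components seed new clusters. Within a
#' run, components are considered in descending variance order (ties by
#' index). A cluster's credibility index is the fraction of runs it covers;
#' clusters spanning fewer than `min_match_runs` runs are dropped.
#'
#' The consensus component of a retained cluster is the sign-aligned mean of
#' its members, rescaled to unit variance.
#'
#' @param run_sources list of per-run source matrices (components x samples);
#'   entries may be `NULL` for non-convergent runs, which still count in the
#'   credibility denominator.
#' @param n_runs total number of runs attempted.
#' @param match_r absolute-correlation threshold for matching (default 0.98).
#' @param min_match_runs minimum run coverage to retain a cluster
#'   (default 13).
#' @return list with `sources` (retained consensus components x samples),
#'   `credibility` (per retained component), and `report` (a
#'   `consensus_report` list with per-run counts, cluster coverage, and drop
#'   statistics).
#' @export
consensus_match <- function(run_sources, n_runs = length(run_sources),
                            match_r = 0.98, min_match_runs = 13L) {
  stopifnot(n_runs >= 1L, min_match_runs >= 1L, min_match_runs <= n_runs)
  members <- list()     # per cluster: matrix of sign-aligned member sources
  runs_in <- list()     # per cluster: integer vector of contributing runs
  reps <- NULL          # cluster representatives (seed members), rows
  for (r in seq_along(run_sources)) {
    S <- run_sources[[r]]
    if (is.null(S)) next
    ord <- order(-apply(S, 1L, stats::var), seq_len(nrow(S)))
    S <- S[ord, , drop = FALSE]
    matched <- rep(NA_integer_, nrow(S))   # cluster index per component
    signs <- rep(1, nrow(S))
    if (length(members)) {
      R <- suppressWarnings(stats::cor(t(reps), t(S)))
      R[is.na(R)] <- 0
      A <- abs(R)
      repeat {
        mx <- max(A)
        if (mx <= match_r) break
        idx <- which(A == mx, arr.ind = TRUE)[1L, ]
        matched[idx[2L]] <- idx[1L]
        signs[idx[2L]] <- sign(R[idx[1L], idx[2L]])
        A[idx[1L], ] <- -Inf
        A[, idx[2L]] <- -Inf
      }
    }
    for (j in seq_len(nrow(S))) {
      if (is.na(matched[j])) {             # seed a new cluster
        members[[length(members) + 1L]] <- S[j, , drop = FALSE]
        runs_in[[length(runs_in) + 1L]] <- r
        reps <- rbind(reps, S[j, , drop = FALSE])
      } else {
        ci <- matched[j]
        members[[ci]] <- rbind(members[[ci]], signs[j] * S[j, , drop = FALSE])
        runs_in[[ci]] <- c(runs_in[[ci]], r)
      }
    }
  }
  if (!length(members))
    stop("consensus matching received no converged runs", call. = FALSE)
  coverage <- lengths(lapply(runs_in, unique))
  credibility <- coverage / n_runs
  keep <- coverage >= min_match_runs
  report <- structure(list(
    n_runs = as.integer(n_runs),
    converged_runs = sum(!vapply(run_sources, is.null, logical(1L))),
    per_run_components = vapply(run_sources, function(s)
      if (is.null(s)) NA_integer_ else nrow(s), integer(1L)),
    cluster_coverage = coverage,
    credibility = credibility[keep],
    n_clusters = length(members),
    n_retained = sum(keep),
    n_dropped = sum(!keep)), class = "consensus_report")
  if (!any(keep)) {
    err <- simpleError(sprintf(
      "no consensus component reached min_match_runs = %d (best coverage %d of %d runs)",
      min_match_runs, max(coverage), n_runs))
    err$report <- report
    stop(err)
  }
  S_cons <- do.call(rbind, lapply(which(keep), function(ci) {
    m <- colMeans(members[[ci]])
    m / stats::sd(m)
  }))
  rownames(S_cons) <- paste0("TC", seq_len(nrow(S_cons)))
  colnames(S_cons) <- colnames(run_sources[[which(
    !vapply(run_sources, is.null, logical(1L)))[1L]]])
  list(sources = S_cons, credibility = stats::setNames(
    credibility[keep], rownames(S_cons)), report = report)
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf(
    "Consensus ICA: %d/%d runs converged; %d clusters, %d retained (min credibility %s), %d dropped\n",
    x$converged_runs, x$n_runs, x$n_clusters, x$n_retained,
    format(min(x$credibility)), x$n_dropped))
  invisible(x)
}

#' Consensus independent component analysis on a whitened basis
#'
#' Runs the FastICA fixed-point algorithm `n_runs` times from different
#' deterministic random starts (seeds derived from `seed`), then matches
#' components across runs by absolute Pearson correlation and retains only
#' consensus components found in at least `min_match_runs` runs — the
#' credibility filter that separates reproducible independent components
#' from unstable ones. At the defaults (25 runs, at least 13 matches) the
#' retention rule is equivalent to a credibility index above 0.5.
#'
#' A run that fails to converge is retried once with a fresh derived seed;
#' if it still fails it is excluded from matching but kept in the
#' credibility denominator, which is conservative.
#'
#' @param basis a [whiten()] result.
#' @param n_components components to extract per run; defaults to the number
#'   of whitened variables.
#' @param n_runs number of FastICA restarts (default 25).
#' @param match_r absolute Pearson correlation threshold for cross-run
#'   matching (default 0.98).
#' @param min_match_runs minimum number of runs a component must appear in
#'   (default 13).
#' @param seed integer seed controlling all restarts.
#' @param max_iter,tol FastICA iteration controls.
#' @param mode `"parallel"` (symmetric, default) or `"deflation"` extraction.
#' @return list with `sources` (consensus components x samples, unit
#'   variance rows), `mixing_whitened` (whitened variables x components,
#'   least-squares), `credibility`, and `report`.
#' @export
run_consensus_ica <- function(basis, n_components = NULL, n_runs = 25L,
                              match_r = 0.98, min_match_runs = 13L,
                              seed, max_iter = 200L, tol = 1e-6,
                              mode = c("parallel", "deflation")) {
  stopifnot(inherits(basis, "whitened_basis"))
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  Z <- basis$whitened
  if (is.null(n_components)) n_components <- nrow(Z)
  if (n_components > nrow(Z))
    stop("n_components cannot exceed the number of whitened variables",
         call. = FALSE)
  stopifnot(n_runs >= 1L, min_match_runs >= 1L, min_match_runs <= n_runs)
  run_sources <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fit <- fastica_run(Z, n_components, derive_seed(seed, r, 1L),
                       max_iter = max_iter, tol = tol, mode = mode)
    if (!fit$converged)
      fit <- fastica_run(Z, n_components, derive_seed(seed, r, 2L),
                         max_iter = max_iter, tol = tol, mode = mode)
    run_sources[[r]] <- if (fit$converged) fit$S else NULL
  }
  if (all(vapply(run_sources, is.null, logical(1L))))
    stop("all FastICA runs failed to converge", call. = FALSE)
  res <- consensus_match(run_sources, n_runs = n_runs, match_r = match_r,
                         min_match_runs = min_match_runs)
  res$mixing_whitened <- ls_mixing(Z, res$sources, center = FALSE)
  # Order consensus components by the variance they explain in gene space:
  # the whitened-space mixing column weighted by the retained eigenvalues.
  # The sources' own variances are all ~1 by construction (and their
  # whitened-space energies are too), so this is the natural, gene-order
  # independent ranking key.
  eig <- basis$eigenvalues[seq_len(nrow(Z))]
  ord <- order(-colSums(res$mixing_whitened^2 * eig))
  ids <- paste0("TC", seq_along(ord))
  res$sources <- res$sources[ord, , drop = FALSE]
  rownames(res$sources) <- ids
  res$mixing_whitened <- res$mixing_whitened[, ord, drop = FALSE]
  colnames(res$mixing_whitened) <- ids
  res$credibility <- stats::setNames(res$credibility[ord], ids)
  res$report$credibility <- unname(res$report$credibility[ord])
  res$params <- list(n_runs = as.integer(n_runs), match_r = match_r,
                     min_match_runs = as.integer(min_match_runs),
                     seed = seed, mode = mode)
  res
}

# Least-squares mixing weights A minimizing ||X - A S||_F, with optional
# row-centering of both matrices. Falls back to an SVD pseudo-inverse (with
# a warning) when S S^T is numerically rank deficient.
ls_mixing <- function(X, S, center = TRUE) {
  if (center) {
    X <- X - rowMeans(X)
    S <- S - rowMeans(S)
  }
  G <- S %*% t(S)
  A <- tryCatch({
    if (rcond(G) < 1e-12) stop("rank deficient")
    X %*% t(S) %*% solve(G)
  }, error = function(e) {
    warning("sources are rank deficient; using pseudo-inverse",
            call. = FALSE)
    sv <- svd(S)
    pos <- sv$d > max(sv$d) * 1e-12
    X %*% sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos], nrow = sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  })
  dimnames(A) <- list(rownames(X), rownames(S))
  A
}

#' Recompute the gene mixing matrix from consensus sources
#'
#' Projects the (gene-centered) expression matrix onto the consensus
#' components by least squares, yielding the genes x components weight
#' matrix whose rows are the transcriptional regulatory barcodes. Sources
#' are centered alongside the genes so the projection is invariant to
#' constant offsets and to duplicating samples.
#'
#' @param X expression matrix (genes x samples).
#' @param sources either the list returned by [run_consensus_ica()] or a
#'   components x samples source matrix with matching sample axis.
#' @return an object of class `mixing_matrix`: list with `weights`
#'   (genes x components), `gene_ids`, `component_ids`, `credibility`
#'   (if available), and the consensus parameters.
#' @export
recompute_mixing <- function(X, sources) {
  validate_expression(X)
  credibility <- NULL
  params <- NULL
  if (is.list(sources) && !is.null(sources$sources)) {
    credibility <- sources$credibility
    params <- sources$params
    sources <- sources$sources
  }
  if (!is.matrix(sources))
    stop("sources must be a components x samples matrix", call. = FALSE)
  if (ncol(sources) != ncol(X))
    stop("sources and expression matrix must share the sample axis",
         call. = FALSE)
  A <- ls_mixing(X, sources, center = TRUE)
  structure(list(weights = A, gene_ids = rownames(X),
                 component_ids = rownames(sources),
                 credibility = credibility, params = params),
            class = "mixing_matrix")
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat(sprintf("Mixing matrix: %d genes x %d components%s\n",
              nrow(x$weights), ncol(x$weights),
              if (!is.null(x$credibility))
                sprintf(" (credibility %.2f-%.2f)", min(x$credibility),
                        max(x$credibility)) else ""))
  invisible(x)
}

#' Construct a mixing matrix from a weight matrix
#'
#' Wraps a precomputed genes x components weight matrix (e.g. loaded from
#' elsewhere, or simulated) as a `mixing_matrix` so it can feed barcode
#' construction and scoring directly.
#'
#' @param weights numeric matrix, genes x components, with rownames.
#' @param credibility optional per-component credibility indices.
#' @return a `mixing_matrix`.
#' @export
mixing_matrix <- function(weights, credibility = NULL) {
  if (!is.matrix(weights) || is.null(rownames(weights)))
    stop("weights must be a matrix with gene rownames", call. = FALSE)
  if (is.null(colnames(weights)))
    colnames(weights) <- paste0("TC", seq_len(ncol(weights)))
  stopifnot_finite(weights, "mixing weights")
  structure(list(weights = weights, gene_ids = rownames(weights),
                 component_ids = colnames(weights),
                 credibility = credibility, params = NULL),
            class = "mixing_matrix")
}

#' Write / read a mixing matrix as TSV
#'
#' The TSV has genes as rows and components as columns; component
#' credibility, if present, is stored in a leading comment line.
#'
#' @param MM a `mixing_matrix`.
#' @param path file path.
#' @param comment optional character vector of extra `#` comment lines
#'   (e.g. a pipeline configuration hash).
#' @rdname mixing_io
#' @export
write_mixing <- function(MM, path, comment = NULL) {
  stopifnot(inherits(MM, "mixing_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  if (!is.null(MM$credibility))
    writeLines(paste0("# credibility\t",
                      paste(format(MM$credibility, digits = 17),
                            collapse = "\t")), con)
  writeLines(paste(c("gene_id", MM$component_ids), collapse = "\t"), con)
  body <- vapply(seq_along(MM$gene_ids), function(i)
    paste(c(MM$gene_ids[i],
            format(MM$weights[i, ], digits = 17, trim = TRUE)),
          collapse = "\t"), character(1L))
  writeLines(body, con)
  invisible(path)
}

#' @rdname mixing_io
#' @export
read_mixing <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  cred <- NULL
  cred_line <- grep("^# credibility\t", lines, value = TRUE)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  genes <- vapply(fields, `[[`, character(1L), 1L)
  W <- t(vapply(fields, function(f) as.numeric(f[-1L]),
                numeric(length(header) - 1L)))
  dimnames(W) <- list(genes, header[-1L])
  if (length(cred_line)) {
    cred <- as.numeric(strsplit(cred_line[[1L]], "\t",
                                fixed = TRUE)[[1L]][-1L])
    names(cred) <- header[-1L]
  }
  structure(list(weights = W, gene_ids = genes, component_ids = header[-1L],
                 credibility = cred, params = NULL),
            class = "mixing_matrix")
}
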