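# Evaluation statistics: multifunctionality scores, member/nonmember
# medians and Mann-Whitney AUCs, method-improvement deltas, and the
# gene-set version-update comparison.

#' Gene multifunctionality scores for one collection
#'
#' A gene's multifunctionality score is a size-weighted sum over the gene
#' sets that contain it: each membership contributes
#' `1 / (N_in * N_out)`, where `N_in` is the set size and `N_out` the number
#' of universe genes outside the set. Genes in no set score exactly 0.
#' Highly annotated genes score high; the weighting downplays memberships in
#' very large sets.
#'
#' @param collection a filtered [gene_set_collection()].
#' @return object of class `multifunctionality`: list with `scores` (named
#'   numeric over the universe) and `collection_name`.
#' @export
multifunctionality <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  u <- collection$universe
  scores <- stats::setNames(numeric(length(u)), u)
  n_u <- length(u)
  for (nm in names(collection$sets)) {
    members <- collection$sets[[nm]]
    n_in <- length(members)
    n_out <- n_u - n_in
    if (n_out == 0L)
      stop("gene set '", nm, "' equals the whole universe (N_out = 0)",
           call. = FALSE)
    scores[members] <- scores[members] + 1 / (n_in * n_out)
  }
  structure(list(scores = scores, collection_name = collection$name),
            class = "multifunctionality")
}

#' Pan-collection multifunctionality
#'
#' Sums the per-collection multifunctionality scores over several
#' collections defined on the same gene universe, giving a single
#' annotation-breadth score per gene.
#'
#' @param collections list of [gene_set_collection()] objects with
#'   identical universes.
#' @return a `multifunctionality` object with
#'   `collection_name = "pan-collection"`.
#' @export
pan_collection_multifunctionality <- function(collections) {
  stopifnot(length(collections) >= 1L)
  u <- collections[[1L]]$universe
  for (cl in collections[-1L])
    if (!setequal(cl$universe, u))
      stop("collections have inconsistent gene universes", call. = FALSE)
  total <- stats::setNames(numeric(length(u)), u)
  for (cl in collections) {
    mf <- multifunctionality(cl)
    total <- total + mf$scores[names(total)]
  }
  structure(list(scores = total, collection_name = "pan-collection"),
            class = "multifunctionality")
}

#' Mann-Whitney AUC between two score groups
#'
#' The area under the ROC curve for separating group `a` (treated as
#' positives) from group `b`, computed as `U / (n_a * n_b)` with midrank
#' handling of ties, together with a two-sided normal-approximation p-value
#' using the tie-corrected variance.
#'
#' @param scores_a,scores_b numeric vectors (both non-empty).
#' @return list with `auc` and `p`.
#' @export
member_nonmember_auc <- function(scores_a, scores_b) {
  na <- length(scores_a); nb <- length(scores_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty",
                                 call. = FALSE)
  stopifnot_finite(scores_a, "scores_a")
  stopifnot_finite(scores_b, "scores_b")
  r <- rank(c(scores_a, scores_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  auc <- U / (na * nb)
  N <- na + nb
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  p <- if (sigma2 <= 0) 1 else {
    z <- (U - na * nb / 2) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
  list(auc = auc, p = min(p, 1))
}

#' Per-set member and nonmember median prediction scores
#'
#' For every gene set, the median prediction score of its current member
#' genes and of the collection's nonmember genes (genes assigned to no set
#' in the collection). Genes outside the score table are ignored; the
#' across-set AUC between the member-median and nonmember-median vectors
#' summarizes how cleanly members separate.
#'
#' @param scores a `prediction_score_table`.
#' @param collection the [gene_set_collection()] the scores were computed
#'   against.
#' @return object of class `evaluation_summary`: list with `per_set` (data
#'   frame: set, n_members, member_median, nonmember_median), `auc`, `p`,
#'   `method_tag`, `collection_name`.
#' @export
evaluate_collection <- function(scores, collection) {
  stopifnot(inherits(scores, "prediction_score_table"),
            inherits(collection, "gene_set_collection"))
  S <- scores$scores
  genes <- rownames(S)
  annotated <- unique(unlist(collection$sets, use.names = FALSE))
  nonmembers <- setdiff(genes, annotated)
  if (!length(nonmembers))
    stop("collection leaves no nonmember genes in the score table",
         call. = FALSE)
  set_names <- intersect(names(collection$sets), colnames(S))
  if (!length(set_names))
    stop("no overlap between collection sets and score columns",
         call. = FALSE)
  per_set <- data.frame(
    set = set_names,
    n_members = NA_integer_,
    member_median = NA_real_,
    nonmember_median = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_along(set_names)) {
    nm <- set_names[i]
    mem <- intersect(collection$sets[[nm]], genes)
    per_set$n_members[i] <- length(mem)
    per_set$member_median[i] <- stats::median(S[mem, nm])
    per_set$nonmember_median[i] <- stats::median(S[nonmembers, nm])
  }
  cmp <- member_nonmember_auc(per_set$member_median,
                              per_set$nonmember_median)
  structure(list(per_set = per_set, auc = cmp$auc, p = cmp$p,
                 method_tag = scores$method_tag,
                 collection_name = collection$name),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(
    "Evaluation (%s, '%s'): %d sets; member vs nonmember median AUC %.3f (p = %.3g)\n",
    x$method_tag, x$collection_name, nrow(x$per_set), x$auc, x$p))
  invisible(x)
}

#' Per-set improvement delta between the ICA and PCA paths
#'
#' For each gene set, delta is the median member prediction score under the
#' ICA path minus the same median under the PCA path. Positive deltas mark
#' ICA-improved sets, negative deltas PCA-improved sets; exact zeros are
#' classed as tied.
#'
#' @param scores_ica,scores_pca `prediction_score_table`s over the same
#'   genes and sets.
#' @param collection the shared [gene_set_collection()].
#' @return data frame: set, n_members, delta, class
#'   (`ica-improved` / `pca-improved` / `tied`).
#' @export
improvement_delta <- function(scores_ica, scores_pca, collection) {
  stopifnot(inherits(scores_ica, "prediction_score_table"),
            inherits(scores_pca, "prediction_score_table"))
  if (!identical(dimnames(scores_ica$scores), dimnames(scores_pca$scores)))
    stop("score tables must cover the same genes and sets", call. = FALSE)
  Si <- scores_ica$scores; Sp <- scores_pca$scores
  genes <- rownames(Si)
  set_names <- intersect(names(collection$sets), colnames(Si))
  out <- data.frame(set = set_names, n_members = NA_integer_,
                    delta = NA_real_, class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(set_names)) {
    nm <- set_names[i]
    mem <- intersect(collection$sets[[nm]], genes)
    out$n_members[i] <- length(mem)
    out$delta[i] <- stats::median(Si[mem, nm]) - stats::median(Sp[mem, nm])
  }
  out$class <- ifelse(out$delta > 0, "ica-improved",
                      ifelse(out$delta < 0, "pca-improved", "tied"))
  out
}

#' Version-update evaluation of prediction scores
#'
#' Genes added to a set between an old and a new collection version are the
#' "updated members". For every set that gained at least one updated member
#' present in the score tables, this reports the updated members' median
#' prediction score when set barcodes were built from the old membership
#' and from the new membership. A method that exploits updated annotation
#' should score updated members at least as high under the new barcodes.
#'
#' @param scores_old_barcodes,scores_new_barcodes `prediction_score_table`s
#'   computed on the same mixing matrix with the old-version and
#'   new-version collections.
#' @param collection_old,collection_new the two collection versions.
#' @return data frame: set, n_updated, median_old, median_new. Empty (with
#'   a warning) when no set gained members.
#' @export
version_update_eval <- function(scores_old_barcodes, scores_new_barcodes,
                                collection_old, collection_new) {
  stopifnot(inherits(collection_old, "gene_set_collection"),
            inherits(collection_new, "gene_set_collection"))
  common <- intersect(names(collection_old$sets),
                      names(collection_new$sets))
  common <- intersect(common,
                      intersect(colnames(scores_old_barcodes$scores),
                                colnames(scores_new_barcodes$scores)))
  rows <- list()
  genes_old <- rownames(scores_old_barcodes$scores)
  genes_new <- rownames(scores_new_barcodes$scores)
  for (nm in common) {
    updated <- setdiff(collection_new$sets[[nm]], collection_old$sets[[nm]])
    updated <- intersect(updated, intersect(genes_old, genes_new))
    if (!length(updated)) next
    rows[[nm]] <- data.frame(
      set = nm, n_updated = length(updated),
      median_old = stats::median(scores_old_barcodes$scores[updated, nm]),
      median_new = stats::median(scores_new_barcodes$scores[updated, nm]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no gene set gained members between versions", call. = FALSE)
    return(data.frame(set = character(), n_updated = integer(),
                      median_old = numeric(), median_new = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Association between multifunctionality and per-set prediction scores
#'
#' For each gene set, the distance correlation between the collection's
#' multifunctionality vector and the set's column of prediction scores. A
#' guilt-by-association method whose scores merely reflect how broadly
#' genes are annotated shows high values here; a well-calibrated method on
#' structure-free data shows values near zero.
#'
#' @param scores a `prediction_score_table`.
#' @param multifun a [multifunctionality()] result covering the scored
#'   genes.
#' @return named numeric vector of distance correlations, one per set.
#' @export
multifunctionality_association <- function(scores, multifun) {
  stopifnot(inherits(scores, "prediction_score_table"),
            inherits(multifun, "multifunctionality"))
  genes <- rownames(scores$scores)
  if (!all(genes %in% names(multifun$scores)))
    stop("multifunctionality vector does not cover all scored genes",
         call. = FALSE)
  mf <- multifun$scores[genes]
  vapply(colnames(scores$scores), function(nm)
    distance_correlation(mf, scores$scores[, nm]), numeric(1L))
}
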