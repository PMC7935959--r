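# Co-functionality matrices and networks, hierarchical clustering of
# regulatory barcodes and score profiles, and cluster diagnostics.

#' Co-functionality matrix from prediction-score profiles
#'
#' The co-functionality of two genes is the absolute Pearson correlation
#' between their vectors of prediction scores across the gene sets of a
#' collection: genes predicted into the same functions correlate strongly
#' whatever the sign. Constant score profiles get 0 against every other
#' gene and 1 on the diagonal by convention.
#'
#' @param scores a `prediction_score_table` with at least 2 sets.
#' @param genes optional subset of gene ids (rows); defaults to all.
#' @param max_genes cap on the subset size (default 300, matching
#'   interactive network exploration limits).
#' @return symmetric matrix in \[0, 1\] with unit diagonal, class
#'   `cofunctionality_matrix`.
#' @export
cofunctionality <- function(scores, genes = NULL, max_genes = 300L) {
  stopifnot(inherits(scores, "prediction_score_table"))
  S <- scores$scores
  if (!is.null(genes)) {
    if (!all(genes %in% rownames(S)))
      stop("unknown gene id(s) in 'genes'", call. = FALSE)
    if (length(genes) > max_genes)
      stop("gene subset exceeds the cap of ", max_genes, " genes",
           call. = FALSE)
    S <- S[genes, , drop = FALSE]
  }
  if (nrow(S) < 2L || ncol(S) < 2L)
    stop("need at least 2 genes and 2 sets", call. = FALSE)
  C <- suppressWarnings(abs(stats::cor(t(S))))
  C[is.na(C)] <- 0
  diag(C) <- 1
  class(C) <- c("cofunctionality_matrix", class(C))
  C
}

# Shared back end: hierarchical clustering (Ward's method, squared-update
# "ward.D2" convention) of a precomputed distance matrix, cut at a height.
cluster_from_distance <- function(D, ids, cut_height, size_bounds,
                                  distance_label) {
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  assignments <- if (is.infinite(cut_height))
    stats::setNames(rep(1L, length(ids)), ids)
  else stats::cutree(hc, h = cut_height)
  sizes <- table(assignments)
  flagged <- as.integer(names(sizes)[sizes < size_bounds[1L] |
                                       sizes > size_bounds[2L]])
  structure(list(assignments = assignments,
                 sizes = as.integer(sizes),
                 cluster_ids = as.integer(names(sizes)),
                 flagged_clusters = flagged,
                 cut_height = cut_height,
                 size_bounds = as.integer(size_bounds),
                 distance = distance_label,
                 tree = hc,
                 similarity = NULL, predictability = NULL,
                 mean_multifunctionality = NULL,
                 similarity_predictability_cor = NULL),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "Clusters: %d (distance: %s, cut height %s); sizes %d-%d; %d outside bounds [%d, %d]\n",
    length(x$cluster_ids), x$distance, format(x$cut_height),
    min(x$sizes), max(x$sizes), length(x$flagged_clusters),
    x$size_bounds[1L], x$size_bounds[2L]))
  invisible(x)
}

#' Cluster genes by their transcriptional regulatory barcodes
#'
#' Pairwise gene distance is one minus the distance correlation between
#' mixing-matrix rows; Ward agglomeration ("ward.D2" convention) is cut at
#' `cut_height`. Clusters of co-regulated genes emerge independently of any
#' gene set annotation. Clusters whose size falls outside `size_bounds` are
#' flagged, not dropped. Each cluster with at least 2 members also gets a
#' transcriptional similarity score: the median pairwise distance
#' correlation among member barcodes.
#'
#' @param MM a [recompute_mixing()] result.
#' @param cut_height dendrogram cut height (default 2.5).
#' @param size_bounds cluster size range to flag against (default 10-500,
#'   the gene set size range).
#' @return a `cluster_report`.
#' @export
cluster_barcodes <- function(MM, cut_height = 2.5, size_bounds = c(10L, 500L)) {
  stopifnot(inherits(MM, "mixing_matrix"))
  W <- MM$weights
  if (nrow(W) < 2L) stop("need at least 2 genes", call. = FALSE)
  R <- dcor_matrix(W)
  rep_ <- cluster_from_distance(1 - R, rownames(W), cut_height, size_bounds,
                                "1 - distance correlation (barcodes)")
  rep_$similarity <- cluster_similarity_from_matrix(rep_, R)
  rep_
}

# Median pairwise similarity per cluster, from a precomputed gene x gene
# similarity matrix; size-1 clusters are NA.
cluster_similarity_from_matrix <- function(rep_, R) {
  vapply(rep_$cluster_ids, function(ci) {
    mem <- names(rep_$assignments)[rep_$assignments == ci]
    if (length(mem) < 2L) return(NA_real_)
    sub <- R[mem, mem]
    stats::median(sub[upper.tri(sub)])
  }, numeric(1L))
}

#' Cluster genes by their prediction-score profiles
#'
#' As [cluster_barcodes()], but the distance is one minus the Pearson
#' correlation between prediction-score vectors, and the default cut height
#' is 0.8 — the convention used to group uncharacterized genes into
#' putative functional clusters.
#'
#' @param scores a `prediction_score_table`.
#' @param genes optional gene subset.
#' @param cut_height dendrogram cut height (default 0.8).
#' @param size_bounds cluster size range to flag against.
#' @return a `cluster_report`.
#' @export
cluster_score_profiles <- function(scores, genes = NULL, cut_height = 0.8,
                                   size_bounds = c(2L, 500L)) {
  stopifnot(inherits(scores, "prediction_score_table"))
  S <- scores$scores
  if (!is.null(genes)) {
    if (!all(genes %in% rownames(S)))
      stop("unknown gene id(s) in 'genes'", call. = FALSE)
    S <- S[genes, , drop = FALSE]
  }
  if (nrow(S) < 2L) stop("need at least 2 genes", call. = FALSE)
  R <- suppressWarnings(stats::cor(t(S)))
  R[is.na(R)] <- 0
  diag(R) <- 1
  cluster_from_distance(1 - R, rownames(S), cut_height, size_bounds,
                        "1 - Pearson correlation (score profiles)")
}

#' Cluster similarity and predictability diagnostics
#'
#' Augments a `cluster_report` with, per cluster: the transcriptional
#' similarity score (median pairwise distance correlation of member
#' barcodes; NA for singletons), the predictability score (median over
#' members of each member's maximum prediction score across all supplied
#' sets), and optionally the mean multifunctionality of members. Also
#' reports the across-cluster Pearson correlation between similarity and
#' predictability: a high value means well-annotated, strongly co-regulated
#' processes are exactly the ones the method predicts confidently.
#'
#' @param clusters a `cluster_report`.
#' @param MM the mixing matrix the barcodes come from.
#' @param scores a `prediction_score_table` (pool collections by column
#'   binding beforehand if desired).
#' @param multifun optional [multifunctionality()] result.
#' @return the augmented `cluster_report` with a `summary` data frame.
#' @export
cluster_diagnostics <- function(clusters, MM, scores, multifun = NULL) {
  stopifnot(inherits(clusters, "cluster_report"),
            inherits(MM, "mixing_matrix"),
            inherits(scores, "prediction_score_table"))
  genes <- names(clusters$assignments)
  if (!all(genes %in% rownames(MM$weights)) ||
      !all(genes %in% rownames(scores$scores)))
    stop("clustered genes must be present in both the mixing matrix and the score table",
         call. = FALSE)
  R <- dcor_matrix(MM$weights[genes, , drop = FALSE])
  clusters$similarity <- cluster_similarity_from_matrix(clusters, R)
  max_score <- apply(scores$scores[genes, , drop = FALSE], 1L, max)
  clusters$predictability <- vapply(clusters$cluster_ids, function(ci) {
    mem <- genes[clusters$assignments == ci]
    stats::median(max_score[mem])
  }, numeric(1L))
  if (!is.null(multifun)) {
    stopifnot(inherits(multifun, "multifunctionality"))
    clusters$mean_multifunctionality <- vapply(clusters$cluster_ids,
                                               function(ci) {
      mem <- genes[clusters$assignments == ci]
      mean(multifun$scores[mem])
    }, numeric(1L))
  }
  ok <- !is.na(clusters$similarity)
  clusters$similarity_predictability_cor <-
    if (sum(ok) >= 3L && stats::sd(clusters$similarity[ok]) > 0 &&
        stats::sd(clusters$predictability[ok]) > 0)
      stats::cor(clusters$similarity[ok], clusters$predictability[ok])
  else NA_real_
  clusters$summary <- data.frame(
    cluster = clusters$cluster_ids,
    size = clusters$sizes,
    similarity = clusters$similarity,
    predictability = clusters$predictability,
    mean_multifunctionality = if (is.null(clusters$mean_multifunctionality))
      NA_real_ else clusters$mean_multifunctionality,
    stringsAsFactors = FALSE)
  clusters
}

#' Export a thresholded co-functionality network
#'
#' Builds an undirected weighted graph whose nodes are the genes with at
#' least one co-functionality value above `threshold` and whose edges carry
#' the co-functionality weight. Node and edge order follow the gene order
#' of the matrix, so exports are deterministic.
#'
#' @param M a [cofunctionality()] matrix.
#' @param threshold edge threshold in \[0, 1\]; only pairs with
#'   co-functionality strictly above it become edges.
#' @param file optional output path; written as GraphML
#'   (`format = "graphml"`) or a TSV edge list with a `weight` column.
#' @param format `"graphml"` or `"tsv"`.
#' @return an [igraph::graph] object (invisibly if `file` is given).
#' @export
export_network <- function(M, threshold = 0.5, file = NULL,
                           format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  A <- as.matrix(M)
  diag(A) <- 0
  A[A <= threshold] <- 0
  keep <- rowSums(A > 0) > 0
  if (!any(keep)) {
    warning("no edge exceeds the threshold; exporting an empty graph",
            call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(A[keep, keep, drop = FALSE],
                                             mode = "undirected",
                                             weighted = TRUE)
  }
  if (!is.null(file)) {
    if (format == "graphml") {
      igraph::write_graph(g, file, format = "graphml")
    } else {
      if (igraph::ecount(g) > 0) {
        el <- igraph::as_data_frame(g, what = "edges")
        names(el) <- c("gene_a", "gene_b", "weight")
      } else {
        el <- data.frame(gene_a = character(), gene_b = character(),
                         weight = numeric())
      }
      utils::write.table(el, file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    return(invisible(g))
  }
  g
}
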