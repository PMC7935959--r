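# Expression matrix and gene set collection input/output, plus the
# PC1-correlation sample quality-control filter.

#' Validate a gene x sample expression matrix
#'
#' Expression matrices are plain numeric matrices: rows are genes, columns are
#' samples, rownames/colnames hold the identifiers, values are on a
#' normalized/log scale. This checks the structural invariants every function
#' in the package relies on.
#'
#' @param X numeric matrix with unique rownames (genes) and colnames (samples).
#' @param min_genes,min_samples minimum dimensions accepted.
#' @return `X` invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(X, min_genes = 2L, min_samples = 3L) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("expression data must be a numeric matrix (genes x samples)",
         call. = FALSE)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(X)))
    stop("duplicate gene identifiers in expression matrix: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(X)))
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  if (nrow(X) < min_genes || ncol(X) < min_samples)
    stop(sprintf("expression matrix needs at least %d genes and %d samples",
                 min_genes, min_samples), call. = FALSE)
  invisible(X)
}

#' Read a gene x sample expression matrix
#'
#' The delimited dialect is tab-separated UTF-8 without quoting: a header row
#' of sample identifiers and a first column of gene identifiers. Lines
#' starting with `#` are treated as comments (pipeline artifacts carry a
#' configuration fingerprint there). The `"feather"` format reads the same
#' table from an Arrow/Feather binary container (column `gene_id` plus one
#' column per sample), convenient for large matrices.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"feather"`.
#' @return validated numeric matrix, genes x samples.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, format = c("tsv", "feather")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for format = \"feather\"",
           call. = FALSE)
    df <- as.data.frame(arrow::read_feather(path))
    if (!"gene_id" %in% names(df))
      stop("feather container must have a 'gene_id' column", call. = FALSE)
    genes <- as.character(df$gene_id)
    X <- as.matrix(df[setdiff(names(df), "gene_id")])
    rownames(X) <- genes
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) < 2L) stop("expression file has no data rows: ", path,
                                 call. = FALSE)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    samples <- trimws(header[-1L])
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != length(header))
    if (length(bad))
      stop(sprintf("malformed row in %s at line %d: expected %d fields, got %d",
                   path, bad[1L] + 1L, length(header), nf[bad[1L]]),
           call. = FALSE)
    genes <- trimws(vapply(fields, `[[`, character(1L), 1L))
    X <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (i in seq_along(fields)) {
      v <- suppressWarnings(as.numeric(fields[[i]][-1L]))
      if (anyNA(v))
        stop(sprintf("non-numeric value in %s at line %d", path, i + 1L),
             call. = FALSE)
      X[i, ] <- v
    }
  }
  validate_expression(X)
  X
}

#' Write a gene x sample expression matrix
#'
#' @param X validated expression matrix.
#' @param path output file.
#' @param format `"tsv"` or `"feather"` (Arrow binary container).
#' @param header_comment optional character vector written as leading
#'   `#`-prefixed comment lines (tsv only).
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, format = c("tsv", "feather"),
                             header_comment = NULL) {
  format <- match.arg(format)
  validate_expression(X)
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for format = \"feather\"",
           call. = FALSE)
    df <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
    arrow::write_feather(df, path)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (length(header_comment))
      writeLines(paste0("# ", header_comment), con)
    writeLines(paste(c("gene_id", colnames(X)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(X)), function(i)
      paste(c(rownames(X)[i], format(X[i, ], digits = 17, trim = TRUE,
                                     scientific = NA)),
            collapse = "\t"), character(1L))
    writeLines(body, con)
  }
  invisible(path)
}

#' Construct a gene set collection
#'
#' A collection is a named list of member vectors over a declared gene
#' universe, together with the size bounds that were (or will be) applied.
#'
#' @param sets named list of character vectors of member gene ids.
#' @param universe character vector of all gene identifiers under study.
#' @param name label for the collection.
#' @param size_bounds integer pair `(min_size, max_size)`.
#' @param log character vector of filtering provenance messages.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, name = "collection",
                                size_bounds = c(10L, 500L), log = character()) {
  universe <- unique(trimws(as.character(universe)))
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("gene sets must have unique names", call. = FALSE)
    sets <- lapply(sets, function(m) unique(trimws(as.character(m))))
    outside <- unlist(lapply(sets, setdiff, y = universe), use.names = FALSE)
    if (length(outside))
      stop("gene set members outside the declared universe: ",
           paste(utils::head(unique(outside), 5L), collapse = ", "),
           call. = FALSE)
  }
  structure(list(name = name, universe = universe, sets = sets,
                 size_bounds = as.integer(size_bounds), log = log),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene set collection '%s': %d sets over %d genes (size bounds %d-%d)\n",
              x$name, length(x$sets), length(x$universe),
              x$size_bounds[1L], x$size_bounds[2L]))
  invisible(x)
}

#' Number of gene sets in a collection
#' @param x a `gene_set_collection`.
#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene set collection
#'
#' Parses the Broad GMT dialect (set name, description, then member ids, all
#' tab-separated). Members are intersected with `universe` *before* the size
#' filter, so filtering acts on the usable members; sets that end up outside
#' `[min_size, max_size]` are dropped, and sets with zero surviving members
#' are silently dropped with a log entry.
#'
#' @param path GMT file.
#' @param universe gene identifiers defining the analysis universe.
#' @param min_size,max_size retained set size range (defaults 10 and 500).
#' @param name collection label; defaults to the file name.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe, min_size = 10L, max_size = 500L,
                     name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.gmt$", "", basename(path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d in %s: need name, description, members",
                 short[1L], path), call. = FALSE)
  set_names <- trimws(vapply(fields, `[[`, character(1L), 1L))
  if (anyDuplicated(set_names))
    stop("duplicate gene set names in ", path, call. = FALSE)
  raw_sets <- lapply(fields, function(f) unique(trimws(f[-c(1L, 2L)])))
  names(raw_sets) <- set_names
  filtered <- filter_collection(
    gene_set_collection(lapply(raw_sets, intersect, y = universe),
                        universe = universe, name = name,
                        size_bounds = c(min_size, max_size)),
    min_size = min_size, max_size = max_size)
  empty <- set_names[vapply(raw_sets, function(m)
    length(intersect(m, universe)) == 0L, logical(1L))]
  if (length(empty))
    filtered$log <- c(filtered$log,
                      sprintf("dropped %d set(s) with no member in universe: %s",
                              length(empty),
                              paste(utils::head(empty, 5L), collapse = ", ")))
  filtered
}

#' Apply the gene set size filter
#'
#' Keeps sets whose member count (after universe harmonization) lies within
#' `[min_size, max_size]`. Idempotent: filtering an already-filtered
#' collection changes nothing.
#'
#' @param collection a [gene_set_collection()].
#' @param min_size,max_size inclusive size bounds.
#' @return the filtered collection, with provenance appended to `$log`.
#' @export
filter_collection <- function(collection,
                              min_size = collection$size_bounds[1L],
                              max_size = collection$size_bounds[2L]) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sizes <- lengths(collection$sets)
  keep <- sizes >= min_size & sizes <= max_size
  dropped <- sum(!keep)
  collection$sets <- collection$sets[keep]
  collection$size_bounds <- as.integer(c(min_size, max_size))
  collection$log <- c(collection$log,
                      sprintf("size filter [%d, %d]: kept %d sets, dropped %d",
                              min_size, max_size, sum(keep), dropped))
  collection
}

#' Write a collection in GMT format
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$name, collection$sets[[nm]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Quality-control filter on sample coherence with the leading component
#'
#' Large expression compendia share a dominant platform-wide signature: the
#' first principal component of the sample-sample Pearson correlation matrix.
#' Samples whose expression profile does not correlate strongly with this
#' component are flagged as low quality and discarded.
#'
#' The component is realized in gene space as the PC1-weighted combination of
#' sample profiles; its sign is chosen so that the majority of sample
#' correlations are positive, making the filter deterministic and invariant
#' to sample order.
#'
#' @param X expression matrix (genes x samples), at least 3 samples.
#' @param r_min minimum Pearson correlation with the leading component
#'   (default 0.8).
#' @return list with `X` (retained samples) and `discarded` (sample ids).
#' @export
qc_filter_samples <- function(X, r_min = 0.8) {
  validate_expression(X)
  C <- stats::cor(X)                       # sample x sample, over genes
  v <- eigen(C, symmetric = TRUE)$vectors[, 1L]
  meta <- as.vector(X %*% v)               # leading component in gene space
  r <- suppressWarnings(stats::cor(X, meta))[, 1L]
  r[is.na(r)] <- 0
  if (sum(r > 0) < length(r) / 2) r <- -r  # majority-positive sign convention
  keep <- r >= r_min
  if (!any(keep))
    stop("all samples discarded by QC filter (r_min = ", r_min, ")",
         call. = FALSE)
  list(X = X[, keep, drop = FALSE], discarded = colnames(X)[!keep])
}
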