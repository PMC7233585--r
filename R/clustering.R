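# Single-linkage clustering of allele SRFI profiles with Manhattan distance.

#' Manhattan distance between two profile vectors
#'
#' \deqn{D(x, y) = \sum_k |x_k - y_k|}
#'
#' @param x,y Equal-length numeric vectors without missing entries.
#' @return Non-negative distance.
#' @export
manhattan <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (anyNA(x) || anyNA(y)) {
    stop("missing entries; impute or drop positions first", call. = FALSE)
  }
  sum(abs(x - y))
}

#' Pairwise Manhattan distances between allele profiles
#'
#' Positions with a missing value in any allele are dropped before distance
#' computation (with a warning).
#'
#' @param x An `srfi_matrix` (alleles x positions).
#' @param positions Optional subset of position labels to use.
#' @return A `dist` object over alleles, ordered by allele label.
#' @export
profile_distances <- function(x, positions = NULL) {
  stopifnot(inherits(x, "srfi_matrix"))
  m <- unclass(x)
  if (!is.null(positions)) {
    missing <- setdiff(as.character(positions), colnames(m))
    if (length(missing) > 0L) {
      stop("unknown position(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- m[, as.character(positions), drop = FALSE]
  }
  keep <- colSums(is.na(m)) == 0L
  if (!all(keep)) {
    warning(sum(!keep), " position(s) with missing values dropped before ",
            "distance computation", call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  stats::dist(m, method = "manhattan")
}

#' Single-linkage agglomeration of a distance matrix
#'
#' Standard agglomerative clustering where the inter-cluster distance is the
#' minimum pairwise member distance, \eqn{L(r,s) = \min D(x_{ri}, x_{sj})}.
#' Input labels are sorted before agglomeration so tie-breaking is
#' deterministic and independent of input order. Single-linkage merge
#' heights are non-decreasing.
#'
#' @param d A `dist` object, or a square symmetric non-negative matrix with
#'   zero diagonal.
#' @return An `hclust` object.
#' @export
single_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12 ||
        any(diag(d) != 0)) {
      stop("distance matrix must be square, symmetric, zero-diagonal",
           call. = FALSE)
    }
    if (any(d < 0)) stop("negative distances", call. = FALSE)
    if (!is.null(rownames(d))) {
      ord <- order(rownames(d))
      d <- d[ord, ord]
    }
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "single")
}

#' Cut a linkage tree into k clusters
#'
#' @param tree An `hclust` object.
#' @param k Number of clusters, 1 <= k <= number of leaves.
#' @return Named integer cluster assignment.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k out of range", call. = FALSE)
  stats::cutree(tree, k = k)
}

#' Cluster alleles by SRFI profile
#'
#' Convenience wrapper: variation-filter or subset positions, compute
#' Manhattan distances, single-linkage agglomerate and cut into k clusters.
#'
#' @param x An `srfi_matrix`.
#' @param k Number of clusters to extract.
#' @param positions Optional position subset (e.g. from
#'   [variation_filter()]); `NULL` uses all positions.
#' @return List with `tree` (hclust), `assignment` (named integer vector)
#'   and `positions` (character vector used).
#' @export
cluster_profiles <- function(x, k, positions = NULL) {
  d <- profile_distances(x, positions)
  tree <- single_linkage(d)
  list(tree = tree, assignment = cut_clusters(tree, k),
       positions = if (is.null(positions)) colnames(x)
                   else as.character(positions))
}

#' Export a linkage tree
#'
#' @param tree An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @describeIn write_dendrogram_newick Newick serialization via ape.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' @describeIn write_dendrogram_newick merge table (left, right, height) TSV.
#' @export
write_merge_table <- function(tree, path) {
  df <- data.frame(left = tree$merge[, 1], right = tree$merge[, 2],
                   height = tree$height)
  .write_tsv(df, path)
  invisible(path)
}
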