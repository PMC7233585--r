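# Per-column information content and real-value Evolutionary Trace ranks.

#' Construct a multiple sequence alignment object
#'
#' @param labels Sequence (allele) names, unique.
#' @param rows Equal-length aligned amino-acid strings; `-` marks a gap.
#' @param background Background amino-acid distribution over
#'   [amino_acids()]; defaults to uniform 1/20.
#' @return An `msa` object.
#' @export
msa <- function(labels, rows, background = rep(1 / 20, 20)) {
  stopifnot(length(labels) == length(rows))
  if (anyDuplicated(labels)) stop("duplicate sequence labels", call. = FALSE)
  w <- nchar(rows)
  if (length(unique(w)) != 1L) {
    stop("alignment rows must have equal length", call. = FALSE)
  }
  chars <- unique(unlist(strsplit(rows, "")))
  bad <- setdiff(chars, c(amino_acids(), "-"))
  if (length(bad) > 0L) {
    stop("invalid alignment symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  background <- stats::setNames(as.numeric(background), amino_acids())
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-8) {
    stop("background must be a strictly positive distribution", call. = FALSE)
  }
  structure(list(labels = as.character(labels), rows = as.character(rows),
                 background = background),
            class = "msa")
}

#' Read an aligned FASTA file as an msa
#'
#' @param path FASTA file of equal-length amino-acid rows.
#' @param background Background distribution, defaults to uniform.
#' @return An `msa` object.
#' @export
read_msa <- function(path, background = rep(1 / 20, 20)) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  msa(names(seqs), toupper(vapply(seqs, as.character, character(1))),
      background)
}

#' Write an msa as aligned FASTA
#'
#' @param x An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  seqinr::write.fasta(as.list(x$rows), x$labels, path)
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

.msa_column <- function(x, position) {
  w <- nchar(x$rows[1])
  if (position < 1L || position > w) {
    stop("position out of alignment range", call. = FALSE)
  }
  substr(x$rows, position, position)
}

#' Empirical amino-acid frequencies of an alignment column
#'
#' Frequencies over the non-gap symbols of the column; an all-gap column is
#' an error.
#'
#' @param x An `msa` object.
#' @param position 1-based column index.
#' @return Named 20-vector summing to 1.
#' @export
column_probabilities <- function(x, position) {
  stopifnot(inherits(x, "msa"))
  col <- .msa_column(x, position)
  col <- col[col != "-"]
  if (length(col) == 0L) stop("all-gap column", call. = FALSE)
  tab <- table(factor(col, levels = amino_acids()))
  stats::setNames(as.numeric(tab) / length(col), amino_acids())
}

#' Shannon information content of a column distribution
#'
#' \deqn{I = \sum_a p_a \log_2(p_a / q_a)} in bits, with 0 log 0 terms
#' taken as zero. With a uniform background this is the sequence-logo column
#' height, bounded by log2(20).
#'
#' @param p Observed 20-vector distribution.
#' @param q Background 20-vector distribution, strictly positive.
#' @return Information content in bits.
#' @export
information_content <- function(p, q = rep(1 / 20, 20)) {
  stopifnot(length(p) == 20L, length(q) == 20L, all(q > 0))
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Build a sequence tree by average-linkage agglomeration
#'
#' Pairwise distance is the normalized Hamming distance between aligned rows
#' (fraction of differing columns; a gap mismatching a residue counts as a
#' difference). Rows are ordered by label before agglomeration so the result
#' is invariant to input order.
#'
#' @param x An `msa` object.
#' @return An `hclust` tree whose labels are the msa labels.
#' @export
build_tree <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (length(x$rows) < 2L) stop("need at least 2 sequences", call. = FALSE)
  ord <- order(x$labels)
  rows <- x$rows[ord]
  labels <- x$labels[ord]
  chars <- do.call(rbind, strsplit(rows, ""))
  n <- length(rows)
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d[a, b] <- d[b, a] <- mean(chars[a, ] != chars[b, ])
    }
  }
  dimnames(d) <- list(labels, labels)
  stats::hclust(stats::as.dist(d), method = "average")
}

# coerce an externally supplied tree (ape phylo, ultrametric) to hclust
.as_hclust_tree <- function(tree) {
  if (inherits(tree, "hclust")) return(tree)
  if (inherits(tree, "phylo")) {
    return(stats::as.hclust(ape::multi2di(tree)))
  }
  stop("tree must be an hclust or an ultrametric phylo object",
       call. = FALSE)
}

#' Real-value Evolutionary Trace rank of an alignment position
#'
#' \deqn{\rho_i = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g=1}^{n} H_g}
#' where cutting the sequence tree into n groups defines groups g, and
#' H_g is the Shannon entropy (natural log) of the column restricted to the
#' non-gap symbols of group g (an all-gap group contributes 0). An invariant
#' column scores exactly 1 (highest evolutionary importance); variation that
#' arises deep in the tree is penalised less than variation within recent
#' groups.
#'
#' @param x An `msa` object.
#' @param tree An `hclust` (or ultrametric `phylo`) over the msa labels;
#'   defaults to [build_tree()].
#' @param position 1-based column index.
#' @return Numeric rank >= 1.
#' @export
rvet <- function(x, position, tree = build_tree(x)) {
  stopifnot(inherits(x, "msa"))
  tree <- .as_hclust_tree(tree)
  if (!setequal(tree$labels, x$labels)) {
    stop("tree leaves must match msa labels", call. = FALSE)
  }
  col <- stats::setNames(.msa_column(x, position), x$labels)
  N <- length(x$labels)
  total <- 0
  for (n in seq_len(N - 1L)) {
    groups <- stats::cutree(tree, k = n)
    hsum <- 0
    for (g in unique(groups)) {
      sym <- col[names(groups)[groups == g]]
      sym <- sym[sym != "-"]
      if (length(sym) == 0L) next
      p <- table(sym) / length(sym)
      hsum <- hsum - sum(p * log(p))
    }
    total <- total + hsum / n
  }
  1 + total
}

#' Per-position conservation and evolutionary importance table
#'
#' Computes the information content (bits, against the msa background) and
#' the rvET rank for every alignment column.
#'
#' @param x An `msa` object.
#' @param tree Optional tree (see [rvet()]); built from the msa by default.
#' @return data.frame with columns `position`, `ic_bits`, `rvet`.
#' @export
evolutionary_trace <- function(x, tree = build_tree(x)) {
  stopifnot(inherits(x, "msa"))
  w <- nchar(x$rows[1])
  ic <- vapply(seq_len(w), function(j) {
    information_content(column_probabilities(x, j), x$background)
  }, numeric(1))
  rho <- vapply(seq_len(w), function(j) rvet(x, j, tree), numeric(1))
  data.frame(position = seq_len(w), ic_bits = ic, rvet = rho)
}
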