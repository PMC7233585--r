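# Per-allele SRFI profiles: medians over structures, ligand-removal deltas,
# and variation-based position filtering.

#' Construct an allele-by-position SRFI matrix
#'
#' Internally alleles are rows and positions columns; [write_srfi_matrix()]
#' serializes transposed (positions as rows) which is the conventional
#' orientation for these tables.
#'
#' @param values Numeric matrix, alleles x positions; `NA` allowed.
#' @param alleles,positions Row / column labels (unique).
#' @return An `srfi_matrix` (a numeric matrix with dimnames and a class).
#' @export
srfi_matrix <- function(values, alleles = rownames(values),
                        positions = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(alleles) || is.null(positions)) {
    stop("allele and position labels are required", call. = FALSE)
  }
  if (anyDuplicated(alleles) || anyDuplicated(positions)) {
    stop("duplicate allele or position labels", call. = FALSE)
  }
  stopifnot(nrow(values) == length(alleles),
            ncol(values) == length(positions))
  dimnames(values) <- list(as.character(alleles), as.character(positions))
  class(values) <- c("srfi_matrix", class(values))
  values
}

#' Write / read an SRFI matrix as TSV (positions as rows)
#'
#' @param x An `srfi_matrix`.
#' @param path File path.
#' @return `write_srfi_matrix` returns `path` invisibly; `read_srfi_matrix`
#'   returns an `srfi_matrix`.
#' @export
write_srfi_matrix <- function(x, path) {
  stopifnot(inherits(x, "srfi_matrix"))
  tx <- t(unclass(x))
  df <- data.frame(position = rownames(tx), tx, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_srfi_matrix
#' @export
read_srfi_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  pos <- as.character(df[[1]])
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  srfi_matrix(m, alleles = rownames(m), positions = pos)
}

# extract a named per-position SRFI vector from a frustration_profile,
# optionally restricted to one chain
.profile_vector <- function(profile, chain = NULL) {
  stopifnot(inherits(profile, "frustration_profile"))
  pr <- profile$per_residue
  if (!is.null(chain)) pr <- pr[pr$chain == chain, , drop = FALSE]
  keys <- if (length(unique(pr$chain)) <= 1L) {
    as.character(pr$resno)
  } else {
    paste0(pr$chain, ":", pr$resno)
  }
  stats::setNames(pr$srfi, keys)
}

#' Median SRFI over a set of structures of one allele
#'
#' Per-position median over the per-structure profiles (one structure per
#' modeled ligand). Missing values are excluded position-wise; a position
#' missing in every profile stays missing. The even-count median is the mean
#' of the central pair.
#'
#' @param profiles List of `frustration_profile` objects sharing residue keys.
#' @param chain Optional chain to restrict to (e.g. the receptor chain).
#' @return Named per-position numeric vector.
#' @export
median_srfi <- function(profiles, chain = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  vecs <- lapply(profiles, .profile_vector, chain = chain)
  keys <- names(vecs[[1]])
  for (v in vecs) {
    if (!identical(names(v), keys)) {
      stop("profiles have inconsistent residue keys", call. = FALSE)
    }
  }
  m <- do.call(rbind, vecs)
  out <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) NA_real_ else stats::median(col)
  })
  stats::setNames(as.numeric(out), keys)
}

#' SRFI change upon ligand binding
#'
#' Per-position difference between the median SRFI of the ligand-loaded
#' structures and the SRFI of a single ligand-free structure. Positive values
#' mean binding reduces frustration at that position.
#'
#' @param loaded_median Named per-position vector (see [median_srfi()]).
#' @param free_profile A `frustration_profile` of the ligand-free structure,
#'   or a named per-position vector.
#' @param chain Optional chain restriction applied when `free_profile` is a
#'   profile object.
#' @return Named per-position vector over the shared positions.
#' @export
delta_srfi <- function(loaded_median, free_profile, chain = NULL) {
  free <- if (inherits(free_profile, "frustration_profile")) {
    .profile_vector(free_profile, chain = chain)
  } else {
    free_profile
  }
  shared <- intersect(names(loaded_median), names(free))
  if (length(shared) == 0L) stop("no shared positions", call. = FALSE)
  loaded_median[shared] - free[shared]
}

#' Filter matrix positions by SRFI variation
#'
#' Keeps positions whose variation across alleles is at least `threshold`
#' (default 0.5). Variation is by default the standard deviation over the
#' non-missing entries — unlike the range, its value does not grow with the
#' number of alleles, so a fixed 0.5 cutoff separates genuinely polymorphic
#' positions from mere sampling noise regardless of panel size; `"range"`
#' and `"var"` are selectable alternatives. Positions missing in more than
#' half the alleles are dropped first with a warning.
#'
#' @param x An `srfi_matrix`.
#' @param threshold Minimum variation to keep a position (default 0.5).
#' @param measure One of "sd" (default), "range", "var".
#' @return Character vector of kept position labels.
#' @export
variation_filter <- function(x, threshold = 0.5,
                             measure = c("sd", "range", "var")) {
  stopifnot(inherits(x, "srfi_matrix"))
  measure <- match.arg(measure)
  m <- unclass(x)
  missing_frac <- colMeans(is.na(m))
  if (any(missing_frac > 0.5)) {
    warning(sum(missing_frac > 0.5),
            " position(s) missing in over half the alleles dropped",
            call. = FALSE)
    m <- m[, missing_frac <= 0.5, drop = FALSE]
  }
  v <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) return(0)
    switch(measure,
           range = diff(range(col)),
           sd = stats::sd(col),
           var = stats::var(col))
  })
  colnames(m)[v >= threshold]
}
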