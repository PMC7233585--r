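# Amino-acid lookup tables shared across modules.

#' Canonical one-letter amino-acid codes
#'
#' The 20 canonical residue types, in alphabetical order of one-letter code.
#' All contact matrices, decoy enumerations and alignment columns are indexed
#' against this vector.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Formal side-chain charges at neutral pH used by the screened electrostatic
# term: D,E -> -1; K,R -> +1; H and everything else 0.
.AA_CHARGE <- c(
  A = 0L, C = 0L, D = -1L, E = -1L, F = 0L, G = 0L, H = 0L, I = 0L,
  K = 1L, L = 0L, M = 0L, N = 0L, P = 0L, Q = 0L, R = 1L, S = 0L,
  T = 0L, V = 0L, W = 0L, Y = 0L
)

# Kyte-Doolittle hydropathy, the basis of the default contact potential.
.AA_KD <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

#' Formal charge of an amino acid
#'
#' Charges used by the Debye-Huckel electrostatic term: aspartate and
#' glutamate carry -1, lysine and arginine +1, histidine and all remaining
#' residues 0.
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Integer vector of charges in \{-1, 0, +1\}.
#' @export
aa_charge <- function(aa) {
  stop_if_noncanonical(aa)
  unname(.AA_CHARGE[aa])
}

stop_if_noncanonical <- function(aa) {
  bad <- setdiff(unique(aa), amino_acids())
  if (length(bad) > 0L) {
    stop("non-canonical amino acid code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
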