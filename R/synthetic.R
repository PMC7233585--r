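# Synthetic fixtures with known ground truth: toy receptor-ligand complexes,
# alignments with planted group motifs, and SRFI matrices with planted
# cluster structure. All generators are pure functions of their arguments
# (seed included); randomness never touches the caller's RNG state.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

.AA_123 <- stats::setNames(names(.AA_321), unname(.AA_321))

.pdb_atom_line <- function(serial, name, aa3, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, aa3, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0)
}

#' Generate a toy receptor-ligand complex
#'
#' Builds a helix-like receptor chain (chain A) and a short ligand chain
#' (chain C) positioned so that ligand residue k contacts exactly receptor
#' groove position k — and no other receptor residue — within the contact
#' cutoff. Receptor geometry: residue i sits at radius `radius` on a helix
#' with `twist_deg` per residue and `rise` per residue, giving same-chain
#' contacts at sequence offsets 3-4 under the default 9.5 A cutoff. Each
#' ligand residue is pushed radially outward by `ligand_offset` from its
#' groove residue. With an empty `groove_positions` the ligand is placed far
#' from the receptor (no contacts). The realized contact map is verified
#' against the requested groove; an unsatisfiable geometry is an error.
#'
#' @param receptor_length Number of receptor residues (default 30).
#' @param groove_positions Receptor residue numbers the ligand must contact
#'   (default 7, 8, 9). The ligand has one residue per groove position (or
#'   `ligand_length` residues when the groove is empty).
#' @param receptor_seq Receptor sequence: a string of one-letter codes, or
#'   `NULL` for the default (alanine background with isoleucine at groove
#'   positions), or `"random"` for a uniform random sequence (seeded).
#' @param ligand_aa One-letter code used for every ligand residue
#'   (default "I", hydrophobic, so groove contacts are stabilizing).
#' @param ligand_length Ligand residue count when `groove_positions` is
#'   empty (otherwise derived from the groove).
#' @param cutoff,min_seq_sep Contact-map parameters used for verification
#'   and returned model.
#' @param radius,rise,twist_deg,ligand_offset Geometry in angstrom / degrees.
#' @param seed Integer seed (used only for `receptor_seq = "random"`).
#' @return List with `model` (a `structure_model` with contacts), `pdb`
#'   (character vector of PDB lines) and `groove` (the groove positions).
#' @export
make_complex <- function(receptor_length = 30L,
                         groove_positions = c(7L, 8L, 9L),
                         receptor_seq = NULL, ligand_aa = "I",
                         ligand_length = 3L,
                         cutoff = 9.5, min_seq_sep = 3L,
                         radius = 2.3, rise = 2.2, twist_deg = 100,
                         ligand_offset = 7.5, seed = 1L) {
  stopifnot(receptor_length >= 1L)
  groove_positions <- sort(unique(as.integer(groove_positions)))
  if (length(groove_positions) > 0L &&
      (min(groove_positions) < 1L ||
       max(groove_positions) > receptor_length)) {
    stop("groove positions outside receptor range", call. = FALSE)
  }
  if (is.null(receptor_seq)) {
    seq_vec <- rep("A", receptor_length)
    seq_vec[groove_positions] <- "I"
  } else if (identical(receptor_seq, "random")) {
    seq_vec <- .with_seed(seed,
                          sample(amino_acids(), receptor_length,
                                 replace = TRUE))
  } else {
    seq_vec <- strsplit(receptor_seq, "")[[1]]
    if (length(seq_vec) != receptor_length) {
      stop("receptor_seq length mismatch", call. = FALSE)
    }
  }
  stop_if_noncanonical(c(seq_vec, ligand_aa))

  theta <- (seq_len(receptor_length) - 1L) * twist_deg * pi / 180
  rec_xyz <- cbind(radius * cos(theta), radius * sin(theta),
                   (seq_len(receptor_length) - 1L) * rise)

  n_lig <- if (length(groove_positions) > 0L) length(groove_positions)
           else as.integer(ligand_length)
  lig_xyz <- if (length(groove_positions) > 0L) {
    t(vapply(groove_positions, function(g) {
      th <- theta[g]
      c((radius + ligand_offset) * cos(th),
        (radius + ligand_offset) * sin(th), rec_xyz[g, 3])
    }, numeric(3)))
  } else {
    cbind(rep(0, n_lig), rep(0, n_lig),
          max(rec_xyz[, 3]) + 50 + seq_len(n_lig) * rise)
  }

  lines <- character(0)
  serial <- 0L
  for (i in seq_len(receptor_length)) {
    serial <- serial + 1L
    name <- if (seq_vec[i] == "G") " CA" else " CB"
    lines <- c(lines, .pdb_atom_line(serial, name, .AA_123[seq_vec[i]], "A",
                                     i, rec_xyz[i, ]))
  }
  lines <- c(lines, "TER")
  for (k in seq_len(n_lig)) {
    serial <- serial + 1L
    name <- if (ligand_aa == "G") " CA" else " CB"
    lines <- c(lines, .pdb_atom_line(serial, name, .AA_123[ligand_aa], "C",
                                     k, lig_xyz[k, ]))
  }
  lines <- c(lines, "TER", "END")

  model <- contact_map(read_structure(lines), cutoff = cutoff,
                       min_seq_sep = min_seq_sep)
  # verify the planted interface
  ct <- contacts_table(model)
  inter <- ct[ct$chain_i != ct$chain_j, , drop = FALSE]
  touched <- sort(unique(c(inter$idx_i[inter$chain_i == "A"],
                           inter$idx_j[inter$chain_j == "A"])))
  if (!identical(touched, groove_positions)) {
    stop("geometrically infeasible request: ligand contacts receptor positions {",
         paste(touched, collapse = ","), "} instead of {",
         paste(groove_positions, collapse = ","), "}", call. = FALSE)
  }
  list(model = model, pdb = lines, groove = groove_positions)
}

#' Generate a synthetic alignment with planted group motifs
#'
#' Emulates a polymorphic receptor alignment: some columns fully conserved,
#' a small motif block whose residues are identical within each allele group
#' but differ between groups (KYRV-like lineage motifs), and the remaining
#' columns drawn uniformly at random from the 20 canonical amino acids.
#'
#' @param group_sizes Integer vector (one entry per group, default three
#'   groups of 10).
#' @param length Alignment width (default 30).
#' @param conserved Named character vector position -> fixed amino acid
#'   (default positions 1, 5, 10, 15, 20 fixed to C, W, G, P, D).
#' @param motif_positions Columns carrying the group motif
#'   (default 8, 9, 11, 14).
#' @param motifs List of per-group motif character vectors, one letter per
#'   motif position (defaults emulate a KYRV-like contrast).
#' @param seed Integer seed.
#' @return List with `msa` (an [msa()] object), `fasta` (text lines) and
#'   `groups` (named integer ground-truth group of each sequence).
#' @export
make_msa <- function(group_sizes = c(10L, 10L, 10L), length = 30L,
                     conserved = c(`1` = "C", `5` = "W", `10` = "G",
                                   `15` = "P", `20` = "D"),
                     motif_positions = c(8L, 9L, 11L, 14L),
                     motifs = list(c("K", "Y", "R", "V"),
                                   c("Q", "F", "T", "A"),
                                   c("E", "H", "S", "G")),
                     seed = 1L) {
  stopifnot(length(motifs) == length(group_sizes))
  stopifnot(all(lengths(motifs) == length(motif_positions)))
  cons_pos <- as.integer(names(conserved))
  if (length(intersect(cons_pos, motif_positions)) > 0L) {
    stop("conserved and motif positions must be disjoint", call. = FALSE)
  }
  n <- sum(group_sizes)
  groups <- rep(seq_along(group_sizes), group_sizes)
  labels <- sprintf("G%d_%02d", groups,
                    unlist(lapply(group_sizes, seq_len)))
  rows <- .with_seed(seed, {
    vapply(seq_len(n), function(s) {
      r <- sample(amino_acids(), length, replace = TRUE)
      r[cons_pos] <- unname(conserved)
      r[motif_positions] <- motifs[[groups[s]]]
      paste(r, collapse = "")
    }, character(1))
  })
  aln <- msa(labels, rows)
  fasta <- as.vector(rbind(paste0(">", labels), rows))
  list(msa = aln, fasta = fasta,
       groups = stats::setNames(groups, labels))
}

#' Generate a synthetic SRFI matrix with planted cluster structure
#'
#' Entries are group-specific mean offsets at the signal positions (zero
#' elsewhere) plus iid Gaussian noise, mimicking an allele panel whose
#' lineages differ in local frustration at a small set of positions.
#'
#' @param group_sizes Allele counts per group (default three groups of 30).
#' @param n_positions Total positions (default 60).
#' @param signal_positions Positions carrying group offsets (default the 14
#'   positions 4, 8, ..., 56).
#' @param offsets Per-group mean offset at signal positions
#'   (default -2, 0, +2).
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return List with `matrix` (an [srfi_matrix()]), `groups` (named integer
#'   ground truth) and `signal_positions` (character labels).
#' @export
make_srfi_matrix <- function(group_sizes = c(30L, 30L, 30L),
                             n_positions = 60L,
                             signal_positions = seq(4L, 56L, by = 4L),
                             offsets = c(-2, 0, 2),
                             noise_sd = 0.3, seed = 1L) {
  stopifnot(length(offsets) == length(group_sizes), noise_sd >= 0)
  signal_positions <- as.integer(signal_positions)
  if (any(signal_positions < 1L) || any(signal_positions > n_positions)) {
    stop("signal positions outside position range", call. = FALSE)
  }
  n <- sum(group_sizes)
  groups <- rep(seq_along(group_sizes), group_sizes)
  labels <- sprintf("allele_%03d", seq_len(n))
  base <- matrix(0, n, n_positions)
  base[, signal_positions] <- rep(offsets[groups],
                                  times = length(signal_positions))
  noise <- .with_seed(seed, matrix(stats::rnorm(n * n_positions,
                                                sd = noise_sd),
                                   n, n_positions))
  m <- srfi_matrix(base + noise, alleles = labels,
                   positions = as.character(seq_len(n_positions)))
  list(matrix = m, groups = stats::setNames(groups, labels),
       signal_positions = as.character(signal_positions))
}
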