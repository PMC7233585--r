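# Residue-level structure models: PDB parsing, contact maps, ligand stripping.

.AA_321 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

#' Read a coarse-grained structure model from a PDB file
#'
#' Parses ATOM records (HETATM are ignored) into one residue per
#' (chain, residue number), represented by the beta-carbon coordinate
#' (alpha-carbon for glycine, or as fallback when CB is absent). Residues
#' with a non-canonical type, or missing both CB and CA, are skipped with a
#' warning. Formal side-chain charges are attached from [aa_charge()].
#' Contacts are not computed; see [contact_map()].
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @return A `structure_model`: list with `residues` (data.frame with columns
#'   `chain`, `resno`, `aa`, `x`, `y`, `z`, `charge`) and `contacts`
#'   (`NULL` until [contact_map()] is applied).
#' @export
read_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  }
  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("no parsable ATOM records in input", call. = FALSE)
  )
  atoms <- parsed$atom[parsed$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no parsable ATOM records in input", call. = FALSE)
  ins <- atoms$insert
  if (any(!is.na(ins) & nzchar(trimws(ins)))) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  # keep the first altloc of each (chain, resno, atom name)
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  atoms <- atoms[!duplicated(key) | alt %in% c("", "A"), , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$elety)), ,
                 drop = FALSE]

  res_key <- paste(atoms$chain, atoms$resno)
  out <- vector("list", length(unique(res_key)))
  ui <- 0L
  for (k in unique(res_key)) {
    rows <- atoms[res_key == k, , drop = FALSE]
    aa3 <- rows$resid[1]
    aa1 <- .AA_321[aa3]
    if (is.na(aa1)) {
      warning("skipping non-canonical residue ", aa3, " at ", k, call. = FALSE)
      next
    }
    pick <- if (aa1 == "G") "CA" else "CB"
    hit <- which(rows$elety == pick)
    if (length(hit) == 0L) hit <- which(rows$elety == "CA")
    if (length(hit) == 0L) {
      warning("skipping residue at ", k, ": no CB or CA atom", call. = FALSE)
      next
    }
    r <- rows[hit[1], ]
    ui <- ui + 1L
    out[[ui]] <- data.frame(
      chain = r$chain, resno = as.integer(r$resno), aa = unname(aa1),
      x = r$x, y = r$y, z = r$z, stringsAsFactors = FALSE
    )
  }
  if (ui == 0L) stop("no canonical residues parsed from input", call. = FALSE)
  residues <- do.call(rbind, out[seq_len(ui)])
  residues$charge <- aa_charge(residues$aa)
  rownames(residues) <- NULL
  new_structure_model(residues)
}

new_structure_model <- function(residues, contacts = NULL) {
  stopifnot(is.data.frame(residues))
  if (anyDuplicated(paste(residues$chain, residues$resno))) {
    stop("duplicate (chain, residue number) pairs", call. = FALSE)
  }
  structure(list(residues = residues, contacts = contacts),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nc <- if (is.null(x$contacts)) "not computed" else nrow(x$contacts)
  cat(sprintf("structure_model: %d residues in %d chain(s); contacts: %s\n",
              nrow(x$residues), length(unique(x$residues$chain)), nc))
  invisible(x)
}

#' Compute the residue contact map
#'
#' All residue pairs within `cutoff` angstrom (Euclidean distance between
#' representative coordinates) become contacts, except same-chain pairs whose
#' sequence separation `|i - j|` is below `min_seq_sep`. Inter-chain pairs are
#' never excluded by sequence separation.
#'
#' @param model A `structure_model`.
#' @param cutoff Contact distance cutoff in angstrom (default 9.5).
#' @param min_seq_sep Minimum same-chain sequence separation (default 3).
#' @return The model with `contacts` populated: data.frame with residue row
#'   indices `i < j` and the distance `dist`.
#' @export
contact_map <- function(model, cutoff = 9.5, min_seq_sep = 3L) {
  stopifnot(inherits(model, "structure_model"))
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  res <- model$residues
  xyz <- as.matrix(res[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(res)
  keep <- matrix(FALSE, n, n)
  keep[upper.tri(keep)] <- TRUE
  keep <- keep & d <= cutoff
  same_chain <- outer(res$chain, res$chain, "==")
  sep <- abs(outer(res$resno, res$resno, "-"))
  keep <- keep & !(same_chain & sep < min_seq_sep)
  idx <- which(keep, arr.ind = TRUE)
  contacts <- data.frame(i = idx[, 1], j = idx[, 2],
                         dist = d[idx])
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  model$contacts <- contacts
  model
}

.find_residue <- function(model, chain, resno) {
  hit <- which(model$residues$chain == chain & model$residues$resno == resno)
  if (length(hit) != 1L) {
    stop("residue ", chain, ":", resno, " not in model", call. = FALSE)
  }
  hit
}

#' Local amino-acid density of a residue
#'
#' Number of residues in contact with the given residue — the coarse-grained
#' local packing descriptor. Requires [contact_map()] to have been applied.
#'
#' @param model A `structure_model` with contacts.
#' @param chain,resno Chain identifier and residue number.
#' @return Integer contact count.
#' @export
local_density <- function(model, chain, resno) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$contacts)) stop("contacts not computed", call. = FALSE)
  k <- .find_residue(model, chain, resno)
  sum(model$contacts$i == k | model$contacts$j == k)
}

#' Remove a ligand chain from a complex
#'
#' Drops every residue of `ligand_chain` and every contact touching it;
#' receptor coordinates and receptor-receptor contacts are untouched. This is
#' the "simple removal" route to a ligand-free receptor used for
#' binding-delta profiles.
#'
#' @param model A `structure_model`.
#' @param ligand_chain Chain identifier to remove.
#' @return A `structure_model` without the ligand chain.
#' @export
strip_ligand <- function(model, ligand_chain) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  drop <- which(res$chain == ligand_chain)
  if (length(drop) == 0L) {
    stop("chain '", ligand_chain, "' not present in model", call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(res)), drop)
  remap <- integer(nrow(res))
  remap[keep] <- seq_along(keep)
  out_res <- res[keep, , drop = FALSE]
  rownames(out_res) <- NULL
  contacts <- model$contacts
  if (!is.null(contacts)) {
    ok <- !(contacts$i %in% drop) & !(contacts$j %in% drop)
    contacts <- contacts[ok, , drop = FALSE]
    contacts$i <- remap[contacts$i]
    contacts$j <- remap[contacts$j]
    rownames(contacts) <- NULL
  }
  new_structure_model(out_res, contacts)
}

#' Export contacts as a tidy table
#'
#' @param model A `structure_model` with contacts.
#' @return data.frame with columns chain_i, idx_i, chain_j, idx_j, distance.
#' @export
contacts_table <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$contacts)) stop("contacts not computed", call. = FALSE)
  res <- model$residues
  cc <- model$contacts
  data.frame(
    chain_i = res$chain[cc$i], idx_i = res$resno[cc$i],
    chain_j = res$chain[cc$j], idx_j = res$resno[cc$j],
    distance = cc$dist, stringsAsFactors = FALSE
  )
}
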