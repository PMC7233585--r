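# Mutational decoy ensembles and frustration indices.
#
# A decoy keeps the native coordinates and contact topology and changes only
# the amino-acid identity (and hence charge) of one residue, or of both
# members of a contact pair. The frustration index is the z-score of the
# native total energy against the full decoy ensemble, oriented so that a
# native more stable than its decoys scores positive (minimal frustration).

.decoy_set <- function(native_energy, decoy_energies, scheme, site) {
  structure(list(native_energy = native_energy,
                 decoy_energies = decoy_energies,
                 scheme = scheme, site = site),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("decoy_set (%s) at %s: native %.4f, %d decoys in [%.4f, %.4f]\n",
              x$scheme, x$site, x$native_energy, length(x$decoy_energies),
              min(x$decoy_energies), max(x$decoy_energies)))
  invisible(x)
}

# all terms (rows of .energy_terms output) touching the given residue rows
.terms_touching <- function(terms, rows) {
  terms$i %in% rows | terms$j %in% rows
}

# energy of the terms in `sub` after substituting identities `aa_new` (named
# by residue row index) for the native identities
.substituted_sum <- function(sub, res, aa_new, params) {
  ai <- res$aa[sub$i]
  aj <- res$aa[sub$j]
  swap_i <- match(as.character(sub$i), names(aa_new))
  swap_j <- match(as.character(sub$j), names(aa_new))
  ai[!is.na(swap_i)] <- aa_new[swap_i[!is.na(swap_i)]]
  aj[!is.na(swap_j)] <- aa_new[swap_j[!is.na(swap_j)]]
  total <- sum(contact_energy(ai, aj, sub$dist, params))
  if (params$electrostatics_on) {
    total <- total + sum(debye_huckel_energy(aa_charge(ai), aa_charge(aj),
                                             sub$dist, params))
  }
  total
}

#' Single-residue mutational decoy energies
#'
#' Enumerates all 19 alternative identities at one site. Each decoy energy is
#' the full model total with every term touching the site recomputed for the
#' mutant identity (charge re-derived); coordinates and contacts unchanged.
#'
#' @param model A `structure_model` with contacts.
#' @param chain,resno Site identity.
#' @param params An `energy_params` object.
#' @return A `decoy_set` with 19 decoy energies (scheme `single_residue`).
#' @export
decoy_energies_single <- function(model, chain, resno,
                                  params = energy_params()) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$contacts)) stop("contacts not computed", call. = FALSE)
  k <- .find_residue(model, chain, resno)
  res <- model$residues
  terms <- .energy_terms(model, params)
  native_total <- sum(terms$contact_term) + sum(terms$elec_term)
  sub <- terms[.terms_touching(terms, k), , drop = FALSE]
  site_native <- sum(sub$contact_term) + sum(sub$elec_term)
  alts <- setdiff(amino_acids(), res$aa[k])
  decoys <- vapply(alts, function(m) {
    aa_new <- stats::setNames(m, as.character(k))
    native_total - site_native + .substituted_sum(sub, res, aa_new, params)
  }, numeric(1))
  .decoy_set(native_total, unname(decoys), "single_residue",
             paste0(chain, ":", resno))
}

#' Pairwise mutational decoy energies
#'
#' Enumerates all 19 x 19 = 361 simultaneous identity substitutions of both
#' members of a contact. Each decoy energy includes the mutual term and every
#' term either residue makes with third parties.
#'
#' @param model A `structure_model` with contacts.
#' @param chain_i,resno_i,chain_j,resno_j The two residues; they must be in
#'   contact.
#' @param params An `energy_params` object.
#' @return A `decoy_set` with 361 decoy energies (scheme `pair`).
#' @export
decoy_energies_pair <- function(model, chain_i, resno_i, chain_j, resno_j,
                                params = energy_params()) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$contacts)) stop("contacts not computed", call. = FALSE)
  ki <- .find_residue(model, chain_i, resno_i)
  kj <- .find_residue(model, chain_j, resno_j)
  cc <- model$contacts
  if (!any((cc$i == min(ki, kj)) & (cc$j == max(ki, kj)))) {
    stop("residues are not in contact", call. = FALSE)
  }
  res <- model$residues
  terms <- .energy_terms(model, params)
  native_total <- sum(terms$contact_term) + sum(terms$elec_term)
  sub <- terms[.terms_touching(terms, c(ki, kj)), , drop = FALSE]
  site_native <- sum(sub$contact_term) + sum(sub$elec_term)
  alts_i <- setdiff(amino_acids(), res$aa[ki])
  alts_j <- setdiff(amino_acids(), res$aa[kj])
  grid <- expand.grid(mi = alts_i, mj = alts_j, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  decoys <- vapply(seq_len(nrow(grid)), function(g) {
    aa_new <- stats::setNames(c(grid$mi[g], grid$mj[g]),
                              as.character(c(ki, kj)))
    native_total - site_native + .substituted_sum(sub, res, aa_new, params)
  }, numeric(1))
  .decoy_set(native_total, decoys, "pair",
             paste0(chain_i, ":", resno_i, "-", chain_j, ":", resno_j))
}

#' Frustration index of a decoy ensemble
#'
#' z-score of the native energy against the decoy ensemble,
#' \deqn{F = \frac{\langle E_{decoy} \rangle - E_{native}}{\sigma(E_{decoy})}}
#' with the population (1/N) standard deviation. A native more stable than
#' its decoys gives a positive index (minimal frustration); a native less
#' stable gives a negative index (high frustration). A degenerate ensemble
#' (zero decoy variance) yields `NA` with a warning naming the site.
#'
#' @param decoys A `decoy_set`.
#' @return Numeric index, or `NA` for a degenerate ensemble.
#' @export
frustration_index <- function(decoys) {
  stopifnot(inherits(decoys, "decoy_set"))
  e <- decoys$decoy_energies
  m <- mean(e)
  sd_pop <- sqrt(mean((e - m)^2))
  scale <- max(abs(e), abs(decoys$native_energy), 1)
  if (sd_pop <= 1e-12 * scale) {
    warning("zero decoy variance at site ", decoys$site,
            "; frustration index undefined", call. = FALSE)
    return(NA_real_)
  }
  (m - decoys$native_energy) / sd_pop
}

#' Classify a frustration index value
#'
#' Values above `high` are minimally frustrated, below `low` highly
#' frustrated, and the closed band `[low, high]` (default -1 to 1) is
#' neutral. `NA` values classify as `NA`.
#'
#' @param value Numeric vector of frustration indices.
#' @param low,high Neutral band bounds (defaults -1 and 1; inclusive).
#' @return Character vector in \{"minimal", "neutral", "high"\}.
#' @export
classify_frustration <- function(value, low = -1, high = 1) {
  if (!(low < high)) stop("require low < high", call. = FALSE)
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value > high] <- "minimal"
  out[!is.na(value) & value < low] <- "high"
  out[!is.na(value) & value >= low & value <= high] <- "neutral"
  out
}

#' Single Residue Frustration Index profile of a structure
#'
#' Computes the SRFI (single-site mutational z-score) for every residue, and
#' optionally the pairwise mutational index for every contact, plus the
#' frustration classification. Fully deterministic.
#'
#' @param model A `structure_model` with contacts.
#' @param params An `energy_params` object.
#' @param include_pair Also compute per-contact pair indices? (default TRUE)
#' @param low,high Neutral classification band.
#' @return A `frustration_profile`: list with `per_residue` (data.frame
#'   chain, resno, aa, srfi, class) and `per_contact` (data.frame or NULL).
#' @export
srfi_profile <- function(model, params = energy_params(),
                         include_pair = TRUE, low = -1, high = 1) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$contacts)) stop("contacts not computed", call. = FALSE)
  res <- model$residues
  srfi <- vapply(seq_len(nrow(res)), function(k) {
    ds <- decoy_energies_single(model, res$chain[k], res$resno[k], params)
    frustration_index(ds)
  }, numeric(1))
  per_residue <- data.frame(
    chain = res$chain, resno = res$resno, aa = res$aa,
    srfi = srfi, class = classify_frustration(srfi, low, high),
    stringsAsFactors = FALSE
  )
  per_contact <- NULL
  if (include_pair && nrow(model$contacts) > 0L) {
    cc <- model$contacts
    fij <- vapply(seq_len(nrow(cc)), function(g) {
      ds <- decoy_energies_pair(model, res$chain[cc$i[g]], res$resno[cc$i[g]],
                                res$chain[cc$j[g]], res$resno[cc$j[g]], params)
      frustration_index(ds)
    }, numeric(1))
    per_contact <- data.frame(
      chain_i = res$chain[cc$i], idx_i = res$resno[cc$i],
      chain_j = res$chain[cc$j], idx_j = res$resno[cc$j],
      dist = cc$dist, f_mut = fij,
      class = classify_frustration(fij, low, high),
      stringsAsFactors = FALSE
    )
  }
  structure(list(per_residue = per_residue, per_contact = per_contact),
            class = "frustration_profile")
}

#' @export
print.frustration_profile <- function(x, ...) {
  tab <- table(factor(x$per_residue$class,
                      levels = c("minimal", "neutral", "high")))
  cat(sprintf(
    "frustration_profile: %d residues (%d minimal / %d neutral / %d high)\n",
    nrow(x$per_residue), tab["minimal"], tab["neutral"], tab["high"]))
  invisible(x)
}

#' Write a frustration profile as TSV
#'
#' @param profile A `frustration_profile`.
#' @param path Output path for the per-residue table.
#' @param contacts_path Optional output path for the per-contact table.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, contacts_path = NULL) {
  stopifnot(inherits(profile, "frustration_profile"))
  .write_tsv(profile$per_residue, path)
  if (!is.null(contacts_path) && !is.null(profile$per_contact)) {
    .write_tsv(profile$per_contact, contacts_path)
  }
  invisible(path)
}

# deterministic TSV writer (fixed significant digits so re-runs are
# byte-identical)
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "NA", sprintf("%.10g", v))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
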