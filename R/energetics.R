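# Coarse-grained pair energetics: tabulated contact term with a distance
# taper, plus optional Debye-Huckel screened electrostatics.

#' Default hydrophobicity-based contact matrix
#'
#' The 20x20 symmetric pair potential shipped with the package
#' (`inst/extdata/kd_contact_matrix.tsv`), built from Kyte-Doolittle
#' hydropathy h as
#' \deqn{e(a,b) = -\frac{h_a h_b}{s^2} + \gamma \left(\frac{h_a-h_b}{s}\right)^2}
#' with s = 4.5 (the hydropathy scale maximum) and gamma = 0.5. The product
#' term rewards hydrophobic-hydrophobic burial; the mismatch term penalises
#' pairing residues of very different hydropathy, making the potential
#' non-separable so that mutational decoy ensembles carry informative
#' variance. Units are arbitrary; all frustration indices are z-scores and
#' therefore scale-free. The frustration machinery accepts any symmetric
#' matrix in its place.
#'
#' @return Named symmetric 20x20 numeric matrix over [amino_acids()].
#' @export
default_contact_matrix <- function() {
  path <- system.file("extdata", "kd_contact_matrix.tsv", package = "locfrust")
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE, sep = "\t"))
  storage.mode(m) <- "double"
  m
}

#' Energy model parameters
#'
#' Bundles the contact matrix, the distance switching bounds of the contact
#' term, and the Debye-Huckel constants.
#'
#' @param contact_matrix Symmetric 20x20 matrix over [amino_acids()].
#' @param r_full Distance (angstrom) up to which a contact has full weight.
#' @param r_cut Distance at which the contact weight reaches zero; also the
#'   default contact-map cutoff.
#' @param k_elect Electrostatic constant k = K_elect / eps_r; 4.15
#'   corresponds to an aqueous solution.
#' @param debye_length Screening length l_D in angstrom (10 at physiological
#'   temperature, eps_r = 80 and ionic strength 0.1 M; see [debye_length()]).
#' @param electrostatics_on Include the screened electrostatic term?
#' @return An `energy_params` object.
#' @export
energy_params <- function(contact_matrix = default_contact_matrix(),
                          r_full = 6.5, r_cut = 9.5,
                          k_elect = 4.15, debye_length = 10,
                          electrostatics_on = TRUE) {
  aas <- amino_acids()
  stopifnot(is.matrix(contact_matrix),
            all(dim(contact_matrix) == c(20L, 20L)))
  contact_matrix <- contact_matrix[aas, aas]
  if (max(abs(contact_matrix - t(contact_matrix))) > 1e-12) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  if (!(r_full > 0 && r_full <= r_cut)) {
    stop("require 0 < r_full <= r_cut", call. = FALSE)
  }
  if (debye_length <= 0) stop("debye_length must be positive", call. = FALSE)
  structure(list(contact_matrix = contact_matrix, r_full = r_full,
                 r_cut = r_cut, k_elect = k_elect,
                 debye_length = debye_length,
                 electrostatics_on = isTRUE(electrostatics_on)),
            class = "energy_params")
}

#' Read / write energy parameters as JSON
#'
#' @param path File path.
#' @param params An `energy_params` object.
#' @return `read_energy_params` returns an `energy_params` object;
#'   `write_energy_params` returns `path` invisibly.
#' @export
read_energy_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.matrix(x$contact_matrix)
  dimnames(m) <- list(amino_acids(), amino_acids())
  energy_params(contact_matrix = m, r_full = x$r_full, r_cut = x$r_cut,
                k_elect = x$k_elect, debye_length = x$debye_length,
                electrostatics_on = x$electrostatics_on)
}

#' @rdname read_energy_params
#' @export
write_energy_params <- function(params, path) {
  stopifnot(inherits(params, "energy_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# linear switching weight: 1 up to r_full, tapering to 0 at r_cut
.contact_weight <- function(r, params) {
  w <- (params$r_cut - r) / (params$r_cut - params$r_full)
  w[r <= params$r_full] <- 1
  w[r >= params$r_cut] <- 0
  if (params$r_cut == params$r_full) w <- as.numeric(r <= params$r_full)
  w
}

#' Tabulated contact energy of a residue pair
#'
#' `contact_matrix[aa_i, aa_j]` weighted by a linear distance taper: full
#' weight up to `r_full`, linearly decaying to zero at `r_cut`, zero beyond.
#'
#' @param aa_i,aa_j One-letter amino-acid codes.
#' @param r_ij Pair distance in angstrom.
#' @param params An `energy_params` object.
#' @return Numeric energy (vectorised over equal-length inputs).
#' @export
contact_energy <- function(aa_i, aa_j, r_ij, params = energy_params()) {
  stop_if_noncanonical(c(aa_i, aa_j))
  stopifnot(all(r_ij > 0))
  params$contact_matrix[cbind(aa_i, aa_j)] * .contact_weight(r_ij, params)
}

#' Debye-Huckel screened electrostatic energy
#'
#' \deqn{V_{DH} = k \, \frac{q_i q_j}{r_{ij}} e^{-r_{ij}/l_D}}
#' with k the electrostatic constant (K_elect / eps_r) and l_D the Debye
#' screening length.
#'
#' @param q_i,q_j Integer formal charges.
#' @param r_ij Pair distance in angstrom.
#' @param params An `energy_params` object.
#' @return Numeric energy (vectorised).
#' @export
debye_huckel_energy <- function(q_i, q_j, r_ij, params = energy_params()) {
  stopifnot(all(r_ij > 0))
  params$k_elect * q_i * q_j / r_ij * exp(-r_ij / params$debye_length)
}

#' Debye screening length from solution conditions
#'
#' \deqn{l_D = \sqrt{\frac{\epsilon_0 \epsilon_r k_B T}{2 N_A e^2 \cdot 10^3 I}}}
#' returned in angstrom. At 25 C, eps_r = 80 and ionic strength 0.1 M this
#' gives ~9.7 A, conventionally rounded to 10 A.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param eps_r Relative dielectric constant (dimensionless).
#' @param ionic_strength Ionic strength in mol/L.
#' @return Screening length in angstrom.
#' @export
debye_length <- function(temperature = 298.15, eps_r = 80,
                         ionic_strength = 0.1) {
  if (any(c(temperature, eps_r, ionic_strength) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  NA_ <- 6.02214076e23       # 1/mol
  e <- 1.602176634e-19       # C
  lm <- sqrt(eps0 * eps_r * kB * temperature /
               (2 * NA_ * e^2 * ionic_strength * 1e3))
  lm * 1e10
}

# Per-contact energy terms for a model with computed contacts.
# Returns a data.frame: i, j, dist, contact_term, elec_term.
.energy_terms <- function(model, params) {
  cc <- model$contacts
  res <- model$residues
  if (nrow(cc) == 0L) {
    return(data.frame(i = integer(), j = integer(), dist = numeric(),
                      contact_term = numeric(), elec_term = numeric()))
  }
  ct <- contact_energy(res$aa[cc$i], res$aa[cc$j], cc$dist, params)
  et <- if (params$electrostatics_on) {
    debye_huckel_energy(res$charge[cc$i], res$charge[cc$j], cc$dist, params)
  } else {
    numeric(nrow(cc))
  }
  data.frame(i = cc$i, j = cc$j, dist = cc$dist,
             contact_term = ct, elec_term = et)
}

#' Total coarse-grained energy of a structure model
#'
#' Sums the tabulated contact term over all contacts, plus (when
#' `electrostatics_on`) the Debye-Huckel term over the same contact pairs.
#'
#' @param model A `structure_model` with contacts.
#' @param params An `energy_params` object.
#' @return An `energy_breakdown`: list with `total` and `per_contact`
#'   (data.frame of per-pair contact and electrostatic terms).
#' @export
total_energy <- function(model, params = energy_params()) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$contacts)) stop("contacts not computed", call. = FALSE)
  terms <- .energy_terms(model, params)
  structure(list(total = sum(terms$contact_term) + sum(terms$elec_term),
                 per_contact = terms),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy_breakdown: total %.4f over %d contacts\n",
              x$total, nrow(x$per_contact)))
  invisible(x)
}
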