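# Independent oracles and in-code fixtures. The oracles deliberately share
# no code with the package internals: distances, switching weights and the
# screened electrostatic term are recomputed from first principles.

ORACLE_CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0,
                   K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
                   T = 0, V = 0, W = 0, Y = 0)

# brute-force total energy from coordinates and sequence alone
naive_total_energy <- function(model, params, cutoff = 9.5,
                               min_seq_sep = 3L) {
  res <- model$residues
  n <- nrow(res)
  total <- 0
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d <- sqrt(sum((c(res$x[a], res$y[a], res$z[a]) -
                     c(res$x[b], res$y[b], res$z[b]))^2))
      if (d > cutoff) next
      if (res$chain[a] == res$chain[b] &&
          abs(res$resno[a] - res$resno[b]) < min_seq_sep) next
      w <- if (d <= params$r_full) 1
           else if (d >= params$r_cut) 0
           else (params$r_cut - d) / (params$r_cut - params$r_full)
      total <- total + params$contact_matrix[res$aa[a], res$aa[b]] * w
      if (params$electrostatics_on) {
        qa <- ORACLE_CHARGE[res$aa[a]]
        qb <- ORACLE_CHARGE[res$aa[b]]
        total <- total + params$k_elect * qa * qb / d *
          exp(-d / params$debye_length)
      }
    }
  }
  unname(total)
}

# swap a residue identity (and charge), keeping coordinates
mutate_model <- function(model, k, aa) {
  model$residues$aa[k] <- aa
  model$residues$charge[k] <- aa_charge(aa)
  model
}

# build a structure model directly from a coordinate table
model_from_coords <- function(chain, resno, aa, xyz, cutoff = 9.5,
                              min_seq_sep = 3L) {
  res <- data.frame(chain = chain, resno = as.integer(resno), aa = aa,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    charge = aa_charge(aa), stringsAsFactors = FALSE)
  contact_map(locfrust:::new_structure_model(res), cutoff = cutoff,
              min_seq_sep = min_seq_sep)
}

# compact random fixture: n residues of one chain in a small box
random_model <- function(n, seed, chain = "A") {
  set.seed(seed)
  model_from_coords(rep(chain, n), seq_len(n),
                    sample(amino_acids(), n, replace = TRUE),
                    matrix(runif(3 * n, 0, 12), ncol = 3))
}

# naive O(N^3) single-linkage agglomeration; returns merge heights (sorted)
# and the cophenetic distance matrix, which is tie-invariant
naive_single_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        link <- min(d[clusters[[a]], clusters[[b]]])
        if (link < best_d) {
          best_d <- link
          best <- c(a, b)
        }
      }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# minimal PDB text for parser tests
pdb_line <- function(serial, name, aa3, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, aa3, chain, resno, x, y, z, 1, 0)
}
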