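params0 <- energy_params()

test_that("single-residue decoys enumerate the 19 alternatives exactly", {
  m <- random_model(5, seed = 1)
  ds <- decoy_energies_single(m, "A", 3, params0)
  expect_s3_class(ds, "decoy_set")
  expect_length(ds$decoy_energies, 19L)
  expect_equal(ds$scheme, "single_residue")
  # substituting the native identity back reproduces the native energy
  k <- 3L
  native_again <- mutate_model(m, k, m$residues$aa[k])
  expect_equal(ds$native_energy, total_energy(native_again, params0)$total)
})

test_that("single decoy energies equal brute-force recomputation per mutant", {
  for (seed in c(4, 8, 15)) {
    m <- random_model(sample(3:10, 1), seed)
    n <- nrow(m$residues)
    k <- ((seed * 7) %% n) + 1L
    ds <- decoy_energies_single(m, m$residues$chain[k], m$residues$resno[k],
                                params0)
    alts <- setdiff(amino_acids(), m$residues$aa[k])
    brute <- vapply(alts, function(aa) {
      naive_total_energy(mutate_model(m, k, aa), params0)
    }, numeric(1))
    expect_equal(ds$decoy_energies, unname(brute), tolerance = 1e-9)
    expect_equal(ds$native_energy, naive_total_energy(m, params0),
                 tolerance = 1e-9)
  }
})

test_that("pair decoys enumerate 361 double mutants matching brute force", {
  # triangle fixture: three mutually contacting residues
  tri <- model_from_coords(c("A", "B", "D"), rep(1L, 3), c("I", "D", "K"),
                           rbind(c(0, 0, 0), c(6, 0, 0), c(3, 5, 0)))
  expect_equal(nrow(tri$contacts), 3L)
  ds <- decoy_energies_pair(tri, "A", 1, "B", 1, params0)
  expect_length(ds$decoy_energies, 361L)
  grid <- expand.grid(mi = setdiff(amino_acids(), "I"),
                      mj = setdiff(amino_acids(), "D"),
                      stringsAsFactors = FALSE)
  brute <- vapply(seq_len(nrow(grid)), function(g) {
    naive_total_energy(mutate_model(mutate_model(tri, 1L, grid$mi[g]),
                                    2L, grid$mj[g]), params0)
  }, numeric(1))
  expect_equal(ds$decoy_energies, brute, tolerance = 1e-9)

  # isolated pair: decoy energies reduce to the mutual term alone
  pair <- model_from_coords(c("A", "B"), c(1L, 1L), c("I", "L"),
                            rbind(c(0, 0, 0), c(5, 0, 0)))
  dp <- decoy_energies_pair(pair, "A", 1, "B", 1, params0)
  g2 <- expand.grid(mi = setdiff(amino_acids(), "I"),
                    mj = setdiff(amino_acids(), "L"),
                    stringsAsFactors = FALSE)
  mutual <- vapply(seq_len(nrow(g2)), function(g) {
    contact_energy(g2$mi[g], g2$mj[g], 5, params0) +
      debye_huckel_energy(aa_charge(g2$mi[g]), aa_charge(g2$mj[g]), 5,
                          params0)
  }, numeric(1))
  expect_equal(dp$decoy_energies, mutual, tolerance = 1e-9)
  expect_error(decoy_energies_pair(pair, "A", 1, "A", 1, params0))
})

test_that("frustration index is the decoy-minus-native z-score with 1/N variance", {
  mk <- function(native, decoys) {
    structure(list(native_energy = native, decoy_energies = decoys,
                   scheme = "single_residue", site = "A:1"),
              class = "decoy_set")
  }
  expect_equal(frustration_index(mk(0, c(-2, 0, 2))), 0)
  expect_equal(frustration_index(mk(-1, c(-1, 0, 1))), 1 / sqrt(2 / 3))
  # shift invariance
  expect_equal(frustration_index(mk(-1 + 7, c(-1, 0, 1) + 7)),
               frustration_index(mk(-1, c(-1, 0, 1))))
  expect_warning(out <- frustration_index(mk(1, rep(1, 19))),
                 "zero decoy variance")
  expect_true(is.na(out))
})

test_that("classification uses the closed neutral band", {
  expect_equal(classify_frustration(0), "neutral")
  expect_equal(classify_frustration(1.5), "minimal")
  expect_equal(classify_frustration(-1.2), "high")
  expect_equal(classify_frustration(c(1, -1)), c("neutral", "neutral"))
  expect_true(is.na(classify_frustration(NA_real_)))
  expect_error(classify_frustration(0, low = 1, high = -1), "low < high")
})

test_that("an optimal occupant maximizes SRFI for its environment", {
  # site 1 surrounded by hydrophobic partners; isoleucine is the contact
  # matrix optimum there
  env <- model_from_coords(c("A", "B", "D"), rep(1L, 3), c("I", "I", "L"),
                           rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)))
  srfi_by_occupant <- vapply(amino_acids(), function(aa) {
    m <- mutate_model(env, 1L, aa)
    frustration_index(decoy_energies_single(m, "A", 1, params0))
  }, numeric(1))
  expect_equal(names(which.max(srfi_by_occupant)), "I")
  prof <- srfi_profile(env, params0, include_pair = FALSE)
  expect_equal(prof$per_residue$srfi[1], srfi_by_occupant[["I"]])
  # a strongly suboptimal occupant is negatively frustrated
  bad <- mutate_model(env, 1L, "R")
  expect_lt(frustration_index(decoy_energies_single(bad, "A", 1, params0)), 0)
})

test_that("SRFI is invariant under positive affine rescaling of the energy model", {
  for (seed in 1:5) {
    m <- random_model(7, seed)
    base <- suppressWarnings(
      srfi_profile(m, params0, include_pair = FALSE))$per_residue$srfi
    c_scale <- 1.7
    shift <- 0.4
    p2 <- energy_params(
      contact_matrix = c_scale * params0$contact_matrix + shift,
      k_elect = c_scale * params0$k_elect
    )
    rescaled <- suppressWarnings(
      srfi_profile(m, p2, include_pair = FALSE))$per_residue$srfi
    expect_equal(rescaled, base, tolerance = 1e-9)
  }
})

test_that("profiles are deterministic and degenerate sites propagate as NA", {
  m <- random_model(6, seed = 21)
  p1 <- suppressWarnings(srfi_profile(m, params0))
  p2 <- suppressWarnings(srfi_profile(m, params0))
  expect_identical(p1, p2)
  expect_true(all(c("per_residue", "per_contact") %in% names(p1)))
  expect_equal(nrow(p1$per_contact), nrow(m$contacts))

  iso <- model_from_coords("A", 1L, "A", rbind(c(0, 0, 0)))
  expect_warning(p <- srfi_profile(iso, params0), "zero decoy variance")
  expect_true(is.na(p$per_residue$srfi))
  expect_true(is.na(p$per_residue$class))
})
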