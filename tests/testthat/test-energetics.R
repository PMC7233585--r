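params0 <- energy_params()

test_that("contact energy is symmetric, tapered, and zero beyond the cutoff", {
  aas <- amino_acids()
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(aas, 1)
    b <- sample(aas, 1)
    r <- runif(1, 1, 12)
    expect_identical(contact_energy(a, b, r, params0),
                     contact_energy(b, a, r, params0))
  }
  expect_equal(contact_energy("I", "L", 11.0, params0), 0)
  # taper midpoint carries half the full weight
  mid <- (params0$r_full + params0$r_cut) / 2
  expect_equal(contact_energy("I", "L", mid, params0),
               0.5 * contact_energy("I", "L", 2.0, params0))
  expect_error(contact_energy("X", "A", 5, params0), "non-canonical")
})

test_that("Debye-Huckel term follows the screened Coulomb form", {
  expect_equal(debye_huckel_energy(0, 1, 5, params0), 0)
  expect_equal(debye_huckel_energy(1, 1, 10, params0),
               4.15 * (1 / 10) * exp(-1))
  r <- 7.3
  expect_equal(debye_huckel_energy(1, -1, r, params0),
               -debye_huckel_energy(1, 1, r, params0))
  # monotone decay to zero in r for fixed charges
  rs <- seq(2, 30, by = 0.5)
  v <- debye_huckel_energy(1, 1, rs, params0)
  expect_true(all(diff(v) < 0))
})

test_that("Debye length reproduces the standard closed form", {
  l <- debye_length(298.15, 80, 0.1)
  expect_equal(round(l), 10)
  expect_lt(abs(l - 9.71), 0.02)
  # inverse square-root scaling with ionic strength
  expect_equal(debye_length(298.15, 80, 0.4), l / 2)
  expect_equal(debye_length(298.15, 80, 0.025), 2 * l)
  expect_error(debye_length(-1, 80, 0.1), "positive")
})

test_that("total energy matches a brute-force term-by-term oracle", {
  m <- model_from_coords(rep("A", 4), c(1L, 5L, 9L, 13L),
                         c("D", "K", "I", "L"),
                         rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0),
                               c(0, 5, 2)))
  e <- total_energy(m, params0)
  expect_equal(e$total, naive_total_energy(m, params0), tolerance = 1e-12)
  expect_equal(e$total,
               sum(e$per_contact$contact_term) + sum(e$per_contact$elec_term))

  for (seed in c(2, 9, 17)) {
    rm <- random_model(8, seed)
    expect_equal(total_energy(rm, params0)$total,
                 naive_total_energy(rm, params0), tolerance = 1e-9)
  }
})

test_that("total energy is additive over disjoint domains and zero without contacts", {
  empty <- model_from_coords("A", 1L, "I", rbind(c(0, 0, 0)))
  expect_equal(total_energy(empty, params0)$total, 0)

  d1 <- model_from_coords(c("A", "B"), c(1L, 1L), c("I", "L"),
                          rbind(c(0, 0, 0), c(5, 0, 0)))
  d2 <- model_from_coords(c("D", "E"), c(1L, 1L), c("K", "E"),
                          rbind(c(100, 0, 0), c(105, 0, 0)))
  both <- model_from_coords(c("A", "B", "D", "E"), rep(1L, 4),
                            c("I", "L", "K", "E"),
                            rbind(c(0, 0, 0), c(5, 0, 0),
                                  c(100, 0, 0), c(105, 0, 0)))
  expect_equal(total_energy(both, params0)$total,
               total_energy(d1, params0)$total +
                 total_energy(d2, params0)$total)
})

test_that("energy is invariant under rigid-body motion and scales with the matrix", {
  m <- random_model(7, seed = 5)
  e0 <- total_energy(m, params0)$total
  # rotate about z by 40 degrees then translate
  th <- 40 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- as.matrix(m$residues[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, c(3, -7, 11), "+")
  m2 <- model_from_coords(m$residues$chain, m$residues$resno,
                          m$residues$aa, xyz)
  expect_equal(total_energy(m2, params0)$total, e0, tolerance = 1e-9)

  p_off <- energy_params(electrostatics_on = FALSE)
  p_scaled <- energy_params(contact_matrix = 3 * p_off$contact_matrix,
                            electrostatics_on = FALSE)
  expect_equal(total_energy(m, p_scaled)$total,
               3 * total_energy(m, p_off)$total, tolerance = 1e-12)
})

test_that("energy parameter files round-trip through JSON", {
  p <- energy_params(k_elect = 2.5, debye_length = 8)
  f <- tempfile(fileext = ".json")
  write_energy_params(p, f)
  q <- read_energy_params(f)
  expect_equal(q$contact_matrix, p$contact_matrix)
  expect_equal(q$k_elect, 2.5)
  expect_equal(q$debye_length, 8)
  expect_error(energy_params(r_full = 10, r_cut = 9.5), "r_full")
})
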