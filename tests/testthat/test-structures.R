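test_that("parser keeps one representative atom per residue with glycine CA fallback", {
  lines <- c(
    pdb_line(1, " CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CB", "ALA", "A", 1, 0.5, 0, 0),
    pdb_line(3, " CA", "GLY", "A", 2, 3, 0, 0),
    "END"
  )
  m <- read_structure(lines)
  expect_equal(nrow(m$residues), 2L)
  expect_equal(m$residues$aa, c("A", "G"))
  expect_equal(m$residues$x, c(0.5, 3))  # ALA uses CB, GLY falls back to CA
})

test_that("chains are tracked separately and charges follow the residue type", {
  lines <- c(
    pdb_line(1, " CB", "ASP", "A", 1, 0, 0, 0),
    pdb_line(2, " CB", "LYS", "A", 2, 4, 0, 0),
    "TER",
    pdb_line(3, " CB", "ALA", "C", 1, 8, 0, 0),
    "END"
  )
  m <- read_structure(lines)
  expect_equal(m$residues$chain, c("A", "A", "C"))
  expect_equal(m$residues$resno, c(1L, 2L, 1L))
  expect_equal(m$residues$charge, c(-1L, 1L, 0L))
})

test_that("parser rejects unusable input and skips non-canonical residues", {
  expect_error(read_structure(c("REMARK nothing here", "END")), "ATOM")
  lines <- c(
    pdb_line(1, " CB", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CB", "MSE", "A", 2, 4, 0, 0),
    "END"
  )
  expect_warning(m <- read_structure(lines), "non-canonical")
  expect_equal(nrow(m$residues), 1L)
})

test_that("contact map applies the cutoff and same-chain sequence separation", {
  # two chains 5 A apart: contact despite adjacency in numbering
  m <- model_from_coords(c("A", "C"), c(1, 1), c("A", "A"),
                         rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(m$contacts), 1L)

  # same-chain neighbors at 4 A are excluded by min_seq_sep = 3
  m2 <- model_from_coords(c("A", "A"), c(1, 2), c("A", "A"),
                          rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(nrow(m2$contacts), 0L)

  # collinear residues spaced 20 A: nothing within the cutoff
  m3 <- model_from_coords(rep("A", 3), 1:3, rep("A", 3),
                          cbind(c(0, 20, 40), 0, 0), min_seq_sep = 1L)
  expect_equal(nrow(m3$contacts), 0L)

  expect_error(contact_map(m, cutoff = -1), "positive")
})

test_that("contact map is idempotent and symmetric in its distance relation", {
  m <- random_model(8, seed = 11)
  m2 <- contact_map(m)
  expect_identical(m$contacts, m2$contacts)
  expect_true(all(m$contacts$i < m$contacts$j))
  expect_true(all(m$contacts$dist <= 9.5))
})

test_that("local density counts contacts and satisfies the handshake identity", {
  # 5-contact star: hub at origin, 5 satellites within the cutoff of the hub
  # (9 A) but ~12.7 A or more from each other
  sat <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5), c(-5, 0, 0), c(0, -5, 0))
  m <- model_from_coords(c("A", rep("B", 5)), c(1L, c(1L, 4L, 7L, 10L, 13L)),
                         rep("A", 6), rbind(c(0, 0, 0), sat * 1.8))
  expect_equal(local_density(m, "A", 1), 5L)
  dens <- vapply(seq_len(6), function(k) {
    local_density(m, m$residues$chain[k], m$residues$resno[k])
  }, integer(1))
  expect_equal(sum(dens), 2L * nrow(m$contacts))
  expect_error(local_density(m, "Z", 99), "not in model")

  iso <- model_from_coords("A", 1, "A", rbind(c(0, 0, 0)))
  expect_equal(local_density(iso, "A", 1), 0L)
})

test_that("stripping the ligand removes its residues and only its contacts", {
  cx <- make_complex()
  stripped <- strip_ligand(cx$model, "C")
  expect_false("C" %in% stripped$residues$chain)
  expect_error(strip_ligand(cx$model, "Z"), "not present")

  # receptor-receptor contacts identical before and after
  rec_before <- contacts_table(cx$model)
  rec_before <- rec_before[rec_before$chain_i == "A" &
                             rec_before$chain_j == "A", ]
  rec_after <- contacts_table(stripped)
  rownames(rec_before) <- rownames(rec_after) <- NULL
  expect_equal(rec_after, rec_before)

  # exactly the groove residues lose contacts
  dens_before <- vapply(1:30, function(i) local_density(cx$model, "A", i),
                        integer(1))
  dens_after <- vapply(1:30, function(i) local_density(stripped, "A", i),
                       integer(1))
  expect_equal(which(dens_before != dens_after), c(7L, 8L, 9L))
})

test_that("stripping commutes with contact-map computation", {
  cx <- make_complex()
  a <- contact_map(strip_ligand(cx$model, "C"))
  b <- strip_ligand(contact_map(cx$model), "C")
  expect_equal(a$contacts, b$contacts)
})
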