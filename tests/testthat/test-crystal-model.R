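test_that("a single ATOM record round-trips through the PDB reader", {
  txt <- paste(pdb_line(1, "CA", "GLY", "A", 1, 1.0, 2.0, 3.0, element = "C"),
               "END", sep = "\n")
  a <- read_structure(txt, text = TRUE)
  expect_s3_class(a, "atom_set")
  expect_equal(n_atoms(a), 1L)
  expect_equal(as.vector(coords(a)), c(1, 2, 3))
  expect_equal(a$element, "C")
})

test_that("multi-model PDB text yields an ensemble with a shared roster", {
  txt <- paste("MODEL        1",
               pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
               "ENDMDL",
               "MODEL        2",
               pdb_line(1, "CA", "GLY", "A", 1, 1, 1, 1, element = "C"),
               "ENDMDL", "END", sep = "\n")
  e <- read_structure(txt, text = TRUE)
  expect_s3_class(e, "ensemble")
  expect_equal(n_frames(e), 2L)
  expect_equal(coords(ensemble_frame(e, 2)), matrix(c(1, 1, 1), 1))
})

test_that("element falls back to atom-name inference and unknowns error", {
  txt <- paste(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "  "),
               "END", sep = "\n")
  a <- read_structure(txt, text = TRUE)
  expect_equal(a$element, "C")
  bad <- paste(pdb_line(1, "XQ7", "UNK", "A", 1, 0, 0, 0, element = "  "),
               "END", sep = "\n")
  expect_error(read_structure(bad, text = TRUE), "element")
})

test_that("waters and ions get per-residue molecule indices", {
  txt <- paste(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
               pdb_line(2, "CA", "ALA", "A", 2, 3, 0, 0, element = "C"),
               pdb_line(3, "O", "HOH", "W", 11, 9, 0, 0, element = "O", het = TRUE),
               pdb_line(4, "O", "HOH", "W", 12, 12, 0, 0, element = "O", het = TRUE),
               pdb_line(5, "CL", "CL", "I", 21, 15, 0, 0, element = "CL", het = TRUE),
               "END", sep = "\n")
  a <- read_structure(txt, text = TRUE)
  expect_equal(length(unique(a$mol)), 4L)        # 1 chain + 2 waters + 1 ion
  expect_equal(length(unique(a$mol[a$resname == "HOH"])), 2L)
})

test_that("CRYST1 cell and space-group name are attached when present", {
  txt <- paste(
    "CRYST1   78.670   78.670   36.930  90.00  90.00  90.00 P 43 21 2     8",
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"),
    "END", sep = "\n")
  a <- read_structure(txt, text = TRUE)
  cell <- attr(a, "cell")
  expect_equal(cell$a, 78.67)
  expect_equal(cell$c, 36.93)
  expect_match(attr(a, "spacegroup_name"), "43 21")
})

test_that("written structures re-read with coordinates and cell intact", {
  a <- random_atom_set(12, seed = 5)
  f <- tempfile(fileext = ".pdb")
  write_structure(a, f, cell = unit_cell(40, 40, 40),
                  spacegroup_name = "P 1")
  b <- read_structure(f)
  expect_equal(coords(b), coords(a), tolerance = 1e-3)  # PDB fixed precision
  expect_equal(attr(b, "cell")$a, 40)
  unlink(f)
})

test_that("P1 expansion is the identity", {
  cell <- unit_cell(20, 25, 30)
  asu <- random_atom_set(7, span = 5, seed = 2)
  ex <- expand_asymmetric_unit(asu, space_group("P1"), cell)
  expect_equal(n_atoms(ex), 7L)
  expect_equal(coords(ex), coords(asu))
})

test_that("P43212 expansion gives 8 rigid copies with preserved distances", {
  cell <- unit_cell(78.67, 78.67, 36.93)
  sg <- space_group("P 43 21 2")
  expect_equal(n_operators(sg), 8L)
  asu <- random_atom_set(10, span = 6, seed = 3)
  ex <- expand_asymmetric_unit(asu, sg, cell)
  expect_equal(n_atoms(ex), 80L)
  expect_equal(length(unique(ex$mol)), 8L)
  ref <- dist(coords(asu))
  for (m in unique(ex$mol)) {
    copy <- coords(ex)[ex$mol == m, ]
    expect_equal(as.vector(dist(copy)), as.vector(ref), tolerance = 1e-9)
  }
})

test_that("the shipped P43212 operators are closed under composition", {
  sg <- space_group("P43212")
  ops <- sg$ops
  key <- function(rot, tr) paste(c(rot, round(tr %% 1, 9)), collapse = ",")
  have <- vapply(ops, function(o) key(o$rot, o$trans), "")
  for (a in ops) for (b in ops) {
    rot <- a$rot %*% b$rot
    tr <- as.vector(a$rot %*% b$trans) + a$trans
    expect_true(key(rot, tr) %in% have)
  }
})

test_that("supercell replication multiplies counts and spans the lattice box", {
  cell <- unit_cell(10, 12, 14)
  asu <- random_atom_set(5, span = 3, seed = 4)
  one <- build_supercell(asu, supercell_spec(1, 1, 1, cell, space_group("P1")))
  expect_equal(coords(one), coords(asu))
  sc <- build_supercell(asu, supercell_spec(3, 2, 4, cell, space_group("P1")))
  expect_equal(n_atoms(sc), 5L * 24L)
  expect_equal(length(unique(sc$mol)), 24L)
  span <- apply(coords(sc), 2, function(v) diff(range(v)))
  base <- apply(coords(asu), 2, function(v) diff(range(v)))
  expect_equal(span, base + c(2 * 10, 1 * 12, 3 * 14))
  expect_error(supercell_spec(0, 1, 1, cell, space_group("P1")), "positive")
})

test_that("an 8-copy cell replicated 5x5x5 contains 1000 molecules", {
  cell <- unit_cell(78.67, 78.67, 36.93)
  sg <- space_group("P43212")
  asu <- random_atom_set(6, span = 5, seed = 6)
  cellset <- expand_asymmetric_unit(asu, sg, cell)
  sc <- build_supercell(cellset, supercell_spec(5, 5, 5, cell, sg))
  expect_equal(length(unique(sc$mol)), 1000L)
  expect_equal(n_atoms(sc), 6L * 8L * 125L)
})

test_that("random solvation is deterministic and respects distances", {
  host <- random_atom_set(20, span = 15, seed = 7)
  s1 <- solvate_random(host, box = c(40, 40, 40), n_waters = 50,
                       min_dist = 2.4, seed = 99)
  s2 <- solvate_random(host, box = c(40, 40, 40), n_waters = 50,
                       min_dist = 2.4, seed = 99)
  expect_identical(coords(s1), coords(s2))
  expect_equal(n_atoms(s1), 20L + 150L)
  ox <- coords(s1)[s1$resname == "HOH" & s1$element == "O", ]
  heavy <- coords(host)[host$element != "H", ]
  dd <- as.matrix(dist(rbind(ox, heavy)))[seq_len(nrow(ox)), ]
  diag(dd) <- Inf
  expect_true(min(dd[, seq_len(nrow(ox))][upper.tri(dd[, seq_len(nrow(ox))])],
                  dd[, -seq_len(nrow(ox))]) >= 2.4)
  expect_identical(solvate_random(host, c(40, 40, 40), 0), host)
})

test_that("solvation reports a placement failure when the box is saturated", {
  empty <- atom_set(data.frame(element = character(0), x = numeric(0),
                               y = numeric(0), z = numeric(0)))
  expect_error(
    solvate_random(empty, box = c(5, 5, 5), n_waters = 100, min_dist = 3,
                   seed = 1, max_attempts = 50L),
    "placement failed")
})

test_that("neutralize adds the right number of counterions of either sign", {
  host <- atom_set(data.frame(
    element = "C", name = "CA",
    resname = c("ARG", "LYS", "GLY"), resno = 1:3, chain = "A", mol = 1L,
    x = c(0, 8, 16), y = 0, z = 0, occ = 1, b = 0))
  out <- neutralize(host, ion_element = "CL", seed = 3)
  expect_equal(sum(out$element == "CL"), 2L)       # net +2 -> 2 anions
  host2 <- atom_set(data.frame(
    element = "C", name = "CA",
    resname = c("ASP", "GLU", "GLU"), resno = 1:3, chain = "A", mol = 1L,
    x = c(0, 8, 16), y = 0, z = 0, occ = 1, b = 0))
  out2 <- neutralize(host2, ion_element = "NA", seed = 3)
  expect_equal(sum(out2$element == "NA"), 3L)      # net -3 -> 3 cations
  host3 <- atom_set(data.frame(
    element = "C", name = "CA", resname = c("ARG", "ASP"), resno = 1:2,
    chain = "A", mol = 1L, x = c(0, 8), y = 0, z = 0, occ = 1, b = 0))
  expect_identical(neutralize(host3, seed = 1), host3)  # net 0
  host4 <- atom_set(data.frame(element = "C", name = "CA", resname = "XXX",
                               resno = 1L, chain = "A", mol = 1L,
                               x = 0, y = 0, z = 0, occ = 1, b = 0))
  expect_error(neutralize(host4), "XXX")
})
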