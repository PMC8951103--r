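test_that("a minimal PDB parses with coordinates exactly as printed", {
  f <- write_tmp_lines(c(
    pdb_line(1, "C1", "LIG", "A", 1, 1.000, 2.000, 3.000, "C"),
    "TER", "END"))
  mol <- read_structure(f, "pdb")
  expect_s3_class(mol, "molecule")
  expect_equal(nrow(mol$atoms), 1)
  expect_equal(unname(unlist(mol$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(mol$atoms$element, "C")
})

test_that("read -> write -> read is a fixed point for both formats", {
  set.seed(42)
  els <- sample(c("C", "N", "O", "S"), 50, replace = TRUE)
  mol <- chain_molecule(els, spacing = 1.5)
  mol$atoms$x <- round(mol$atoms$x + runif(50, -0.2, 0.2), 3)
  mol$atoms$y <- round(runif(50, -5, 5), 3)
  mol$atoms$z <- round(runif(50, -5, 5), 3)
  for (ext in c(".pdb", ".pdbqt")) {
    f1 <- tempfile(fileext = ext)
    write_structure(mol, f1)
    back <- read_structure(f1)
    f2 <- tempfile(fileext = ext)
    write_structure(back, f2)
    back2 <- read_structure(f2)
    expect_equal(back$atoms$serial, mol$atoms$serial)
    expect_equal(back$atoms$name, mol$atoms$name)
    expect_equal(back$atoms$x, mol$atoms$x, tolerance = 1e-9)
    expect_equal(back$atoms$y, mol$atoms$y, tolerance = 1e-9)
    expect_equal(back$atoms$z, mol$atoms$z, tolerance = 1e-9)
    expect_equal(back2$atoms, back$atoms)
  }
})

test_that("PDBQT branching records are tolerated and TORSDOF is retained", {
  mol <- chain_molecule(c("C", "C", "C"))
  mol$n_rot <- 5L
  f <- tempfile(fileext = ".pdbqt")
  write_structure(mol, f)
  txt <- readLines(f)
  expect_true(any(grepl("^TORSDOF 5", txt)))
  back <- read_structure(f)
  expect_equal(back$n_rot, 5L)
  expect_false(is.na(back$atoms$partial_charge[1]))
})

test_that("CONECT records survive a PDB round trip", {
  mol <- chain_molecule(c("C", "C", "O"))
  f <- tempfile(fileext = ".pdb")
  write_structure(mol, f)
  expect_true(any(grepl("^CONECT", readLines(f))))
  back <- read_structure(f)
  expect_equal(nrow(back$bonds), 2)
  expect_equal(back$bonds$i, c(1, 2))
  expect_equal(back$bonds$j, c(2, 3))
})

test_that("malformed records and unknown elements raise typed errors", {
  f <- write_tmp_lines(c(
    pdb_line(1, "C1", "LIG", "A", 1, 1, 2, 3, "C"),
    "HETATM    2  C2  LIG A   1         bad   2.000   3.000",
    "END"))
  expect_error(read_structure(f, "pdb"), "line 2")
  f2 <- write_tmp_lines(c(pdb_line(1, "XX1", "LIG", "A", 1, 1, 2, 3, "Xx"), "END"))
  expect_error(read_structure(f2, "pdb"), "unknown element")
})

test_that("component selection filters segments, altlocs and waters", {
  seg_a <- vapply(1:10, function(i) {
    pdb_line(i, paste0("C", i), "ALA", "A", i, i, 0, 0, "C", record = "ATOM",
             segid = "A")
  }, "")
  seg_b <- vapply(11:20, function(i) {
    pdb_line(i, paste0("C", i), "ALA", "B", i, i, 1, 0, "C", record = "ATOM",
             segid = "B")
  }, "")
  waters <- vapply(21:25, function(i) {
    pdb_line(i, "O", "HOH", "W", i, i, 5, 0, "O")
  }, "")
  mol <- read_structure(write_tmp_lines(c(seg_a, seg_b, waters, "END")), "pdb")

  only_a <- select_component(mol, segments = "A")
  expect_equal(nrow(only_a$atoms), 10)
  expect_true(all(only_a$atoms$segid == "A"))

  dry <- select_component(mol, strip_solvent = TRUE)
  expect_false(any(dry$atoms$resname == "HOH"))
  expect_equal(nrow(dry$atoms), 20)

  # selection is idempotent and a subset of the input
  again <- select_component(only_a, segments = "A")
  expect_equal(again$atoms, only_a$atoms)
  expect_true(all(only_a$atoms$serial %in% mol$atoms$serial))

  expect_error(select_component(mol, chains = "Z"), "available chains")
})

test_that("altloc policy keeps exactly the first-listed alternative", {
  lines <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C", record = "ATOM", altloc = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 0.3, 0, 0, "C", record = "ATOM", altloc = "B"),
    pdb_line(3, "CB", "ALA", "A", 1, 1.5, 0, 0, "C", record = "ATOM"),
    "END")
  mol <- read_structure(write_tmp_lines(lines), "pdb")
  expect_warning(kept <- select_component(mol), "alternate-location")
  expect_equal(nrow(kept$atoms), 2)
  expect_equal(kept$atoms$altloc[kept$atoms$name == "CA"], "A")
})

test_that("interaction typing follows the parameter-table rules", {
  # methane-like: apolar carbon
  methane <- molecule(
    data.frame(serial = 1:5, name = c("C1", "H1", "H2", "H3", "H4"),
               element = c("C", "H", "H", "H", "H"),
               x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1), z = 0),
    bonds = data.frame(i = 1, j = 2:5, order = 1))
  t1 <- assign_interaction_types(methane)
  expect_true(t1$atoms$hydrophobic[1])
  expect_false(t1$atoms$donor[1])
  expect_false(t1$atoms$acceptor[1])
  expect_false(any(t1$atoms$is_heavy[2:5]))

  # carboxylate oxygen: acceptor, not donor; its carbon is polar
  carbox <- molecule(
    data.frame(serial = 1:3, name = c("C1", "O1", "O2"),
               element = c("C", "O", "O"),
               x = c(0, 1.2, -0.6), y = c(0, 0, 1.0), z = 0),
    bonds = data.frame(i = c(1, 1), j = c(2, 3), order = c(2, 1)))
  t2 <- assign_interaction_types(carbox)
  expect_true(all(t2$atoms$acceptor[2:3]))
  expect_false(any(t2$atoms$donor[2:3]))
  expect_false(t2$atoms$hydrophobic[1])

  # hydroxyl: donor and acceptor
  ohgrp <- molecule(
    data.frame(serial = 1:2, name = c("O1", "H1"), element = c("O", "H"),
               x = c(0, 0.96), y = 0, z = 0),
    bonds = data.frame(i = 1, j = 2, order = 1))
  t3 <- assign_interaction_types(ohgrp)
  expect_true(t3$atoms$donor[1])
  expect_true(t3$atoms$acceptor[1])
  expect_gt(t3$atoms$radius[1], 0)

  # element missing from the table
  zn <- molecule(data.frame(serial = 1, name = "ZN", element = "Zn",
                            x = 0, y = 0, z = 0))
  expect_error(assign_interaction_types(zn), "parameter table")
})

test_that("distance-based bond perception finds the chain; CONECT wins", {
  mol <- chain_molecule(c("C", "C", "C"), spacing = 1.54)
  bare <- molecule(mol$atoms)  # no bonds
  perceived <- perceive_bonds(bare)
  expect_equal(nrow(perceived$bonds), 2)
  # explicit bonds are left alone by default
  explicit <- molecule(mol$atoms, bonds = data.frame(i = 1, j = 3, order = 1))
  expect_equal(perceive_bonds(explicit)$bonds$j, 3)
})
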