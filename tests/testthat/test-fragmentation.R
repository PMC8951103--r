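test_that("scheme validation reports gaps, overlaps and missing cut bonds", {
  lig <- chain_molecule(rep("C", 10))
  ok_scheme <- fragment_scheme(list(A = 1:6, B = 7:10),
                               cut_bonds = rbind(c(6, 7)))
  rep1 <- validate_scheme(lig, ok_scheme)
  expect_true(rep1$ok)
  expect_length(rep1$errors, 0)

  overlap <- fragment_scheme(list(A = 1:7, B = 7:10), cut_bonds = rbind(c(6, 7)))
  rep2 <- validate_scheme(lig, overlap)
  expect_false(rep2$ok)
  expect_true(any(grepl("overlap: atom 7", rep2$errors)))

  nocut <- fragment_scheme(list(A = 1:6, B = 7:10))
  rep3 <- validate_scheme(lig, nocut)
  expect_false(rep3$ok)
  expect_true(any(grepl("missing cut bond", rep3$errors)))
  expect_equal(rep3$implied_cut_bonds, cbind(6L, 7L), ignore_attr = TRUE)

  gap <- fragment_scheme(list(A = 1:6, B = 8:10),
                         cut_bonds = rbind(c(6, 7)))
  expect_false(validate_scheme(lig, gap)$ok)

  notbond <- fragment_scheme(list(A = 1:6, B = 7:10),
                             cut_bonds = rbind(c(6, 7), c(2, 9)))
  expect_true(any(grepl("not a ligand bond", validate_scheme(lig, notbond)$errors)))
})

test_that("ring cut bonds validate with a warning entry", {
  atoms <- data.frame(serial = 1:4, name = paste0("C", 1:4), element = "C",
                      x = c(0, 1.5, 1.5, 0), y = c(0, 0, 1.5, 1.5), z = 0)
  ring <- molecule(atoms, bonds = data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 1),
                                             order = 1))
  sch <- fragment_scheme(list(A = 1:2, B = 3:4),
                         cut_bonds = rbind(c(2, 3), c(1, 4)))
  rep_ <- validate_scheme(ring, sch)
  expect_true(rep_$ok)
  expect_true(any(grepl("ring bond", rep_$warnings)))
})

test_that("an ethane-like split yields two methane-like capped fragments", {
  lig <- chain_molecule(c("C", "C"), spacing = 1.54)
  sch <- fragment_scheme(list(A = 1, B = 2), cut_bonds = rbind(c(1, 2)))
  frs <- cut_and_cap(lig, sch)
  expect_length(frs, 2)
  expect_equal(vapply(frs, `[[`, 0L, "nh"), c(1L, 1L))
  # fragment A: C at origin, H cap at (1.09, 0, 0) toward the departed C
  a <- frs[[1]]$molecule$atoms
  expect_equal(a$element, c("C", "H"))
  expect_equal(unname(unlist(a[2, c("x", "y", "z")])), c(1.09, 0, 0),
               tolerance = 1e-12)
  # fragment B: cap points back toward the origin
  b <- frs[[2]]$molecule$atoms
  expect_equal(unname(unlist(b[2, c("x", "y", "z")])), c(1.54 - 1.09, 0, 0),
               tolerance = 1e-12)
})

test_that("a single-fragment scheme reproduces the ligand", {
  lig <- chain_molecule(c("C", "C", "N", "C"))
  sch <- fragment_scheme(list(ALL = 1:4))
  frs <- cut_and_cap(lig, sch)
  expect_length(frs, 1)
  expect_equal(frs[[1]]$molecule$atoms$serial, lig$atoms$serial)
  expect_identical(frs[[1]]$molecule$atoms$x, lig$atoms$x)
  expect_equal(frs[[1]]$nh, n_heavy(lig))
  expect_length(frs[[1]]$cap_atom_indices, 0)
})

test_that("a middle fragment receives two caps and originals never move", {
  lig <- chain_molecule(rep("C", 6))
  sch <- fragment_scheme(list(A = 1:2, B = 3:4, C = 5:6),
                         cut_bonds = rbind(c(2, 3), c(4, 5)))
  frs <- cut_and_cap(lig, sch)
  expect_equal(vapply(frs, function(f) length(f$cap_atom_indices), 0L),
               c(1L, 2L, 1L))
  # originals bit-identical to the parent ligand
  for (f in frs) {
    orig <- f$molecule$atoms[f$molecule$atoms$serial %in% f$original_atom_serials, ]
    parent <- lig$atoms[match(orig$serial, lig$atoms$serial), ]
    expect_identical(orig$x, parent$x)
    expect_identical(orig$y, parent$y)
    expect_identical(orig$z, parent$z)
  }
  # heavy-atom conservation: sum of NH equals the ligand's heavy count
  expect_equal(sum(vapply(frs, `[[`, 0L, "nh")), n_heavy(lig))
  # union of original heavy serials is exactly the ligand heavy set
  got <- sort(unlist(lapply(frs, function(f) {
    m <- f$molecule
    m$atoms$serial[m$atoms$serial %in% f$original_atom_serials & is_heavy(m)]
  })))
  expect_equal(got, lig$atoms$serial[is_heavy(lig)])
})

test_that("fragment hydrogens travel with their heavy atoms", {
  atoms <- data.frame(serial = 1:4,
                      name = c("C1", "H1", "C2", "H2"),
                      element = c("C", "H", "C", "H"),
                      x = c(0, 0, 1.54, 1.54), y = c(0, 1.0, 0, -1.0), z = 0)
  lig <- molecule(atoms, bonds = data.frame(i = c(1, 1, 3), j = c(2, 3, 4),
                                            order = 1))
  frs <- cut_and_cap(lig, fragment_scheme(list(A = 1, B = 3),
                                          cut_bonds = rbind(c(1, 3))))
  expect_equal(sort(frs[[1]]$molecule$atoms$serial[1:2]), c(1L, 2L))
  expect_equal(frs[[1]]$nh, 1L)  # the original H does not count toward NH
})

test_that("cut_and_cap is deterministic and refuses multiple-order cuts", {
  lig <- chain_molecule(rep("C", 4))
  sch <- fragment_scheme(list(A = 1:2, B = 3:4), cut_bonds = rbind(c(2, 3)))
  f1 <- cut_and_cap(lig, sch)
  f2 <- cut_and_cap(lig, sch)
  expect_identical(f1[[1]]$molecule$atoms, f2[[1]]$molecule$atoms)

  lig2 <- lig
  lig2$bonds$order[2] <- 2  # make the 2-3 bond double
  expect_error(cut_and_cap(lig2, sch), "order 2")
  expect_length(cut_and_cap(lig2, sch, allow_nonsingle = TRUE), 2)
})

test_that("hydrogen caps sit at the configured length along the bond vector", {
  # axis-aligned examples forced by geometry
  cap <- place_cap("C", c(0, 0, 0), c(1.54, 0, 0), "hydrogen")
  expect_equal(unname(unlist(cap[1, c("x", "y", "z")])), c(1.09, 0, 0),
               tolerance = 1e-12)
  cap_z <- place_cap("C", c(0, 0, 0), c(0, 0, 2), "hydrogen")
  expect_equal(unname(unlist(cap_z[1, c("x", "y", "z")])), c(0, 0, 1.09),
               tolerance = 1e-12)
  # length property over random directions, per stub element
  set.seed(7)
  lens <- c(C = 1.09, N = 1.01, O = 0.96)
  for (k in 1:100) {
    el <- sample(names(lens), 1)
    v <- rnorm(3)
    stub <- rnorm(3)
    cap <- place_cap(el, stub, stub + v, "hydrogen")
    got <- sqrt(sum((unlist(cap[1, c("x", "y", "z")]) - stub)^2))
    expect_equal(got, unname(lens[el]), tolerance = 1e-6)
    # direction preserved
    u <- v / sqrt(sum(v^2))
    w <- (unlist(cap[1, c("x", "y", "z")]) - stub) / got
    expect_equal(unname(w), unname(u), tolerance = 1e-9)
  }
  expect_error(place_cap("C", c(0, 0, 0), c(0, 0, 0)), "zero-length")
})

test_that("methyl caps have tetrahedral geometry at standard lengths", {
  cap <- place_cap("C", c(0, 0, 0), c(1.54, 0, 0), "methyl")
  expect_equal(cap$element, c("C", "H", "H", "H"))
  cxyz <- unlist(cap[1, c("x", "y", "z")])
  expect_equal(sqrt(sum(cxyz^2)), 1.54, tolerance = 1e-9)
  for (k in 2:4) {
    h <- unlist(cap[k, c("x", "y", "z")])
    expect_equal(sqrt(sum((h - cxyz)^2)), 1.09, tolerance = 1e-9)
    # H-C-stub angle is tetrahedral
    v1 <- -cxyz / sqrt(sum(cxyz^2))
    v2 <- (h - cxyz) / sqrt(sum((h - cxyz)^2))
    expect_equal(acos(sum(v1 * v2)) * 180 / pi, 109.471, tolerance = 1e-3)
  }
})

test_that("schemes round-trip through JSON and the map-file reader works", {
  sch <- fragment_scheme(list(head = 1:3, tail = 4:6),
                         cut_bonds = rbind(c(3, 4)), cap = "methyl",
                         labels = c("head group", "tail group"))
  f <- tempfile(fileext = ".json")
  write_scheme(sch, f)
  back <- read_scheme(f)
  expect_equal(back$fragments, sch$fragments)
  expect_equal(unname(back$labels), unname(sch$labels))
  expect_equal(back$cut_bonds, sch$cut_bonds)
  expect_equal(back$cap, "methyl")

  mapf <- tempfile(fileext = ".txt")
  writeLines(c("1 A", "2 A", "3 B"), mapf)
  m <- read_scheme(mapf)
  expect_equal(m$fragments$A, 1:2)
  expect_equal(m$fragments$B, 3L)
})
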