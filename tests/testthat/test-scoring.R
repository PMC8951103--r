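hydroph <- list(hydrophobic = TRUE, donor = FALSE, acceptor = FALSE)
donor_t <- list(hydrophobic = FALSE, donor = TRUE, acceptor = TRUE)
accept_t <- list(hydrophobic = FALSE, donor = FALSE, acceptor = TRUE)

test_that("pair terms take their forced values at landmark distances", {
  p <- sf_params("vina")
  at_zero <- pair_terms(0, hydroph, hydroph, p)
  expect_equal(unname(at_zero[1, "gauss1"]), 1)       # exp(0)
  expect_equal(unname(at_zero[1, "repulsion"]), 0)    # boundary of d^2 branch
  expect_equal(unname(at_zero[1, "hydrophobic"]), 1)  # plateau
  expect_equal(unname(at_zero[1, "hbond"]), 0)        # not a donor-acceptor pair

  expect_equal(unname(pair_terms(-1, hydroph, hydroph, p)[1, "repulsion"]), 1)
  expect_equal(unname(pair_terms(p$cutoff, hydroph, hydroph, p)[1, ]),
               rep(0, 5))                            # excluded at cutoff

  hb <- pair_terms(c(-0.7, -0.35, 0), donor_t, accept_t, p)
  expect_equal(unname(hb[, "hbond"]), c(1, 0.5, 0))
  # direction does not matter for the donor-acceptor pairing
  expect_equal(unname(pair_terms(-0.7, accept_t, donor_t, p)[1, "hbond"]), 1)
})

test_that("a single pair reproduces the hand-written weighted sum", {
  p <- sf_params("vina")
  rec <- assign_interaction_types(molecule(
    data.frame(serial = 1, name = "P1", element = "C", x = 0, y = 0, z = 0)))
  lig <- assign_interaction_types(molecule(
    data.frame(serial = 1, name = "C1", element = "C", x = 4.5, y = 0, z = 0)))
  d <- 4.5 - 1.9 - 1.9
  w <- p$weights
  by_hand <- w[["gauss1"]] * exp(-(d / 0.5)^2) +
    w[["gauss2"]] * exp(-((d - 3) / 2)^2) +
    w[["hydrophobic"]] * ((1.5 - d) / (1.5 - 0.5))
  got <- score_pose(rec, lig, p)
  expect_equal(got$value, by_hand, tolerance = 1e-12)
  expect_equal(got$units, "kcal_per_mol")
  expect_equal(got$backend_id, "builtin_vina")
})

test_that("a ligand beyond the cutoff from every receptor atom scores zero", {
  rec <- assign_interaction_types(molecule(
    data.frame(serial = 1, name = "P1", element = "C", x = 0, y = 0, z = 0)))
  lig <- assign_interaction_types(molecule(
    data.frame(serial = 1, name = "C1", element = "C", x = 50, y = 0, z = 0)))
  expect_equal(score_pose(rec, lig)$value, 0)
})

test_that("vectorized scorer equals the direct double-loop reference", {
  for (seed in 1:12) {
    rec <- random_cloud(30, seed = seed, box = c(0, 10))
    lig <- random_cloud(10, seed = seed + 1000, box = c(2, 12))
    for (set in c("vina", "vinardo")) {
      p <- sf_params(set)
      got <- score_pose(assign_interaction_types(rec),
                        assign_interaction_types(lig), p)$value
      want <- oracle_score(rec$atoms, lig$atoms, rec$bonds, lig$bonds, p)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("score is additive over disjoint receptor subsets", {
  rec <- assign_interaction_types(random_cloud(24, seed = 5, box = c(0, 10)))
  lig <- assign_interaction_types(random_cloud(8, seed = 6, box = c(2, 12)))
  n <- nrow(rec$atoms)
  half1 <- fragshare:::subset_molecule(rec, 1:(n %/% 2))
  half2 <- fragshare:::subset_molecule(rec, (n %/% 2 + 1):n)
  p <- sf_params("vina")
  expect_equal(score_pose(half1, lig, p)$value + score_pose(half2, lig, p)$value,
               score_pose(rec, lig, p)$value, tolerance = 1e-9)
})

test_that("a rigid motion of the whole frame leaves the score unchanged", {
  rec <- assign_interaction_types(random_cloud(20, seed = 9, box = c(0, 10)))
  lig <- assign_interaction_types(random_cloud(7, seed = 10, box = c(2, 12)))
  p <- sf_params("vina")
  before <- score_pose(rec, lig, p)$value
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  t <- c(5, -3, 2)
  after <- score_pose(transform_molecule(rec, R, t),
                      transform_molecule(lig, R, t), p)$value
  expect_equal(after, before, tolerance = 1e-9)
})

test_that("the score is linear in the term weights", {
  rec <- assign_interaction_types(random_cloud(15, seed = 3, box = c(0, 9)))
  lig <- assign_interaction_types(random_cloud(6, seed = 4, box = c(1, 10)))
  p <- sf_params("vina")
  p3 <- sf_params("vina", weights = p$weights * 3)
  expect_equal(score_pose(rec, lig, p3)$value,
               3 * score_pose(rec, lig, p)$value, tolerance = 1e-12)
})

test_that("rotatable-bond scaling divides by 1 + w_rot * n_rot", {
  rec <- assign_interaction_types(random_cloud(10, seed = 11, box = c(0, 8)))
  lig <- assign_interaction_types(random_cloud(5, seed = 12, box = c(1, 9)))
  lig$n_rot <- 4L
  p <- sf_params("vina")
  raw <- score_pose(rec, lig, p)$value
  scaled <- score_pose(rec, lig, p, apply_nrot_scaling = TRUE)$value
  expect_equal(scaled, raw / (1 + p$w_rot * 4), tolerance = 1e-12)
})

test_that("untyped or empty molecules are rejected", {
  rec <- random_cloud(5, seed = 1)
  lig <- random_cloud(3, seed = 2)
  expect_error(score_pose(rec, lig), "untyped")
  typed <- assign_interaction_types(rec)
  empty <- molecule(rec$atoms[0, ])
  expect_error(score_pose(typed, empty), "empty")
})

test_that("external score-only adapters parse scores and fail loudly", {
  vina_like <- write_tmp_lines(c("#!/bin/sh",
                                 'echo "Affinity: -7.95 (kcal/mol)"'),
                               ext = ".sh")
  ad <- external_backend("mock_vina", paste("sh", vina_like),
                         pattern = "Affinity:\\s+(-?[0-9.]+)")
  sv <- external_score(ad, "r.pdbqt", "l.pdbqt")
  expect_equal(sv$value, -7.95)
  expect_equal(sv$units, "kcal_per_mol")
  expect_true(any(grepl("Affinity", attr(sv, "raw_output"))))

  pkd_like <- write_tmp_lines(c("#!/bin/sh", 'echo "6.5"'), ext = ".sh")
  ad2 <- external_backend("mock_pkd", paste("sh", pkd_like),
                          pattern = "^([0-9.]+)$", units = "pKd",
                          favorable_direction = "positive_is_better")
  sv2 <- external_score(ad2, "r", "l")
  expect_equal(sv2$value, 6.5)
  expect_equal(sv2$favorable_direction, "positive_is_better")

  silent <- write_tmp_lines(c("#!/bin/sh", 'echo "no score here"'), ext = ".sh")
  ad3 <- external_backend("mock_bad", paste("sh", silent),
                          pattern = "Affinity:\\s+(-?[0-9.]+)")
  expect_error(external_score(ad3, "r", "l"), "no parseable score")

  crash <- write_tmp_lines(c("#!/bin/sh", "exit 3"), ext = ".sh")
  ad4 <- external_backend("mock_crash", paste("sh", crash),
                          pattern = "(\\d+)")
  expect_error(external_score(ad4, "r", "l"), "mock_crash")
})
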