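#' Specification for a synthetic receptor-ligand fixture
#'
#' Describes a chemically minimal complex with analytically known pairwise
#' scores: a ligand built as fragments of bonded heavy atoms laid out along
#' x, and isolated receptor probe atoms placed at chosen surface distances
#' perpendicular to the chain. Fragments are spaced far apart (default 20
#' Angstrom, beyond the scoring cutoff) so each probe interacts with exactly
#' one fragment and the per-fragment scores — hence the expected shares —
#' follow in closed form. Realism is not the goal; exercising every term
#' regime deterministically is.
#'
#' @param n_fragments number of ligand fragments.
#' @param atoms_per_fragment heavy atoms per fragment.
#' @param probes_per_fragment integer vector (recycled) of receptor probes
#'   near each fragment.
#' @param probe_surface_distance surface distance d (Angstrom) between each
#'   probe and its target atom (scalar or per-fragment vector).
#' @param fragment_spacing x-gap between the last atom of one fragment and
#'   the first of the next, Angstrom.
#' @param bond_length within-fragment atom spacing, Angstrom.
#' @param ligand_element,probe_element element symbols.
#' @param seed integer; fixes the probe azimuthal angles, so equal seeds give
#'   identical fixtures.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_fragments = 2, atoms_per_fragment = 1,
                         probes_per_fragment = c(3, 1),
                         probe_surface_distance = 0,
                         fragment_spacing = 20, bond_length = 1.54,
                         ligand_element = "C", probe_element = "C",
                         seed = 1) {
  structure(list(n_fragments = n_fragments,
                 atoms_per_fragment = atoms_per_fragment,
                 probes_per_fragment = rep_len(probes_per_fragment, n_fragments),
                 probe_surface_distance = rep_len(probe_surface_distance, n_fragments),
                 fragment_spacing = fragment_spacing,
                 bond_length = bond_length,
                 ligand_element = ligand_element,
                 probe_element = probe_element,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build a synthetic complex with known per-fragment scores
#'
#' Constructs the complex described by a [fixture_spec], a matching
#' fragmentation scheme, and the expected per-fragment single-point scores
#' computed by [oracle_score()], the direct closed-form pair sum that serves
#' as the independent reference for the vectorized scorer.
#'
#' @param spec a [fixture_spec].
#' @param params [sf_params] used for radii and for the expected scores.
#' @return list with `complex` (a [complex_geometry], untyped), `scheme`
#'   (a [fragment_scheme]), `expected_scores` (named numeric, kcal/mol) and
#'   `spec`.
#' @export
make_toy_complex <- function(spec = fixture_spec(), params = sf_params("vina")) {
  set.seed(spec$seed)
  npf <- spec$atoms_per_fragment
  frag_ids <- paste0("F", seq_len(spec$n_fragments))
  lig_rows <- list()
  frag_atoms <- list()
  serial <- 0L
  x0 <- 0
  for (f in seq_len(spec$n_fragments)) {
    xs <- x0 + (seq_len(npf) - 1) * spec$bond_length
    rows <- data.frame(serial = serial + seq_len(npf),
                       name = paste0(spec$ligand_element, serial + seq_len(npf)),
                       element = spec$ligand_element,
                       x = xs, y = 0, z = 0, resname = "LIG", resid = 1L)
    lig_rows[[f]] <- rows
    frag_atoms[[frag_ids[f]]] <- rows$serial
    serial <- serial + npf
    x0 <- xs[npf] + spec$fragment_spacing
  }
  lig_atoms <- do.call(rbind, lig_rows)
  n <- nrow(lig_atoms)
  bonds <- NULL
  if (n > 1) {
    bonds <- data.frame(i = 1:(n - 1), j = 2:n, order = 1)
  }
  ligand <- molecule(lig_atoms, bonds = bonds, provenance = "synthetic fixture ligand")
  cuts <- NULL
  if (spec$n_fragments > 1) {
    last <- cumsum(rep(npf, spec$n_fragments))
    cuts <- cbind(last[-spec$n_fragments], last[-spec$n_fragments] + 1L)
  }
  scheme <- fragment_scheme(frag_atoms, cut_bonds = cuts)

  tab <- sf_type_table()
  r_lig <- tab$radius[match(spec$ligand_element, tab$element)]
  r_probe <- tab$radius[match(spec$probe_element, tab$element)]
  probe_rows <- list()
  k <- 0L
  for (f in seq_len(spec$n_fragments)) {
    np <- spec$probes_per_fragment[f]
    if (np == 0) next
    d <- spec$probe_surface_distance[f]
    rr <- r_lig + r_probe + d
    phi0 <- stats::runif(1, 0, 2 * pi)
    targets <- frag_atoms[[frag_ids[f]]]
    for (m in seq_len(np)) {
      tgt <- targets[((m - 1) %% length(targets)) + 1]
      phi <- phi0 + 2 * pi * (m - 1) / np
      xyz <- c(lig_atoms$x[match(tgt, lig_atoms$serial)],
               rr * cos(phi), rr * sin(phi))
      k <- k + 1L
      probe_rows[[k]] <- data.frame(serial = k, name = paste0("P", k),
                                    element = spec$probe_element,
                                    x = xyz[1], y = xyz[2], z = xyz[3],
                                    resname = "PRB", resid = k, hetatm = FALSE)
    }
  }
  if (!length(probe_rows)) stop("fixture has no receptor probes")
  rec_atoms <- do.call(rbind, probe_rows)
  # infeasible geometry guard: probes must not collide with each other
  if (nrow(rec_atoms) > 1) {
    px <- as.matrix(rec_atoms[, c("x", "y", "z")])
    dmin <- min(stats::dist(px))
    if (dmin < 1.0) {
      stop("infeasible fixture geometry: probe atoms collide (min distance ",
           format(dmin), " Angstrom)")
    }
  }
  receptor <- molecule(rec_atoms, provenance = "synthetic fixture receptor")
  expected <- vapply(frag_ids, function(id) {
    frag <- subset_molecule(ligand, match(frag_atoms[[id]], ligand$atoms$serial))
    oracle_score(receptor$atoms, frag$atoms, receptor$bonds, frag$bonds, params)
  }, numeric(1))
  list(complex = complex_geometry(receptor, ligand, "synthetic fixture"),
       scheme = scheme,
       expected_scores = expected,
       spec = spec)
}

#' Direct double-loop pair sum (reference scorer)
#'
#' Scalar O(N*M) evaluation of the built-in scoring function, written as a
#' plain double loop with the term formulas inlined and its own typing rules.
#' It is the independent reference the vectorized [score_pose()] is tested
#' against, and supplies the expected scores of [make_toy_complex()].
#'
#' @param receptor_atoms,mol_atoms atom data.frames (columns `element`, `x`,
#'   `y`, `z`).
#' @param receptor_bonds,mol_bonds bond data.frames used for the typing rules
#'   (may be NULL/empty).
#' @param params an [sf_params].
#' @return numeric score, kcal/mol.
#' @export
oracle_score <- function(receptor_atoms, mol_atoms,
                         receptor_bonds = NULL, mol_bonds = NULL,
                         params = sf_params("vina")) {
  radius_of <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1,
                 F = 1.5, Cl = 1.8, Br = 2.0, I = 2.2)
  typing <- function(atoms, bonds) {
    n <- nrow(atoms)
    nb_el <- rep(list(character()), n)
    if (!is.null(bonds) && NROW(bonds)) {
      for (k in seq_len(NROW(bonds))) {
        i <- bonds$i[k]; j <- bonds$j[k]
        if (i <= n && j <= n) {
          nb_el[[i]] <- c(nb_el[[i]], atoms$element[j])
          nb_el[[j]] <- c(nb_el[[j]], atoms$element[i])
        }
      }
    }
    data.frame(
      heavy = atoms$element != "H",
      hydrophobic = (atoms$element == "C" &
                       !vapply(nb_el, function(e) any(e %in% c("N", "O")), TRUE)) |
        atoms$element %in% c("F", "Cl", "Br", "I"),
      donor = atoms$element %in% c("N", "O") &
        vapply(nb_el, function(e) any(e == "H"), TRUE),
      acceptor = atoms$element %in% c("N", "O"),
      radius = unname(radius_of[atoms$element])
    )
  }
  tr <- typing(receptor_atoms, receptor_bonds)
  tl <- typing(mol_atoms, mol_bonds)
  w <- params$weights
  total <- 0
  for (i in seq_len(nrow(receptor_atoms))) {
    if (!tr$heavy[i]) next
    for (j in seq_len(nrow(mol_atoms))) {
      if (!tl$heavy[j]) next
      r <- sqrt((receptor_atoms$x[i] - mol_atoms$x[j])^2 +
                  (receptor_atoms$y[i] - mol_atoms$y[j])^2 +
                  (receptor_atoms$z[i] - mol_atoms$z[j])^2)
      d <- r - tr$radius[i] - tl$radius[j]
      if (d >= params$cutoff) next
      g1 <- exp(-((d - params$gauss1_offset) / params$gauss1_width)^2)
      g2 <- exp(-((d - params$gauss2_offset) / params$gauss2_width)^2)
      rp <- if (d < 0) d * d else 0
      hy <- 0
      if (tr$hydrophobic[i] && tl$hydrophobic[j]) {
        hy <- if (d <= params$hydrophobic_lo) 1
        else if (d >= params$hydrophobic_hi) 0
        else (params$hydrophobic_hi - d) / (params$hydrophobic_hi - params$hydrophobic_lo)
      }
      hb <- 0
      if ((tr$donor[i] && tl$acceptor[j]) || (tr$acceptor[i] && tl$donor[j])) {
        hb <- if (d <= params$hbond_lo) 1
        else if (d >= params$hbond_hi) 0
        else (params$hbond_hi - d) / (params$hbond_hi - params$hbond_lo)
      }
      total <- total + w[["gauss1"]] * g1 + w[["gauss2"]] * g2 +
        w[["repulsion"]] * rp + w[["hydrophobic"]] * hy + w[["hbond"]] * hb
    }
  }
  total
}

#' Write a fixture to disk
#'
#' Emits `receptor.pdbqt`, `ligand.pdbqt` and `scheme.json` into a directory,
#' the same trio the analysis entry points consume, so every fixture
#' round-trips through the structure readers.
#'
#' @param toy result of [make_toy_complex()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(toy$complex$receptor, file.path(dir, "receptor.pdbqt"))
  write_structure(toy$complex$ligand, file.path(dir, "ligand.pdbqt"))
  write_scheme(toy$scheme, file.path(dir, "scheme.json"))
  invisible(dir)
}
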