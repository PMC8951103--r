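#' Define a fragmentation scheme
#'
#' A scheme partitions the ligand's heavy atoms into named fragments and lists
#' the inter-fragment bonds to cut. Fragmentation itself is the researcher's
#' choice; this package only enforces that the scheme is a true partition.
#' Atom serials are 1-based, exactly as printed in the ligand's source file.
#'
#' @param fragments named list: each element a vector of heavy-atom serials;
#'   names are fragment ids. Alternatively a list of
#'   `list(id=, label=, atoms=)` entries.
#' @param cut_bonds two-column matrix/data.frame of serial pairs to cut, or
#'   `NULL`.
#' @param cap `"hydrogen"` (default) or `"methyl"`: what to place at each open
#'   valence.
#' @param labels optional character vector of human-readable labels, parallel
#'   to `fragments`.
#' @return An object of class `fragment_scheme`.
#' @export
fragment_scheme <- function(fragments, cut_bonds = NULL,
                            cap = c("hydrogen", "methyl"), labels = NULL) {
  cap <- match.arg(cap)
  if (!is.list(fragments) || is.null(names(fragments)) && !all(vapply(fragments, is.list, TRUE))) {
    if (is.null(names(fragments))) names(fragments) <- paste0("F", seq_along(fragments))
  }
  if (all(vapply(fragments, is.list, TRUE))) {
    ids <- vapply(fragments, function(f) as.character(f$id), "")
    labels <- vapply(fragments, function(f) as.character(f$label %||% f$id), "")
    fragments <- lapply(fragments, function(f) as.integer(f$atoms))
    names(fragments) <- ids
  }
  if (is.null(labels)) labels <- names(fragments)
  if (!is.null(cut_bonds)) {
    cut_bonds <- matrix(as.integer(as.matrix(cut_bonds)), ncol = 2)
  } else {
    cut_bonds <- matrix(integer(), ncol = 2)
  }
  structure(
    list(fragments = lapply(fragments, function(x) as.integer(sort(x))),
         labels = stats::setNames(labels, names(fragments)),
         cut_bonds = cut_bonds, cap = cap),
    class = "fragment_scheme"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fragment_scheme <- function(x, ...) {
  cat("<fragment_scheme> ", length(x$fragments), " fragments, ",
      nrow(x$cut_bonds), " cut bonds, cap = ", x$cap, "\n", sep = "")
  for (id in names(x$fragments)) {
    cat("  ", id, " (", x$labels[[id]], "): ", length(x$fragments[[id]]),
        " heavy atoms\n", sep = "")
  }
  invisible(x)
}

#' Read / write a fragmentation scheme (JSON)
#'
#' The JSON document carries `cap`, a `fragments` array of
#' `{id, label, atoms}` objects (1-based heavy-atom serials) and a
#' `cut_bonds` array of serial pairs. A plain two-column whitespace-separated
#' `serial fragment_id` map file is also accepted by `read_scheme()`; cut
#' bonds are then taken as every ligand bond joining two fragments once a
#' ligand is supplied to [validate_scheme()] or [cut_and_cap()].
#'
#' @param path file path.
#' @param scheme a [fragment_scheme].
#' @return `read_scheme()`: a [fragment_scheme]; `write_scheme()`: `path`,
#'   invisibly.
#' @export
read_scheme <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    frs <- lapply(doc$fragments, function(f) {
      list(id = f$id, label = f$label %||% f$id, atoms = unlist(f$atoms))
    })
    cuts <- if (length(doc$cut_bonds)) {
      do.call(rbind, lapply(doc$cut_bonds, unlist))
    } else NULL
    fragment_scheme(frs, cut_bonds = cuts, cap = doc$cap %||% "hydrogen")
  } else {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("serial", "fragment_id"),
                             stringsAsFactors = FALSE)
    frs <- split(as.integer(tab$serial), tab$fragment_id)
    fragment_scheme(frs[unique(tab$fragment_id)])
  }
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  doc <- list(
    cap = scheme$cap,
    fragments = lapply(names(scheme$fragments), function(id) {
      list(id = id, label = unname(scheme$labels[[id]]),
           atoms = scheme$fragments[[id]])
    }),
    cut_bonds = if (nrow(scheme$cut_bonds)) {
      lapply(seq_len(nrow(scheme$cut_bonds)), function(k) scheme$cut_bonds[k, ])
    } else list()
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a fragmentation scheme against a ligand
#'
#' Report-style check of the partition contract: fragments must be pairwise
#' disjoint and cover exactly the ligand's heavy atoms; every cut bond must be
#' a real ligand bond joining two different fragments; every inter-fragment
#' ligand bond must be cut. Ring bonds among the cut bonds are allowed but
#' warned about (capping both ends of a ring bond leaves both fragments open
#' in the same region). When the scheme has no recorded cut bonds but the
#' ligand's inter-fragment bonds are unambiguous, they are reported as the
#' implied cut set.
#'
#' @param ligand a [molecule] with bonds (perceived or from CONECT).
#' @param scheme a [fragment_scheme].
#' @return list with `ok` (TRUE iff no errors), `errors`, `warnings`
#'   (character vectors) and `implied_cut_bonds` (serial pairs).
#' @export
validate_scheme <- function(ligand, scheme) {
  errors <- character()
  warnings <- character()
  heavy_serials <- ligand$atoms$serial[is_heavy(ligand)]
  frag_atoms <- scheme$fragments
  all_assigned <- unlist(frag_atoms, use.names = FALSE)

  dup <- unique(all_assigned[duplicated(all_assigned)])
  if (length(dup)) {
    owners <- vapply(dup, function(s) {
      paste(names(frag_atoms)[vapply(frag_atoms, function(a) s %in% a, TRUE)],
            collapse = "+")
    }, "")
    errors <- c(errors, paste0("overlap: atom ", dup, " in fragments ", owners))
  }
  gaps <- setdiff(heavy_serials, all_assigned)
  if (length(gaps)) {
    errors <- c(errors, paste0("coverage gap: heavy atom(s) ",
                               paste(gaps, collapse = ", "),
                               " assigned to no fragment"))
  }
  extra <- setdiff(all_assigned, heavy_serials)
  if (length(extra)) {
    errors <- c(errors, paste0("unknown/non-heavy atom serial(s) in scheme: ",
                               paste(extra, collapse = ", ")))
  }

  # which fragment owns each serial
  owner <- stats::setNames(rep(names(frag_atoms), lengths(frag_atoms)),
                           unlist(frag_atoms, use.names = FALSE))
  b <- ligand$bonds
  ser_i <- ligand$atoms$serial[b$i]
  ser_j <- ligand$atoms$serial[b$j]
  heavy_bond <- ser_i %in% heavy_serials & ser_j %in% heavy_serials
  inter <- heavy_bond & !is.na(owner[as.character(ser_i)]) &
    !is.na(owner[as.character(ser_j)]) &
    owner[as.character(ser_i)] != owner[as.character(ser_j)]
  implied <- cbind(ser_i[inter], ser_j[inter])

  cut_key <- function(m) {
    if (!NROW(m)) return(character())
    paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  }
  declared <- cut_key(scheme$cut_bonds)
  needed <- cut_key(implied)
  missing_cuts <- setdiff(needed, declared)
  if (length(missing_cuts)) {
    errors <- c(errors, paste0("missing cut bond: inter-fragment bond ",
                               missing_cuts, " not in cut_bonds"))
  }
  bond_keys <- paste(pmin(ser_i, ser_j), pmax(ser_i, ser_j))
  not_bonds <- setdiff(declared, bond_keys)
  if (length(not_bonds)) {
    errors <- c(errors, paste0("cut bond ", not_bonds, " is not a ligand bond"))
  }
  same_frag <- setdiff(intersect(declared, bond_keys), needed)
  if (length(same_frag)) {
    errors <- c(errors, paste0("cut bond ", same_frag,
                               " joins atoms of the same fragment"))
  }
  for (key in intersect(declared, needed)) {
    ss <- as.integer(strsplit(key, " ")[[1]])
    if (bond_in_ring(ligand, ss[1], ss[2])) {
      warnings <- c(warnings, paste0("cut bond ", key,
                                     " is a ring bond; capping cannot preserve the ring"))
    }
    ord <- bond_order_of(ligand, ss[1], ss[2])
    if (!is.na(ord) && ord > 1) {
      warnings <- c(warnings, paste0("cut bond ", key, " has order ", ord,
                                     "; hydrogen capping cannot preserve hybridization"))
    }
  }

  list(ok = length(errors) == 0, errors = errors, warnings = warnings,
       implied_cut_bonds = implied)
}

bond_order_of <- function(mol, serial_a, serial_b) {
  ia <- match(serial_a, mol$atoms$serial)
  ib <- match(serial_b, mol$atoms$serial)
  b <- mol$bonds
  hit <- (b$i == ia & b$j == ib) | (b$i == ib & b$j == ia)
  if (!any(hit)) return(NA_real_)
  b$order[which(hit)[1]]
}

# a bond is a ring bond iff its endpoints stay connected after its removal
bond_in_ring <- function(mol, serial_a, serial_b) {
  ia <- match(serial_a, mol$atoms$serial)
  ib <- match(serial_b, mol$atoms$serial)
  b <- mol$bonds
  drop <- (b$i == ia & b$j == ib) | (b$i == ib & b$j == ia)
  b <- b[!drop, , drop = FALSE]
  # BFS from ia
  adj <- rep(list(integer()), nrow(mol$atoms))
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  seen <- logical(nrow(mol$atoms))
  queue <- ia
  seen[ia] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  seen[ib]
}

#' Place a cap at a broken bond
#'
#' Places cap atom(s) along the unit vector from the stub atom toward the
#' departed neighbor's original position, so the cap points exactly where the
#' severed bond pointed. Hydrogen caps put one H at the tabulated X-H length
#' for the stub's element; methyl caps put one C at the tabulated X-C
#' single-bond length plus three H in tetrahedral geometry around it,
#' staggered relative to the stub's remaining substituents when any are given.
#' Lengths come from the versioned config `extdata/cap_lengths_v1.json`.
#'
#' @param stub_element element symbol of the atom keeping the cap.
#' @param stub_coords,departed_coords numeric length-3 positions (Angstrom) of
#'   the stub atom and of the atom that was cut away.
#' @param cap_kind `"hydrogen"` or `"methyl"`.
#' @param stub_neighbors optional matrix (rows = positions) of the stub's
#'   other bonded atoms, used only to orient methyl hydrogens.
#' @return data.frame with columns `element`, `x`, `y`, `z`, one row per cap
#'   atom (the first row bonds to the stub).
#' @export
place_cap <- function(stub_element, stub_coords, departed_coords,
                      cap_kind = c("hydrogen", "methyl"),
                      stub_neighbors = NULL) {
  cap_kind <- match.arg(cap_kind)
  v <- as.numeric(departed_coords) - as.numeric(stub_coords)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("zero-length direction vector for cap placement")
  u <- v / nv
  cfg <- cap_length_table()
  len_tab <- cfg[[cap_kind]]
  L <- len_tab[[stub_element]] %||% len_tab[["default"]]
  first <- as.numeric(stub_coords) + L * u
  if (cap_kind == "hydrogen") {
    return(data.frame(element = "H", x = first[1], y = first[2], z = first[3]))
  }
  # methyl: C at `first`, then 3 H tetrahedrally around the stub->C axis
  lch <- cfg$methyl_CH
  theta <- pi - cfg$tetrahedral_angle_deg * pi / 180  # from +u axis
  # orthonormal frame about u; reference direction from a neighbor if provided
  ref <- c(1, 0, 0)
  if (!is.null(stub_neighbors) && NROW(stub_neighbors)) {
    w <- as.numeric(stub_neighbors[1, ]) - as.numeric(stub_coords)
    w <- w - sum(w * u) * u
    if (sqrt(sum(w^2)) > 1e-6) ref <- w / sqrt(sum(w^2))
  }
  if (abs(sum(ref * u)) > 0.99) ref <- c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  # staggered: offset 60 degrees from the (eclipsed) reference substituent
  phis <- pi / 3 + c(0, 2, 4) * pi / 3
  hs <- t(vapply(phis, function(phi) {
    dir <- cos(theta) * u + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
    first + lch * dir
  }, numeric(3)))
  data.frame(element = c("C", "H", "H", "H"),
             x = c(first[1], hs[, 1]), y = c(first[2], hs[, 2]),
             z = c(first[3], hs[, 3]))
}

cap_length_table <- function() {
  if (is.null(.fragshare_cache$cap_lengths)) {
    path <- system.file("extdata", "cap_lengths_v1.json", package = "fragshare")
    .fragshare_cache$cap_lengths <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .fragshare_cache$cap_lengths
}

#' Cut a ligand into capped fragments
#'
#' Extracts each scheme fragment from the ligand (heavy atoms plus their
#' attached hydrogens) and caps every cut bond, producing a valence-complete
#' small molecule per fragment. Coordinates of every original atom are kept
#' bit-for-bit; only cap atoms are new. Formal charges of retained atoms are
#' unchanged, so e.g. a carboxylate fragment stays anionic. Cut bonds of order
#' > 1 are refused unless `allow_nonsingle = TRUE` (a hydrogen cap cannot
#' preserve the hybridization of a multiple bond).
#'
#' @param ligand a [molecule] with bonds.
#' @param scheme a [fragment_scheme] that validates against `ligand`.
#' @param allow_nonsingle permit cutting bonds of order > 1.
#' @return list of `capped_fragment` objects, one per scheme fragment, each
#'   with elements `fragment_id`, `label`, `molecule`, `original_atom_serials`,
#'   `cap_atom_indices`, `nh` (heavy atoms of the original fragment, caps
#'   excluded).
#' @export
cut_and_cap <- function(ligand, scheme, allow_nonsingle = FALSE) {
  rep_ok <- validate_scheme(ligand, scheme)
  if (!rep_ok$ok) {
    stop("invalid fragmentation scheme:\n  ",
         paste(rep_ok$errors, collapse = "\n  "))
  }
  if (!allow_nonsingle && nrow(scheme$cut_bonds)) {
    for (k in seq_len(nrow(scheme$cut_bonds))) {
      ord <- bond_order_of(ligand, scheme$cut_bonds[k, 1], scheme$cut_bonds[k, 2])
      if (!is.na(ord) && ord > 1) {
        stop("cut bond ", scheme$cut_bonds[k, 1], "-", scheme$cut_bonds[k, 2],
             " has order ", ord,
             "; set allow_nonsingle = TRUE to cut it anyway")
      }
    }
  }
  el <- ligand$atoms$element
  serial <- ligand$atoms$serial
  max_serial <- max(serial)
  lapply(names(scheme$fragments), function(id) {
    heavy_ser <- scheme$fragments[[id]]
    idx <- serial_to_index(ligand, heavy_ser)
    # bring along hydrogens bonded to the fragment's heavy atoms
    h_idx <- unlist(lapply(idx, function(i) {
      nb <- bonded_to(ligand, i)
      nb[el[nb] == "H"]
    }))
    keep <- sort(unique(c(idx, h_idx)))
    frag <- subset_molecule(ligand, keep, note = paste0("fragment ", id))
    frag$n_rot <- NA_integer_
    # caps: one per cut bond with exactly one end inside this fragment
    caps <- list()
    cb <- scheme$cut_bonds
    next_serial <- max_serial
    for (k in seq_len(nrow(cb))) {
      a <- cb[k, 1]; b <- cb[k, 2]
      a_in <- a %in% heavy_ser
      b_in <- b %in% heavy_ser
      if (a_in == b_in) next
      stub_ser <- if (a_in) a else b
      gone_ser <- if (a_in) b else a
      stub_row <- match(stub_ser, frag$atoms$serial)
      stub_xyz <- as.numeric(frag$atoms[stub_row, c("x", "y", "z")])
      gone_xyz <- as.numeric(ligand$atoms[match(gone_ser, serial), c("x", "y", "z")])
      nb_idx <- bonded_to(ligand, match(stub_ser, serial))
      nb_xyz <- coords(ligand)[setdiff(nb_idx, match(gone_ser, serial)), , drop = FALSE]
      cap <- place_cap(frag$atoms$element[stub_row], stub_xyz, gone_xyz,
                       cap_kind = scheme$cap, stub_neighbors = nb_xyz)
      # collision guard against existing fragment atoms
      fx <- coords(frag)
      d_all <- sqrt(colSums((t(fx) - as.numeric(cap[1, c("x", "y", "z")]))^2))
      if (min(d_all) < 0.5) {
        stop("cap placement collision at cut bond ", a, "-", b,
             " of fragment ", id, " (cap within 0.5 Angstrom of an existing atom)")
      }
      caps[[length(caps) + 1]] <- list(cap = cap, stub_serial = stub_ser)
    }
    cap_rows <- integer()
    for (cp in caps) {
      cap <- cp$cap
      n0 <- nrow(frag$atoms)
      new <- frag$atoms[rep(1, nrow(cap)), , drop = FALSE]
      new$element <- cap$element
      new$x <- cap$x; new$y <- cap$y; new$z <- cap$z
      new$serial <- next_serial + seq_len(nrow(cap))
      next_serial <- next_serial + nrow(cap)
      new$name <- ifelse(cap$element == "H", "HCP", "CCP")
      new$altloc <- ""
      new$partial_charge <- NA_real_
      new$ad_type <- NA_character_
      new$formal_charge <- 0L
      new$occupancy <- 1; new$bfactor <- 0
      frag$atoms <- rbind(frag$atoms, new)
      rownames(frag$atoms) <- NULL
      stub_row <- match(cp$stub_serial, frag$atoms$serial)
      add_bonds <- data.frame(i = stub_row, j = n0 + 1L, order = 1)
      if (nrow(cap) > 1) {  # methyl C-H bonds
        add_bonds <- rbind(add_bonds,
                           data.frame(i = n0 + 1L, j = n0 + 1L + seq_len(nrow(cap) - 1L),
                                      order = 1))
      }
      frag$bonds <- normalize_bonds(rbind(frag$bonds, add_bonds), nrow(frag$atoms))
      cap_rows <- c(cap_rows, n0 + seq_len(nrow(cap)))
    }
    structure(
      list(fragment_id = id, label = unname(scheme$labels[[id]]),
           molecule = frag,
           original_atom_serials = frag$atoms$serial[setdiff(seq_len(nrow(frag$atoms)), cap_rows)],
           cap_atom_indices = cap_rows,
           nh = length(heavy_ser)),
      class = "capped_fragment"
    )
  })
}

#' @export
print.capped_fragment <- function(x, ...) {
  cat("<capped_fragment> ", x$fragment_id, " (", x$label, "): NH = ", x$nh,
      ", ", length(x$cap_atom_indices), " cap atom(s)\n", sep = "")
  invisible(x)
}
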