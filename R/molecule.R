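#' Molecular structure container
#'
#' A `molecule` holds an ordered atom table, an explicit bond list and
#' provenance. Atom order is stable across read/write round trips; coordinates
#' are Cartesian Angstrom in the frame of the source file and are never
#' transformed by any function in this package.
#'
#' @param atoms data.frame with one row per atom. Required columns: `serial`
#'   (positive integer, 1-based as printed in the source file), `name`,
#'   `element`, `x`, `y`, `z`. Optional columns (filled with defaults when
#'   absent): `altloc`, `resname`, `chain`, `resid`, `segid`, `occupancy`,
#'   `bfactor`, `partial_charge`, `ad_type`, `formal_charge`, `hetatm`.
#' @param bonds data.frame with columns `i`, `j` (row indices into `atoms`,
#'   `i < j`, each bond stored once) and `order` (numeric bond order), or
#'   `NULL` for no bonds.
#' @param n_rot integer count of rotatable bonds (from a PDBQT `TORSDOF`
#'   record), or `NA` when unknown.
#' @param provenance free-text note recording source file and selection.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, n_rot = NA_integer_, provenance = "") {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  defaults <- list(
    altloc = "", resname = "LIG", chain = "A", resid = 1L, segid = "",
    occupancy = 1, bfactor = 0, partial_charge = NA_real_,
    ad_type = NA_character_, formal_charge = 0L, hetatm = TRUE
  )
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  bad <- !atoms$element %in% known_elements()
  if (any(bad)) {
    stop("unknown element '", atoms$element[which(bad)[1]], "' for atom serial ",
         atoms$serial[which(bad)[1]])
  }
  bonds <- normalize_bonds(bonds, nrow(atoms))
  structure(
    list(atoms = atoms, bonds = bonds, n_rot = as.integer(n_rot),
         provenance = provenance),
    class = "molecule"
  )
}

# canonical bond table: i < j, unique, no self bonds
normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || NROW(bonds) == 0) {
    return(data.frame(i = integer(), j = integer(), order = numeric()))
  }
  bonds <- as.data.frame(bonds)
  if (is.null(bonds$order)) bonds$order <- 1
  if (any(bonds$i == bonds$j)) stop("self-bond in bond list")
  if (any(bonds$i < 1 | bonds$j < 1 | bonds$i > n_atoms | bonds$j > n_atoms)) {
    stop("bond index out of range")
  }
  ii <- pmin(bonds$i, bonds$j)
  jj <- pmax(bonds$i, bonds$j)
  keep <- !duplicated(paste(ii, jj))
  data.frame(i = as.integer(ii[keep]), j = as.integer(jj[keep]),
             order = as.numeric(bonds$order[keep]))
}

known_elements <- function() {
  c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
    "B", "Si", "Se", "Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", nrow(x$atoms), " atoms (", sum(is_heavy(x)), " heavy), ",
      nrow(x$bonds), " bonds", sep = "")
  if (!is.na(x$n_rot)) cat(", ", x$n_rot, " rotatable bonds", sep = "")
  cat("\n")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Heavy-atom predicate and count
#'
#' @param mol a `molecule`
#' @return `is_heavy()`: logical vector over atoms; `n_heavy()`: integer count
#'   of non-hydrogen atoms.
#' @export
is_heavy <- function(mol) mol$atoms$element != "H"

#' @rdname is_heavy
#' @export
n_heavy <- function(mol) sum(is_heavy(mol))

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

# neighbor indices of atom i in the bond graph
bonded_to <- function(mol, i) {
  b <- mol$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}

# map 1-based file serials to atom-table row indices; error on misses
serial_to_index <- function(mol, serials) {
  idx <- match(serials, mol$atoms$serial)
  if (anyNA(idx)) {
    stop("serial(s) not present in molecule: ",
         paste(serials[is.na(idx)], collapse = ", "))
  }
  idx
}
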