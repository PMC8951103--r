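#' Select a component of a structure
#'
#' Filters atoms by chain, segment and/or residue name, applies an altloc
#' policy, and optionally strips solvent, mirroring the usual preparation of a
#' crystal structure for single-point scoring (keep one segment, remove waters
#' and alternative positions). Bonds between surviving atoms are kept; serials
#' and coordinates are untouched.
#'
#' @param mol a [molecule].
#' @param chains,segments,resnames character vectors of identifiers to keep
#'   (`NULL` = no filter on that field).
#' @param strip_solvent drop water residues (HOH, WAT, H2O, SOL, TIP3).
#' @param altloc policy for alternate locations: `"first"` keeps the
#'   first-listed alternative of each atom and warns about dropped ones;
#'   `"all"` keeps everything.
#' @return The filtered [molecule].
#' @export
select_component <- function(mol, chains = NULL, segments = NULL,
                             resnames = NULL, strip_solvent = FALSE,
                             altloc = c("first", "all")) {
  altloc <- match.arg(altloc)
  a <- mol$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(segments)) keep <- keep & a$segid %in% segments
  if (!is.null(resnames)) keep <- keep & a$resname %in% resnames
  if (strip_solvent) keep <- keep & !a$resname %in% c("HOH", "WAT", "H2O", "SOL", "TIP3")
  if (!any(keep)) {
    stop("empty selection; available chains: ",
         paste(unique(a$chain), collapse = ", "),
         "; segments: ", paste(unique(a$segid[nzchar(a$segid)]), collapse = ", "))
  }
  if (altloc == "first") {
    key <- paste(a$chain, a$segid, a$resid, a$resname, a$name)
    has_alt <- nzchar(a$altloc)
    dup <- duplicated(key) & has_alt
    dropped <- keep & dup
    if (any(dropped)) {
      warning("dropped ", sum(dropped), " alternate-location atom(s): ",
              paste(utils::head(paste0(a$name[dropped], "/", a$altloc[dropped]), 5),
                    collapse = ", "),
              if (sum(dropped) > 5) ", ..." else "")
    }
    keep <- keep & !dup
  }
  subset_molecule(mol, which(keep),
                  note = paste0("selection of ", sum(keep), "/", nrow(a), " atoms"))
}

# keep the given atom rows (indices), re-indexing bonds
subset_molecule <- function(mol, idx, note = "subset") {
  idx <- sort(unique(idx))
  atoms <- mol$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  remap <- integer(nrow(mol$atoms))
  remap[idx] <- seq_along(idx)
  b <- mol$bonds
  keepb <- b$i %in% idx & b$j %in% idx
  bonds <- data.frame(i = remap[b$i[keepb]], j = remap[b$j[keepb]],
                      order = b$order[keepb])
  molecule(atoms, bonds = bonds, n_rot = mol$n_rot,
           provenance = paste0(mol$provenance, "; ", note))
}

#' Assign interaction types for the built-in scoring function
#'
#' Stamps every atom with the flags and radius the pairwise scoring terms
#' need, from the versioned parameter table shipped with the package
#' (`extdata/sf_types_v1.csv`): carbon is hydrophobic unless bonded to N or O;
#' N and O are acceptors, and donors when they carry at least one hydrogen;
#' halogens are hydrophobic. Hydrogens are flagged non-interacting (they
#' contribute no pairs). Requires a bond list; call [perceive_bonds()] first
#' for PDB ligands without CONECT records.
#'
#' @param mol a [molecule] with bonds (a bond-free molecule is accepted; every
#'   carbon is then apolar and N/O are non-donors, which is only right for
#'   isolated probe atoms).
#' @return The molecule with columns `is_heavy`, `hydrophobic`, `donor`,
#'   `acceptor`, `radius` added to its atom table, and attribute
#'   `type_table_version` recorded.
#' @export
assign_interaction_types <- function(mol) {
  tab <- sf_type_table()
  el <- mol$atoms$element
  miss <- setdiff(unique(el), tab$element)
  if (length(miss)) {
    stop("element(s) absent from interaction-type parameter table: ",
         paste(miss, collapse = ", "))
  }
  row <- tab[match(el, tab$element), ]
  n <- nrow(mol$atoms)
  heavy <- el != "H"
  hydro <- donor <- accept <- logical(n)
  nb <- neighbor_elements(mol)
  for (k in seq_len(n)) {
    r <- row[k, ]
    if (r$hydrophobic == "TRUE") hydro[k] <- TRUE
    if (r$hydrophobic == "apolar_only") hydro[k] <- !any(nb[[k]] %in% c("N", "O"))
    if (isTRUE(as.logical(r$acceptor))) accept[k] <- TRUE
    if (isTRUE(as.logical(r$donor_if_h))) donor[k] <- any(nb[[k]] == "H")
  }
  mol$atoms$is_heavy <- heavy
  mol$atoms$hydrophobic <- hydro & heavy
  mol$atoms$donor <- donor & heavy
  mol$atoms$acceptor <- accept & heavy
  mol$atoms$radius <- ifelse(heavy, row$radius, 0)
  attr(mol, "type_table_version") <- attr(tab, "version")
  mol
}

neighbor_elements <- function(mol) {
  el <- mol$atoms$element
  out <- rep(list(character()), nrow(mol$atoms))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    out[[b$i[k]]] <- c(out[[b$i[k]]], el[b$j[k]])
    out[[b$j[k]]] <- c(out[[b$j[k]]], el[b$i[k]])
  }
  out
}

is_typed <- function(mol) {
  all(c("is_heavy", "hydrophobic", "donor", "acceptor", "radius") %in%
        names(mol$atoms))
}

# cached interaction-type table from the versioned config
sf_type_table <- function() {
  if (is.null(.fragshare_cache$sf_types)) {
    path <- system.file("extdata", "sf_types_v1.csv", package = "fragshare")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    attr(tab, "version") <- "sf_types_v1"
    .fragshare_cache$sf_types <- tab
  }
  .fragshare_cache$sf_types
}

.fragshare_cache <- new.env(parent = emptyenv())

#' Bundle receptor and ligand into one scored frame
#'
#' The receptor and ligand share a single Cartesian frame: no transform is
#' ever applied between them, since fragments must be scored at exactly the
#' position they occupy in the complex.
#'
#' @param receptor,ligand [molecule] objects in the same frame.
#' @param frame_note free text (e.g. "crystal, segment A" or "docked pose 7").
#' @return An object of class `complex_geometry`.
#' @export
complex_geometry <- function(receptor, ligand, frame_note = "") {
  stopifnot(inherits(receptor, "molecule"), inherits(ligand, "molecule"))
  structure(list(receptor = receptor, ligand = ligand, frame_note = frame_note),
            class = "complex_geometry")
}

#' @export
print.complex_geometry <- function(x, ...) {
  cat("<complex_geometry>\n  receptor: ", nrow(x$receptor$atoms), " atoms\n",
      "  ligand:   ", nrow(x$ligand$atoms), " atoms (",
      n_heavy(x$ligand), " heavy)\n", sep = "")
  if (nzchar(x$frame_note)) cat("  frame: ", x$frame_note, "\n", sep = "")
  invisible(x)
}
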