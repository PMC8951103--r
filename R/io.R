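#' Read a molecular structure from PDB or PDBQT
#'
#' Coordinates are kept exactly as printed (Angstrom, no re-centering or
#' rotation). For PDBQT, partial charges and AutoDock atom-type strings are
#' retained per atom, branching records (`ROOT`/`BRANCH`) are tolerated and
#' ignored for geometry, and a `TORSDOF` record is stored as the molecule's
#' rotatable-bond count. `CONECT` records define bonds when present; otherwise
#' bonds can be perceived later with [perceive_bonds()].
#'
#' @param path file path.
#' @param format `"pdb"`, `"pdbqt"`, or `"auto"` (from the file extension).
#' @param model for multi-model files, which MODEL block to read (default 1).
#' @return A [molecule].
#' @seealso [write_structure()], [read_poses()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pdbqt"), model = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  if (model > length(models)) {
    stop("requested MODEL ", model, " but file has ", length(models))
  }
  parse_structure_lines(models[[model]], format = format,
                        provenance = paste0(basename(path), " (", format, ")"))
}

#' Read a multi-pose file as a pose set
#'
#' Reads every `MODEL`/`ENDMDL` block of a multi-model PDB or multi-pose PDBQT
#' file (the layout docking programs emit). Scores are taken from
#' `REMARK VINA RESULT` lines when present.
#'
#' @inheritParams read_structure
#' @return A `pose_set`: list with `poses`, itself a list of
#'   `list(rank, molecule, score)` where `score` is a [score_value] or `NULL`.
#' @export
read_poses <- function(path, format = c("auto", "pdb", "pdbqt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  models <- split_models(readLines(path, warn = FALSE))
  poses <- lapply(seq_along(models), function(k) {
    block <- models[[k]]
    score <- NULL
    hit <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (length(hit)) {
      val <- suppressWarnings(as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "", hit[1])), "\\s+")[[1]][1]))
      if (is.finite(val)) {
        score <- score_value(val, units = "kcal_per_mol", backend_id = "docking",
                             favorable_direction = "negative_is_better")
      }
    }
    mol <- parse_structure_lines(block, format = format,
                                 provenance = paste0(basename(path), " pose ", k))
    list(rank = k, molecule = mol, score = score)
  })
  structure(list(poses = poses), class = "pose_set")
}

# split file lines into MODEL blocks (whole file if no MODEL records)
split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

# AutoDock atom type -> element
ad_type_to_element <- function(t) {
  map <- c(A = "C", C = "C", N = "N", NA. = "N", OA = "O", O = "O",
           HD = "H", HS = "H", H = "H", SA = "S", S = "S", P = "P",
           F = "F", Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I",
           Zn = "Zn", ZN = "Zn", Mg = "Mg", MG = "Mg", Ca = "Ca", CA = "Ca",
           Fe = "Fe", FE = "Fe", Mn = "Mn", MN = "Mn")
  key <- ifelse(t == "NA", "NA.", t)
  out <- unname(map[key])
  out
}

# guess element from a PDB atom name when the element column is blank
element_from_name <- function(name) {
  n <- gsub("[0-9'\\*\\+\\-]", "", trimws(name))
  two <- c("Cl", "CL", "Br", "BR", "Zn", "ZN", "Mg", "MG", "Fe", "FE",
           "Mn", "MN", "Se", "SE", "Si", "SI", "Na")
  first2 <- substr(n, 1, 2)
  out <- ifelse(first2 %in% two,
                paste0(substr(first2, 1, 1), tolower(substr(first2, 2, 2))),
                substr(n, 1, 1))
  # NA sodium vs N-alpha ambiguity: atom names starting with N are nitrogen
  out[substr(n, 1, 1) == "N"] <- "N"
  out
}

parse_structure_lines <- function(lines, format, provenance = "") {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  if (!length(atom_lines)) stop("no ATOM/HETATM records found")

  num_field <- function(txt, lo, hi, what) {
    raw <- trimws(substr(txt, lo, hi))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!nzchar(raw) | is.na(val))
    if (length(bad) && what %in% c("serial", "x", "y", "z")) {
      stop("malformed ATOM/HETATM record at line ", atom_lineno[bad[1]],
           ": cannot parse ", what, " from '", raw[bad[1]], "'")
    }
    val
  }

  serial <- as.integer(num_field(atom_lines, 7, 11, "serial"))
  name <- trimws(substr(atom_lines, 13, 16))
  altloc <- trimws(substr(atom_lines, 17, 17))
  resname <- trimws(substr(atom_lines, 18, 21))
  chain <- trimws(substr(atom_lines, 22, 22))
  resid <- suppressWarnings(as.integer(trimws(substr(atom_lines, 23, 26))))
  resid[is.na(resid)] <- 1L
  x <- num_field(atom_lines, 31, 38, "x")
  y <- num_field(atom_lines, 39, 46, "y")
  z <- num_field(atom_lines, 47, 54, "z")
  occupancy <- num_field(atom_lines, 55, 60, "occupancy")
  occupancy[is.na(occupancy)] <- 1
  bfactor <- num_field(atom_lines, 61, 66, "bfactor")
  bfactor[is.na(bfactor)] <- 0

  if (format == "pdbqt") {
    partial_charge <- num_field(atom_lines, 67, 76, "charge")
    ad_type <- trimws(substr(atom_lines, 77, 79))
    element <- ad_type_to_element(ad_type)
    segid <- rep("", length(serial))
    if (anyNA(element)) {
      k <- which(is.na(element))[1]
      stop("unknown AutoDock atom type '", ad_type[k], "' for atom serial ",
           serial[k], " (line ", atom_lineno[k], ")")
    }
  } else {
    segid <- trimws(substr(atom_lines, 73, 76))
    element_col <- trimws(substr(atom_lines, 77, 78))
    element <- ifelse(nzchar(element_col),
                      paste0(toupper(substr(element_col, 1, 1)),
                             tolower(substr(element_col, 2, 2))),
                      element_from_name(name))
    partial_charge <- rep(NA_real_, length(serial))
    ad_type <- rep(NA_character_, length(serial))
  }
  bad_el <- which(!element %in% known_elements())
  if (length(bad_el)) {
    stop("unknown element '", element[bad_el[1]], "' for atom '",
         name[bad_el[1]], "' (serial ", serial[bad_el[1]], ")")
  }

  atoms <- data.frame(
    serial = serial, name = name, altloc = altloc, resname = resname,
    chain = chain, resid = resid, segid = segid,
    x = x, y = y, z = z, occupancy = occupancy, bfactor = bfactor,
    partial_charge = partial_charge, ad_type = ad_type,
    element = element, formal_charge = 0L,
    hetatm = grepl("^HETATM", atom_lines)
  )

  # CONECT: serial pairs -> bond indices (records may repeat; dedup in molecule())
  bonds <- NULL
  conect <- lines[grepl("^CONECT", lines)]
  if (length(conect)) {
    pairs <- do.call(rbind, lapply(conect, function(l) {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]]))
      f <- f[!is.na(f)]
      if (length(f) < 2) return(NULL)
      cbind(f[1], f[-1])
    }))
    if (!is.null(pairs)) {
      i <- match(pairs[, 1], serial)
      j <- match(pairs[, 2], serial)
      ok <- !is.na(i) & !is.na(j)
      bonds <- data.frame(i = i[ok], j = j[ok], order = 1)
    }
  }

  n_rot <- NA_integer_
  tors <- grep("^TORSDOF", lines, value = TRUE)
  if (length(tors)) {
    n_rot <- suppressWarnings(as.integer(strsplit(trimws(tors[1]), "\\s+")[[1]][2]))
  }

  molecule(atoms, bonds = bonds, n_rot = n_rot, provenance = provenance)
}

#' Write a molecule to PDB or PDBQT
#'
#' PDB output goes through `bio3d::write.pdb()` with `CONECT` records appended
#' for any explicit bonds. PDBQT output carries partial charges (0 when
#' unknown) and AutoDock atom types (stored types verbatim, otherwise derived
#' from the element and bonding), plus a `TORSDOF` record when the count is
#' known.
#'
#' @param mol a [molecule].
#' @param path output file path.
#' @param format `"pdb"`, `"pdbqt"`, or `"auto"` (from the extension).
#' @param conect write CONECT records for PDB output (default TRUE).
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = c("auto", "pdb", "pdbqt"),
                            conect = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  a <- mol$atoms
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(coords(mol))),
      type = ifelse(a$hetatm, "HETATM", "ATOM"),
      eleno = a$serial, elety = a$name,
      resid = a$resname, chain = ifelse(nzchar(a$chain), a$chain, " "),
      resno = a$resid, o = a$occupancy, b = a$bfactor,
      segid = a$segid, elesy = a$element
    )
    if (conect && nrow(mol$bonds)) {
      lines <- readLines(path, warn = FALSE)
      con <- sprintf("CONECT%5d%5d", a$serial[mol$bonds$i], a$serial[mol$bonds$j])
      end_at <- grep("^END", lines)
      insert_at <- if (length(end_at)) end_at[length(end_at)] else length(lines) + 1L
      lines <- append(lines, con, after = insert_at - 1L)
      writeLines(lines, path)
    }
  } else {
    q <- a$partial_charge
    q[is.na(q)] <- 0
    adt <- a$ad_type
    if (anyNA(adt)) adt[is.na(adt)] <- derive_ad_type(mol)[is.na(adt)]
    rec <- sprintf("%-6s%5d %-4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
                   ifelse(a$hetatm, "HETATM", "ATOM"), a$serial,
                   formatC(a$name, width = 4, flag = "-"), substr(paste0(a$altloc, " "), 1, 1),
                   a$resname, ifelse(nzchar(a$chain), a$chain, "A"), a$resid,
                   a$x, a$y, a$z, a$occupancy, a$bfactor, q, adt)
    out <- c("ROOT", rec, "ENDROOT")
    if (conect && nrow(mol$bonds)) {
      out <- c(out, sprintf("CONECT%5d%5d",
                            a$serial[mol$bonds$i], a$serial[mol$bonds$j]))
    }
    if (!is.na(mol$n_rot)) out <- c(out, sprintf("TORSDOF %d", mol$n_rot))
    writeLines(out, path)
  }
  invisible(path)
}

# minimal element -> AutoDock type derivation for writing
derive_ad_type <- function(mol) {
  el <- mol$atoms$element
  out <- el
  out[el == "O"] <- "OA"
  out[el == "N"] <- "NA"
  out[el == "S"] <- "SA"
  if (el[1] == "H" || any(el == "H")) {
    hh <- which(el == "H")
    for (k in hh) {
      nb <- bonded_to(mol, k)
      out[k] <- if (length(nb) && any(el[nb] %in% c("N", "O", "S"))) "HD" else "H"
    }
  }
  out
}

#' Perceive bonds from interatomic distances
#'
#' Adds bonds between atom pairs whose distance is below the sum of covalent
#' radii plus `tol`. Existing (e.g. CONECT-derived) bonds always win: when the
#' molecule already has bonds, they are kept and only missing pairs are added
#' when `augment = TRUE` (default FALSE leaves an existing bond list alone).
#'
#' @param mol a [molecule].
#' @param tol slack added to the covalent-radius sum, Angstrom (default 0.45).
#' @param augment add perceived bonds even when explicit bonds exist.
#' @return The molecule with a populated bond list.
#' @export
perceive_bonds <- function(mol, tol = 0.45, augment = FALSE) {
  if (nrow(mol$bonds) && !augment) return(mol)
  rc <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
          F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Si = 1.11,
          Se = 1.20, Zn = 1.22, Mg = 1.41, Ca = 1.76, Fe = 1.32, Mn = 1.39,
          Na = 1.66, K = 2.03, Cu = 1.32)
  r <- rc[mol$atoms$element]
  r[is.na(r)] <- 1.0
  xyz <- coords(mol)
  n <- nrow(xyz)
  new <- list()
  for (i in seq_len(max(0, n - 1))) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    thr <- r[i] + r[(i + 1):n] + tol
    hit <- which(d < thr & d > 0.4)
    if (length(hit)) new[[length(new) + 1]] <- data.frame(i = i, j = i + hit, order = 1)
  }
  add <- if (length(new)) do.call(rbind, new) else NULL
  mol$bonds <- normalize_bonds(rbind(mol$bonds, add), n)
  mol
}
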