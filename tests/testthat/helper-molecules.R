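# Builders for small in-memory molecules and random scored fixtures.

# bonded chain of heavy atoms along x (spacing in Angstrom)
chain_molecule <- function(elements, spacing = 1.54) {
  n <- length(elements)
  atoms <- data.frame(serial = seq_len(n),
                      name = paste0(elements, seq_len(n)),
                      element = elements,
                      x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
  bonds <- if (n > 1) data.frame(i = 1:(n - 1), j = 2:n, order = 1) else NULL
  molecule(atoms, bonds = bonds)
}

# random cloud of typed atoms in a box, with hydrogens attached to some N/O
# so donor-acceptor pairs occur; returns an untyped molecule with bonds
random_cloud <- function(n, seed, box = c(0, 8), elements = c("C", "N", "O", "S", "F")) {
  set.seed(seed)
  el <- sample(elements, n, replace = TRUE)
  atoms <- data.frame(serial = seq_len(n), name = paste0(el, seq_len(n)),
                      element = el,
                      x = runif(n, box[1], box[2]),
                      y = runif(n, box[1], box[2]),
                      z = runif(n, box[1], box[2]))
  bonds <- NULL
  polar <- which(el %in% c("N", "O"))
  give_h <- polar[runif(length(polar)) < 0.5]
  if (length(give_h)) {
    hrows <- data.frame(serial = n + seq_along(give_h),
                        name = paste0("H", seq_along(give_h)),
                        element = "H",
                        x = atoms$x[give_h] + 1.0, y = atoms$y[give_h],
                        z = atoms$z[give_h])
    atoms <- rbind(atoms, hrows)
    bonds <- data.frame(i = give_h, j = n + seq_along(give_h), order = 1)
  }
  molecule(atoms, bonds = bonds)
}

# minimal PDB ATOM/HETATM line with correct fixed columns
pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     element, record = "HETATM", altloc = " ", segid = "    ") {
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
          record, serial, name, altloc, resname, chain, resid,
          x, y, z, 1, 0, segid, element)
}

write_tmp_lines <- function(lines, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# rotation matrix from axis-angle (for frame-invariance checks)
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  outer(u, u) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) * s
}

transform_molecule <- function(mol, R, t) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
  mol$atoms$x <- xyz[, 1] + t[1]
  mol$atoms$y <- xyz[, 2] + t[2]
  mol$atoms$z <- xyz[, 3] + t[3]
  mol
}
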