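#' Thermodynamic context
#'
#' Carries the temperature used to convert measured dissociation/inhibition
#' constants into free energies, RT = R * T with
#' R = 1.98720425e-3 kcal/(mol K). At the default 298.15 K, RT is about
#' 0.593 kcal/mol.
#'
#' @param temperature Kelvin.
#' @return list with `temperature` and `RT` (kcal/mol), class
#'   `thermo_context`.
#' @export
thermo_context <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  R_kcal <- 1.98720425e-3
  structure(list(temperature = temperature, RT = R_kcal * temperature),
            class = "thermo_context")
}

#' Free energy from an experimental measurement
#'
#' Converts a molar K_D, K_i or IC50 into a binding free energy
#' `delta_G = RT * ln(value)` (kcal/mol; negative for sub-molar binders).
#' IC50 is only an approximation to a true dissociation constant and is
#' flagged as such in the provenance note.
#'
#' @param value molar concentration, > 0.
#' @param kind `"kd"`, `"ki"` or `"ic50"`.
#' @param ctx a [thermo_context].
#' @return A [binding_affinity].
#' @export
delta_g_from_measurement <- function(value, kind = c("kd", "ki", "ic50"),
                                     ctx = thermo_context()) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) || value <= 0) {
    stop("measurement must be a single positive molar concentration")
  }
  dg <- ctx$RT * log(value)
  source <- switch(kind, kd = "experimental_kd", ki = "experimental_ki",
                   ic50 = "experimental_ic50")
  note <- sprintf("RT ln(%g M) at T = %.2f K", value, ctx$temperature)
  if (kind == "ic50") note <- paste0(note, "; IC50-derived, approximate")
  binding_affinity(dg, source = source, note = note)
}

#' Ligand efficiency
#'
#' Binding free energy magnitude per heavy atom,
#' `LE = -delta_G / NH` (kcal/mol/atom, positive for favorable binding).
#' The customary drug-likeness threshold is 0.30 kcal/mol/atom. Values are
#' kept at full precision; round only at report time (2 decimals by
#' convention).
#'
#' @param affinity a [binding_affinity] or a numeric delta_G in kcal/mol.
#' @param nh heavy-atom count, >= 1.
#' @return numeric LE.
#' @export
ligand_efficiency <- function(affinity, nh) {
  dg <- if (inherits(affinity, "binding_affinity")) affinity$delta_g else affinity
  if (!is.numeric(nh) || any(nh < 1)) stop("nh must be >= 1")
  -dg / nh
}

#' Group efficiency of fragment contributions
#'
#' The fragment-level analog of ligand efficiency: each fragment's scaled
#' energy contribution per heavy atom of that fragment,
#' `GE_j = -E_j_scaled / NH_j`, reported with the same positive-favorable
#' sign convention as LE. For a single-fragment partition GE reduces exactly
#' to LE, and over any valid partition `sum(GE_j * NH_j) = |delta_E_mol|`.
#' Heavy-atom counts exclude cap atoms: caps are artifacts of the
#' fragmentation, not of the fragment.
#'
#' @param contribs a `contribution_table` from [scaled_contributions()], or a
#'   numeric vector of scaled energies.
#' @param nh named (by fragment id) or parallel vector of heavy-atom counts.
#' @param threshold flag level, kcal/mol/atom (default 0.30, the customary LE
#'   threshold for drug-like molecules).
#' @return data.frame with `fragment_id`, `omega`, `e_scaled`, `nh`, `ge`,
#'   `below_threshold`, class `ge_table`.
#' @export
group_efficiency <- function(contribs, nh, threshold = 0.30) {
  if (is.data.frame(contribs)) {
    ids <- contribs$fragment_id
    e <- contribs$e_scaled
    omega <- contribs$omega %||% rep(NA_real_, length(e))
  } else {
    e <- as.numeric(contribs)
    ids <- names(contribs) %||% as.character(seq_along(e))
    omega <- rep(NA_real_, length(e))
  }
  if (!is.null(names(nh))) nh <- nh[ids]
  nh <- as.numeric(nh)
  if (length(nh) != length(e) || anyNA(nh)) {
    stop("nh must supply one heavy-atom count per fragment")
  }
  if (any(nh < 1)) {
    stop("fragment(s) with NH < 1 (only hydrogens?): ",
         paste(ids[nh < 1], collapse = ", "))
  }
  out <- data.frame(fragment_id = ids, omega = omega, e_scaled = e,
                    nh = nh, ge = -e / nh)
  out$below_threshold <- out$ge < threshold
  attr(out, "threshold") <- threshold
  attr(out, "affinity") <- attr(contribs, "affinity")
  attr(out, "backend_id") <- attr(contribs, "backend_id")
  class(out) <- c("ge_table", "data.frame")
  out
}
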