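#' Scoring-function parameter sets
#'
#' Loads a named parameter set of the built-in empirical pairwise scoring
#' function from the versioned config shipped with the package
#' (`extdata/sf_params_v1.json`). The functional form is a weighted sum, over
#' intermolecular heavy-atom pairs, of five terms of the surface distance
#' d = r − R_i − R_j: two Gaussians, a quadratic repulsion for d < 0, and
#' piecewise-linear hydrophobic (both atoms hydrophobic) and hydrogen-bond
#' (donor–acceptor pair) ramps. `"vina"` uses the published empirical weights
#' of that functional form; `"vinardo"` is the re-tuned variant (wider single
#' Gaussian, longer hydrophobic ramp, stronger h-bond term).
#'
#' @param set `"vina"` or `"vinardo"`.
#' @param ... named overrides of individual parameters (e.g. `cutoff = 10`);
#'   any override changes `parameter_set_id` to `"custom"`.
#' @return An object of class `sf_params`.
#' @export
sf_params <- function(set = c("vina", "vinardo"), ...) {
  set <- match.arg(set)
  if (is.null(.fragshare_cache$sf_params)) {
    path <- system.file("extdata", "sf_params_v1.json", package = "fragshare")
    .fragshare_cache$sf_params <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- .fragshare_cache$sf_params[[paste0(set, "_default")]]
  cfg$weights <- unlist(cfg$weights)
  cfg$parameter_set_id <- paste0(set, "_default")
  cfg$backend_id <- paste0("builtin_", set)
  dots <- list(...)
  if (length(dots)) {
    for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
    cfg$parameter_set_id <- "custom"
  }
  stopifnot(cfg$cutoff > 0, all(is.finite(cfg$weights)))
  structure(cfg, class = "sf_params")
}

#' @export
print.sf_params <- function(x, ...) {
  cat("<sf_params> ", x$parameter_set_id, " (backend ", x$backend_id, ")\n",
      "  weights: ", paste(names(x$weights), sprintf("%.6g", x$weights),
                           sep = "=", collapse = ", "), "\n",
      "  cutoff: ", x$cutoff, " A (surface distance)\n", sep = "")
  invisible(x)
}

#' A scored value with units and provenance
#'
#' Scores from different backends live in different units (kcal/mol, pKd,
#' knowledge-based pseudo-energies); every value therefore carries its units
#' and which direction is favorable, and cross-backend comparisons are only
#' meaningful on derived unitless quantities (shares) or unit-consistent ones
#' (group efficiencies).
#'
#' @param value numeric scalar.
#' @param units one of `"kcal_per_mol"`, `"pKd"`, `"knowledge_based"`,
#'   `"unitless"`.
#' @param backend_id identifier of the producing backend.
#' @param favorable_direction `"negative_is_better"` or
#'   `"positive_is_better"`.
#' @param provenance free text (parameter-set id, raw output reference, ...).
#' @return An object of class `score_value`.
#' @export
score_value <- function(value,
                        units = c("kcal_per_mol", "pKd", "knowledge_based", "unitless"),
                        backend_id = "unknown",
                        favorable_direction = c("negative_is_better", "positive_is_better"),
                        provenance = "") {
  units <- match.arg(units)
  favorable_direction <- match.arg(favorable_direction)
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(value = value, units = units, backend_id = backend_id,
                 favorable_direction = favorable_direction,
                 provenance = provenance),
            class = "score_value")
}

#' @export
print.score_value <- function(x, ...) {
  cat(sprintf("<score_value> %.4f %s [%s, %s]\n", x$value, x$units,
              x$backend_id, x$favorable_direction))
  invisible(x)
}

#' Unweighted pairwise terms at a surface distance
#'
#' Evaluates the five term values for one atom pair at surface distance
#' `d = r - R_i - R_j`: `gauss1 = exp(-((d-o1)/w1)^2)`, `gauss2` likewise,
#' `repulsion = d^2` for `d < 0` (0 otherwise), and hydrophobic / h-bond
#' ramps that are 1 below their lower knot, 0 above their upper knot and
#' linear in between. The hydrophobic term is nonzero only when both atoms
#' are hydrophobic; the h-bond term only for a donor–acceptor pair. Pairs at
#' `d >= cutoff` are excluded entirely (all terms 0).
#'
#' @param surface_distance numeric vector d, Angstrom.
#' @param types_i,types_j lists (or data.frame rows) with logical fields
#'   `hydrophobic`, `donor`, `acceptor` for the two atoms.
#' @param params an [sf_params].
#' @return matrix with columns `gauss1`, `gauss2`, `repulsion`,
#'   `hydrophobic`, `hbond`, one row per element of `surface_distance`.
#' @export
pair_terms <- function(surface_distance, types_i, types_j, params) {
  d <- as.numeric(surface_distance)
  ramp <- function(d, lo, hi) {
    out <- (hi - d) / (hi - lo)
    out[d <= lo] <- 1
    out[d >= hi] <- 0
    out
  }
  g1 <- exp(-((d - params$gauss1_offset) / params$gauss1_width)^2)
  g2 <- exp(-((d - params$gauss2_offset) / params$gauss2_width)^2)
  rep_t <- ifelse(d < 0, d^2, 0)
  both_hydro <- isTRUE(types_i$hydrophobic) && isTRUE(types_j$hydrophobic)
  da_pair <- (isTRUE(types_i$donor) && isTRUE(types_j$acceptor)) ||
    (isTRUE(types_j$donor) && isTRUE(types_i$acceptor))
  hyd <- if (both_hydro) ramp(d, params$hydrophobic_lo, params$hydrophobic_hi) else 0 * d
  hb <- if (da_pair) ramp(d, params$hbond_lo, params$hbond_hi) else 0 * d
  out <- cbind(gauss1 = g1, gauss2 = g2, repulsion = rep_t,
               hydrophobic = hyd, hbond = hb)
  out[d >= params$cutoff, ] <- 0
  out
}

#' Single-point score of a molecule against a receptor
#'
#' Sums the weighted pairwise terms over all intermolecular heavy-atom pairs
#' within the cutoff — a pure single-point evaluation at the given
#' coordinates: no optimization, no docking, no intramolecular terms.
#' Hydrogens contribute no pairs. With `apply_nrot_scaling = TRUE` the pair
#' sum is divided by `1 + w_rot * n_rot` (the conformational-entropy penalty
#' whole-ligand scores usually carry); fragment shares are formed from
#' unscaled sums by default since they compare in-place interaction strength.
#'
#' @param receptor,mol [molecule] objects with interaction types assigned
#'   (see [assign_interaction_types()]) sharing one Cartesian frame.
#' @param params an [sf_params].
#' @param apply_nrot_scaling divide by `1 + w_rot * n_rot` using the
#'   molecule's recorded rotatable-bond count (0 when unknown).
#' @return A [score_value] in kcal/mol (negative favorable).
#' @export
score_pose <- function(receptor, mol, params = sf_params("vina"),
                       apply_nrot_scaling = FALSE) {
  if (!nrow(mol$atoms)) stop("empty molecule")
  if (!nrow(receptor$atoms)) stop("empty receptor")
  if (!is_typed(receptor) || !is_typed(mol)) {
    stop("atoms are untyped; run assign_interaction_types() on receptor and molecule first")
  }
  ra <- receptor$atoms[receptor$atoms$is_heavy, , drop = FALSE]
  la <- mol$atoms[mol$atoms$is_heavy, , drop = FALSE]
  value <- 0
  if (nrow(ra) && nrow(la)) {
    rx <- as.matrix(ra[, c("x", "y", "z")])
    lx <- as.matrix(la[, c("x", "y", "z")])
    # pair matrices (N x M): distances and surface distances
    d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
    d2[d2 < 0] <- 0
    d <- sqrt(d2) - outer(ra$radius, la$radius, "+")
    within <- d < params$cutoff
    g1 <- exp(-((d - params$gauss1_offset) / params$gauss1_width)^2)
    g2 <- exp(-((d - params$gauss2_offset) / params$gauss2_width)^2)
    rep_t <- ifelse(d < 0, d^2, 0)
    ramp_m <- function(d, lo, hi) pmin(1, pmax(0, (hi - d) / (hi - lo)))
    hyd <- ramp_m(d, params$hydrophobic_lo, params$hydrophobic_hi) *
      outer(ra$hydrophobic, la$hydrophobic, "&")
    da <- outer(ra$donor, la$acceptor, "&") | outer(ra$acceptor, la$donor, "&")
    hb <- ramp_m(d, params$hbond_lo, params$hbond_hi) * da
    w <- params$weights
    total <- w[["gauss1"]] * g1 + w[["gauss2"]] * g2 +
      w[["repulsion"]] * rep_t + w[["hydrophobic"]] * hyd + w[["hbond"]] * hb
    value <- sum(total[within])
  }
  if (apply_nrot_scaling) {
    n_rot <- if (is.na(mol$n_rot)) 0L else mol$n_rot
    value <- value / (1 + params$w_rot * n_rot)
  }
  score_value(value, units = "kcal_per_mol", backend_id = params$backend_id,
              favorable_direction = "negative_is_better",
              provenance = params$parameter_set_id)
}

#' External score-only backend adapter
#'
#' Declares how to run a third-party scoring program in score-only mode and
#' how to read one scalar back from its output. The adapter is contract-only:
#' the command template receives the receptor and molecule file paths via the
#' placeholders `{receptor}` and `{ligand}`, and `pattern` must contain one
#' capture group matching the score. Raw output is kept on the returned value
#' for audit.
#'
#' @param id backend identifier.
#' @param command_template shell command with `{receptor}` and `{ligand}`
#'   placeholders.
#' @param pattern regular expression with exactly one capture group.
#' @param units,favorable_direction as in [score_value()].
#' @return An object of class `external_backend`.
#' @export
external_backend <- function(id, command_template, pattern,
                             units = c("kcal_per_mol", "pKd", "knowledge_based", "unitless"),
                             favorable_direction = c("negative_is_better", "positive_is_better")) {
  units <- match.arg(units)
  favorable_direction <- match.arg(favorable_direction)
  structure(list(id = id, command_template = command_template,
                 pattern = pattern, units = units,
                 favorable_direction = favorable_direction),
            class = "external_backend")
}

#' Run an external score-only backend
#'
#' @param adapter an [external_backend].
#' @param receptor_file,mol_file paths to the already-written structure files.
#' @return A [score_value]; the captured program output is attached as the
#'   `raw_output` attribute.
#' @export
external_score <- function(adapter, receptor_file, mol_file) {
  cmd <- gsub("{receptor}", receptor_file,
              gsub("{ligand}", mol_file, adapter$command_template, fixed = TRUE),
              fixed = TRUE)
  out <- tryCatch(
    system(cmd, intern = TRUE, ignore.stderr = FALSE),
    warning = function(w) {
      stop("external backend '", adapter$id, "' exited abnormally: ",
           conditionMessage(w))
    },
    error = function(e) {
      stop("external backend '", adapter$id, "' failed to run: ",
           conditionMessage(e))
    }
  )
  m <- regexec(adapter$pattern, out)
  hits <- regmatches(out, m)
  val <- NA_real_
  for (h in hits) {
    if (length(h) >= 2) {
      val <- suppressWarnings(as.numeric(h[2]))
      if (is.finite(val)) break
    }
  }
  if (!is.finite(val)) {
    stop("external backend '", adapter$id,
         "' produced no parseable score; captured output:\n",
         paste(out, collapse = "\n"))
  }
  sv <- score_value(val, units = adapter$units, backend_id = adapter$id,
                    favorable_direction = adapter$favorable_direction,
                    provenance = paste0("external: ", adapter$command_template))
  attr(sv, "raw_output") <- out
  sv
}
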