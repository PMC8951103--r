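#' Partition a ligand's binding affinity into fragment contributions
#'
#' The package's main entry point. For each scoring backend it runs the full
#' chain: cut the ligand into capped fragments at their in-complex
#' coordinates, score every fragment against the receptor single-point,
#' form stakeholder shares, scale them by the molecular interaction energy,
#' and convert the additive contributions into group efficiencies. Results
#' across backends are aggregated into a consensus table (unweighted mean and
#' SD of GE per fragment — GE is unit-consistent across backends even when
#' their raw scores are not) and annotated with decision flags.
#'
#' @param complex a [complex_geometry] (receptor and ligand in one frame).
#' @param scheme a [fragment_scheme] for the ligand.
#' @param affinity a [binding_affinity]: the whole-ligand interaction energy
#'   to partition (experimental or scored), kcal/mol.
#' @param backends list of [sf_params] (built-in) and/or [external_backend]
#'   adapters; must be non-empty.
#' @param threshold GE flag level, kcal/mol/atom (default 0.30).
#' @param anchor optional fragment id of the anchor fragment (the
#'   experimentally positioned one); enables the anchor-violation diagnostic.
#' @param mixed_sign_policy passed to [share_vector()].
#' @param allow_nonsingle passed to [cut_and_cap()].
#' @return An object of class `fragshare` with components `consensus` (the
#'   per-fragment table), `per_backend` (list of [ge_table][group_efficiency]
#'   data.frames), `raw_scores` (fragments x backends matrix of backend-unit
#'   scores), `fragments`, `affinity`, `flags`, and metadata. Methods:
#'   `print`, `summary`, `coef`, `plot`, `as.data.frame`.
#' @examples
#' toy <- make_toy_complex(fixture_spec(probes_per_fragment = c(3, 1)))
#' fit <- partition_affinity(toy$complex, toy$scheme,
#'                           affinity = binding_affinity(-8, "scored"))
#' coef(fit)
#' @export
partition_affinity <- function(complex, scheme, affinity,
                               backends = list(sf_params("vina")),
                               threshold = 0.30, anchor = NULL,
                               mixed_sign_policy = "error",
                               allow_nonsingle = FALSE) {
  stopifnot(inherits(complex, "complex_geometry"),
            inherits(scheme, "fragment_scheme"),
            inherits(affinity, "binding_affinity"))
  if (!length(backends)) stop("empty backend list")
  ligand <- complex$ligand
  if (!nrow(ligand$bonds)) ligand <- perceive_bonds(ligand)
  rep_ok <- validate_scheme(ligand, scheme)
  if (!rep_ok$ok) {
    stop("scheme does not validate:\n  ", paste(rep_ok$errors, collapse = "\n  "))
  }
  fragments <- cut_and_cap(ligand, scheme, allow_nonsingle = allow_nonsingle)
  frag_ids <- vapply(fragments, `[[`, "", "fragment_id")
  nh <- stats::setNames(vapply(fragments, `[[`, 0L, "nh"), frag_ids)

  receptor_typed <- if (is_typed(complex$receptor)) complex$receptor else
    assign_interaction_types(complex$receptor)

  backend_ids <- character()
  per_backend <- list()
  raw_scores <- matrix(NA_real_, nrow = length(frag_ids), ncol = 0,
                       dimnames = list(frag_ids, NULL))
  for (bk in backends) {
    if (inherits(bk, "sf_params")) {
      id <- bk$backend_id
      svals <- vapply(fragments, function(fr) {
        m <- assign_interaction_types(fr$molecule)
        score_pose(receptor_typed, m, bk)$value
      }, numeric(1))
      fss <- fragment_scores(frag_ids, svals, backend_id = id,
                             units = "kcal_per_mol",
                             favorable_direction = "negative_is_better")
    } else if (inherits(bk, "external_backend")) {
      id <- bk$id
      tmp <- tempfile("fragshare_")
      dir.create(tmp)
      rec_file <- file.path(tmp, "receptor.pdbqt")
      write_structure(complex$receptor, rec_file)
      svals <- vapply(fragments, function(fr) {
        f <- file.path(tmp, paste0(fr$fragment_id, ".pdbqt"))
        write_structure(fr$molecule, f)
        external_score(bk, rec_file, f)$value
      }, numeric(1))
      fss <- fragment_scores(frag_ids, svals, backend_id = id,
                             units = bk$units,
                             favorable_direction = bk$favorable_direction)
    } else {
      stop("backend must be an sf_params or external_backend object")
    }
    shares <- share_vector(fss, mixed_sign_policy = mixed_sign_policy)
    contribs <- scaled_contributions(shares, affinity)
    ge <- group_efficiency(contribs, nh, threshold = threshold)
    backend_ids <- c(backend_ids, id)
    per_backend[[id]] <- ge
    raw_scores <- cbind(raw_scores, fss$entries$score)
  }
  colnames(raw_scores) <- backend_ids

  omega_mat <- vapply(per_backend, function(g) g$omega, numeric(length(frag_ids)))
  ge_mat <- vapply(per_backend, function(g) g$ge, numeric(length(frag_ids)))
  e_mat <- vapply(per_backend, function(g) g$e_scaled, numeric(length(frag_ids)))
  if (length(frag_ids) == 1) {
    omega_mat <- matrix(omega_mat, 1); ge_mat <- matrix(ge_mat, 1)
    e_mat <- matrix(e_mat, 1)
  }
  consensus <- data.frame(
    fragment_id = frag_ids,
    label = vapply(fragments, `[[`, "", "label"),
    nh = as.integer(nh),
    mean_omega = rowMeans(omega_mat),
    mean_e_scaled = rowMeans(e_mat),
    mean_ge = rowMeans(ge_mat),
    sd_ge = apply(ge_mat, 1, stats::sd)
  )
  fit <- structure(
    list(consensus = consensus, per_backend = per_backend,
         raw_scores = raw_scores,
         fragments = fragments, affinity = affinity,
         threshold = threshold, anchor = anchor,
         scheme = scheme,
         frame_note = complex$frame_note,
         validation = rep_ok,
         call = match.call()),
    class = "fragshare"
  )
  fit$consensus <- flag_decisions(fit$consensus, threshold = threshold,
                                  anchor = anchor)
  fit
}

#' Annotate a consensus table with decision flags
#'
#' Applies the decision heuristics of the method: fragments whose mean GE
#' falls below the threshold are flagged; the below-threshold fragment with
#' the lowest mean GE is recommended as the optimization focus; and, when an
#' anchor fragment is named, an anchor violation is raised if any non-anchor
#' fragment's mean contribution magnitude reaches the anchor's — the sign
#' that the pose contradicts the premise that the experimentally placed
#' fragment dominates the binding, so that pose should not ground further
#' optimization.
#'
#' @param table consensus data.frame with columns `fragment_id`, `mean_ge`,
#'   `mean_e_scaled` (as built by [partition_affinity()]).
#' @param threshold GE flag level, kcal/mol/atom.
#' @param anchor anchor fragment id, or `NULL` to skip the anchor check.
#' @param anchor_slack fraction of the anchor's contribution magnitude a
#'   non-anchor fragment must reach to trigger the violation (default 1,
#'   i.e. greater-or-equal).
#' @return The table with `below_threshold` and `anchor_violation` columns
#'   and attributes `optimization_focus` (fragment id or `NA`) and
#'   `anchor_violation` (logical).
#' @export
flag_decisions <- function(table, threshold = 0.30, anchor = NULL,
                           anchor_slack = 1) {
  stopifnot(all(c("fragment_id", "mean_ge", "mean_e_scaled") %in% names(table)))
  table$below_threshold <- table$mean_ge < threshold
  focus <- NA_character_
  if (any(table$below_threshold)) {
    sub <- table[table$below_threshold, ]
    focus <- sub$fragment_id[which.min(sub$mean_ge)]
  }
  violation <- FALSE
  table$anchor_violation <- FALSE
  if (!is.null(anchor)) {
    if (!anchor %in% table$fragment_id) {
      stop("unknown anchor fragment id: ", anchor)
    }
    mag <- abs(table$mean_e_scaled)
    a_mag <- mag[table$fragment_id == anchor]
    offender <- table$fragment_id != anchor & mag >= anchor_slack * a_mag
    table$anchor_violation <- offender
    violation <- any(offender)
  }
  attr(table, "optimization_focus") <- focus
  attr(table, "anchor_violation") <- violation
  attr(table, "threshold") <- threshold
  attr(table, "anchor") <- anchor
  table
}

#' @export
print.fragshare <- function(x, digits = 3, ...) {
  cat("Fragment contribution analysis (stakeholder partition)\n")
  cat(sprintf("  interaction energy: %.3f kcal/mol (%s)\n",
              x$affinity$delta_g, x$affinity$source))
  cat("  backends: ", paste(colnames(x$raw_scores), collapse = ", "), "\n",
      sep = "")
  tab <- x$consensus
  show <- data.frame(fragment = tab$fragment_id, label = tab$label,
                     NH = tab$nh,
                     omega = round(tab$mean_omega, digits),
                     E_scaled = round(tab$mean_e_scaled, digits),
                     GE = round(tab$mean_ge, 2),
                     sd = round(tab$sd_ge, digits),
                     flag = ifelse(tab$below_threshold, "<thr", ""))
  print(show, row.names = FALSE)
  focus <- attr(tab, "optimization_focus")
  if (!is.na(focus)) {
    cat("  optimization focus: ", focus, " (lowest mean GE below ",
        x$threshold, " kcal/mol/atom)\n", sep = "")
  } else {
    cat("  no suboptimal fragment: all GE at or above ", x$threshold,
        " kcal/mol/atom\n", sep = "")
  }
  if (isTRUE(attr(tab, "anchor_violation"))) {
    cat("  WARNING: anchor violation - a non-anchor fragment's contribution",
        "reaches the anchor's;\n  this geometry should not ground further",
        "optimization\n")
  }
  invisible(x)
}

#' @export
summary.fragshare <- function(object, ...) {
  structure(list(fit = object), class = "summary.fragshare")
}

#' @export
print.summary.fragshare <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nRaw per-fragment scores (backend units):\n")
  print(round(fit$raw_scores, 4))
  cat("\nPer-backend shares:\n")
  om <- vapply(fit$per_backend, function(g) g$omega,
               numeric(nrow(fit$consensus)))
  if (is.null(dim(om))) om <- matrix(om, nrow = nrow(fit$consensus),
                                     dimnames = list(NULL, names(fit$per_backend)))
  rownames(om) <- fit$consensus$fragment_id
  print(round(om, 4))
  if (nzchar(fit$frame_note)) cat("\nframe: ", fit$frame_note, "\n", sep = "")
  invisible(x)
}

#' Extract consensus quantities from a fit
#'
#' @param object a `fragshare` fit.
#' @param type which quantity: mean group efficiency (`"ge"`), mean share
#'   (`"omega"`), or mean scaled contribution (`"e_scaled"`).
#' @param ... unused.
#' @return named numeric vector over fragments.
#' @export
coef.fragshare <- function(object, type = c("ge", "omega", "e_scaled"), ...) {
  type <- match.arg(type)
  tab <- object$consensus
  col <- switch(type, ge = "mean_ge", omega = "mean_omega",
                e_scaled = "mean_e_scaled")
  stats::setNames(tab[[col]], tab$fragment_id)
}

#' @export
as.data.frame.fragshare <- function(x, ...) {
  tab <- as.data.frame(unclass(x$consensus))
  tab
}

#' Bar plot of consensus group efficiencies
#'
#' @param x a `fragshare` fit.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.fragshare <- function(x, ...) {
  tab <- x$consensus
  mids <- graphics::barplot(tab$mean_ge, names.arg = tab$fragment_id,
                            ylab = "group efficiency (kcal/mol/atom)",
                            main = "Consensus group efficiency", ...)
  if (any(is.finite(tab$sd_ge)) && nrow(x$raw_scores) &&
      ncol(x$raw_scores) > 1) {
    graphics::arrows(mids, tab$mean_ge - tab$sd_ge, mids,
                     tab$mean_ge + tab$sd_ge,
                     angle = 90, code = 3, length = 0.05)
  }
  graphics::abline(h = x$threshold, lty = 2)
  invisible(mids)
}

#' Write analysis outputs to a directory
#'
#' Persists every intermediate needed to regenerate the report: the
#' consensus table (CSV), per-backend raw scores, shares, contributions and
#' GE (CSV), and a JSON report with all metadata (affinity source, backends,
#' parameter-set ids, flags).
#'
#' @param fit a `fragshare` fit.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fit), file.path(dir, "consensus.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(fragment_id = rownames(fit$raw_scores),
                              fit$raw_scores, check.names = FALSE),
                   file.path(dir, "raw_scores.csv"), row.names = FALSE)
  for (id in names(fit$per_backend)) {
    utils::write.csv(as.data.frame(unclass(fit$per_backend[[id]])),
                     file.path(dir, paste0("contributions_", id, ".csv")),
                     row.names = FALSE)
  }
  report <- list(
    affinity = unclass(fit$affinity),
    backends = colnames(fit$raw_scores),
    threshold = fit$threshold,
    anchor = fit$anchor,
    frame_note = fit$frame_note,
    optimization_focus = attr(fit$consensus, "optimization_focus"),
    anchor_violation = attr(fit$consensus, "anchor_violation"),
    consensus = as.data.frame(fit)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
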