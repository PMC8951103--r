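#' Per-fragment score set from one backend
#'
#' @param fragment_ids character vector.
#' @param scores numeric vector, parallel to `fragment_ids`.
#' @param backend_id producing backend.
#' @param units,favorable_direction as in [score_value()].
#' @return An object of class `fragment_score_set`.
#' @export
fragment_scores <- function(fragment_ids, scores, backend_id = "unknown",
                            units = c("kcal_per_mol", "pKd", "knowledge_based", "unitless"),
                            favorable_direction = c("negative_is_better", "positive_is_better")) {
  units <- match.arg(units)
  favorable_direction <- match.arg(favorable_direction)
  stopifnot(length(fragment_ids) == length(scores), length(scores) >= 1,
            all(is.finite(scores)))
  structure(list(entries = data.frame(fragment_id = as.character(fragment_ids),
                                      score = as.numeric(scores)),
                 backend_id = backend_id, units = units,
                 favorable_direction = favorable_direction),
            class = "fragment_score_set")
}

#' Stakeholder shares of per-fragment scores
#'
#' Forms the unitless share of each fragment as its score divided by the sum
#' over all fragments. Scores are first mapped so that the favorable
#' direction is positive (for negative-is-better kcal/mol scores this leaves
#' the resulting shares identical to the raw ratio). Shares are invariant
#' under any positive rescaling of all scores, which is why multiplicative
#' scoring-function errors cancel out of the partition. Shares sum to 1 by
#' construction and are unitless whatever the backend's units.
#'
#' A fragment scored in the unfavorable direction while others are favorable
#' makes raw shares fall outside `[0, 1]`; by default this is an error, and
#' with `mixed_sign_policy = "clip_to_zero"` such scores are set to 0 before
#' normalizing and the result is flagged.
#'
#' @param scores a [fragment_scores] set.
#' @param mixed_sign_policy `"error"` (default) or `"clip_to_zero"`.
#' @param near_zero_tol denominator guard: an absolute favorable-score sum
#'   below this (backend units) is an error.
#' @return An object of class `share_vector`: `entries` data.frame
#'   (`fragment_id`, `omega`), `flags` (logical `mixed_sign`,
#'   `near_zero_sum`, `clipped`), plus backend metadata.
#' @export
share_vector <- function(scores, mixed_sign_policy = c("error", "clip_to_zero"),
                         near_zero_tol = 1e-6) {
  mixed_sign_policy <- match.arg(mixed_sign_policy)
  stopifnot(inherits(scores, "fragment_score_set"))
  s <- scores$entries$score
  fav <- if (scores$favorable_direction == "negative_is_better") -s else s
  flags <- c(mixed_sign = FALSE, near_zero_sum = FALSE, clipped = FALSE)
  if (any(fav > 0) && any(fav < 0)) {
    flags[["mixed_sign"]] <- TRUE
    if (mixed_sign_policy == "error") {
      bad <- scores$entries$fragment_id[fav < 0]
      stop("mixed-sign fragment scores (unfavorable: ",
           paste(bad, collapse = ", "),
           "); shares would fall outside [0, 1]. Use mixed_sign_policy = ",
           "'clip_to_zero' to zero unfavorable fragments explicitly.")
    }
    fav[fav < 0] <- 0
    flags[["clipped"]] <- TRUE
  }
  denom <- sum(fav)
  if (abs(denom) < near_zero_tol) {
    stop("near-zero score sum (|sum| = ", format(abs(denom)),
         " < ", near_zero_tol, "); shares are ill-defined")
  }
  omega <- fav / denom
  structure(list(entries = data.frame(fragment_id = scores$entries$fragment_id,
                                      omega = omega),
                 flags = flags, backend_id = scores$backend_id,
                 units = scores$units),
            class = "share_vector")
}

#' @export
print.share_vector <- function(x, ...) {
  cat("<share_vector> backend ", x$backend_id, "\n", sep = "")
  print(x$entries, row.names = FALSE)
  on <- names(x$flags)[x$flags]
  if (length(on)) cat("  flags:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Molecular interaction energy to be partitioned
#'
#' The one quantity in the chain that carries kcal/mol: the whole-ligand
#' binding energy, either converted from an experimental measurement (see
#' [delta_g_from_measurement()]) or taken from an in silico score.
#'
#' @param delta_g numeric, kcal/mol, negative = favorable.
#' @param source one of `"experimental_kd"`, `"experimental_ki"`,
#'   `"experimental_ic50"`, `"scored"`.
#' @param note provenance free text (temperature used, backend, ...).
#' @return An object of class `binding_affinity`.
#' @export
binding_affinity <- function(delta_g,
                             source = c("scored", "experimental_kd",
                                        "experimental_ki", "experimental_ic50"),
                             note = "") {
  source <- match.arg(source)
  stopifnot(is.numeric(delta_g), length(delta_g) == 1, is.finite(delta_g))
  structure(list(delta_g = delta_g, source = source, note = note),
            class = "binding_affinity")
}

#' @export
print.binding_affinity <- function(x, ...) {
  cat(sprintf("<binding_affinity> %.3f kcal/mol (%s)\n", x$delta_g, x$source))
  if (nzchar(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Scale shares into additive energy contributions
#'
#' Multiplies each fragment's share by the molecular interaction energy,
#' giving per-fragment contributions that are additive by construction: they
#' sum back to the whole-ligand energy exactly.
#'
#' @param shares a [share_vector].
#' @param affinity a [binding_affinity].
#' @return A `contribution_table` data.frame with columns `fragment_id`,
#'   `omega`, `e_scaled` (kcal/mol); the affinity is attached as attribute
#'   `affinity`.
#' @export
scaled_contributions <- function(shares, affinity) {
  stopifnot(inherits(shares, "share_vector"),
            inherits(affinity, "binding_affinity"))
  out <- data.frame(fragment_id = shares$entries$fragment_id,
                    omega = shares$entries$omega,
                    e_scaled = shares$entries$omega * affinity$delta_g)
  attr(out, "affinity") <- affinity
  attr(out, "backend_id") <- shares$backend_id
  class(out) <- c("contribution_table", "data.frame")
  out
}
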