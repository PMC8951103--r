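#' Crystal reference for an anchor fragment
#'
#' Wraps the experimentally determined position of the anchor fragment (the
#' fragment whose placement grounds the optimization) together with the rule
#' for matching its atoms to pose atoms. Correspondence is explicit — no
#' symmetry detection — with atom-name matching as the default.
#'
#' @param molecule a [molecule] holding the reference fragment at crystal
#'   coordinates, in the receptor frame.
#' @param correspondence `"by_atom_name"`, `"by_serial"`, or a two-column
#'   matrix of explicit (reference serial, pose serial) pairs.
#' @return An object of class `anchor_reference`.
#' @export
anchor_reference <- function(molecule, correspondence = "by_atom_name") {
  stopifnot(inherits(molecule, "molecule"))
  if (n_heavy(molecule) < 3) {
    stop("anchor reference needs at least 3 heavy atoms")
  }
  structure(list(molecule = molecule, correspondence = correspondence),
            class = "anchor_reference")
}

#' Anchor-fragment RMSD of a pose, in the shared receptor frame
#'
#' Root-mean-square deviation over corresponded heavy atoms WITHOUT any
#' superposition: poses and reference live in the receptor's frame, and
#' fitting would defeat the positional criterion the RMSD is meant to test.
#'
#' @param pose a [molecule] (one docking pose of the whole ligand).
#' @param anchor_atom_serials serials of the pose atoms that form the anchor
#'   fragment.
#' @param ref an [anchor_reference].
#' @return RMSD in Angstrom.
#' @export
anchor_rmsd <- function(pose, anchor_atom_serials, ref) {
  stopifnot(inherits(ref, "anchor_reference"))
  ra <- ref$molecule$atoms[is_heavy(ref$molecule), , drop = FALSE]
  pa <- pose$atoms[pose$atoms$serial %in% anchor_atom_serials &
                     is_heavy(pose), , drop = FALSE]
  corr <- ref$correspondence
  if (is.matrix(corr) || is.data.frame(corr)) {
    corr <- as.matrix(corr)
    ri <- match(corr[, 1], ra$serial)
    pi_ <- match(corr[, 2], pa$serial)
    if (anyNA(ri) || anyNA(pi_)) {
      stop("explicit correspondence references missing atoms: ",
           paste(corr[is.na(ri) | is.na(pi_), ], collapse = ", "))
    }
  } else if (identical(corr, "by_atom_name")) {
    ri <- seq_len(nrow(ra))
    pi_ <- match(ra$name, pa$name)
    if (anyNA(pi_)) {
      stop("unmatched reference atom name(s): ",
           paste(ra$name[is.na(pi_)], collapse = ", "))
    }
  } else if (identical(corr, "by_serial")) {
    ri <- seq_len(nrow(ra))
    pi_ <- match(ra$serial, pa$serial)
    if (anyNA(pi_)) {
      stop("unmatched reference serial(s): ",
           paste(ra$serial[is.na(pi_)], collapse = ", "))
    }
  } else {
    stop("unknown correspondence spec")
  }
  if (length(ri) < 3) stop("fewer than 3 corresponded heavy atoms")
  P <- as.matrix(ra[ri, c("x", "y", "z")])
  Q <- as.matrix(pa[pi_, c("x", "y", "z")])
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Select the docking pose closest to the anchor's crystal position
#'
#' Docking ranks poses by score, but scores rank binding modes poorly; when
#' the anchor fragment's experimental position is known, the pose to analyze
#' is the one whose anchor lies closest to it in RMSD. Ties (RMSD within
#' 0.01 Angstrom) are broken by the better docking score.
#'
#' @param poses a `pose_set` from [read_poses()], or a list of
#'   `list(rank, molecule, score)`.
#' @param anchor_atom_serials serials of the anchor fragment's atoms in each
#'   pose.
#' @param ref an [anchor_reference].
#' @param rmsd_tie_tol tie width in Angstrom (default 0.01).
#' @return list with `rank` (chosen pose rank), `molecule`, and `table`
#'   (data.frame of rank, rmsd, score for the report).
#' @export
select_pose <- function(poses, anchor_atom_serials, ref, rmsd_tie_tol = 0.01) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  if (!length(plist)) stop("empty pose set")
  rmsd <- vapply(plist, function(p) anchor_rmsd(p$molecule, anchor_atom_serials, ref),
                 numeric(1))
  score <- vapply(plist, function(p) {
    if (is.null(p$score)) NA_real_ else p$score$value
  }, numeric(1))
  dir <- "negative_is_better"
  for (p in plist) if (!is.null(p$score)) { dir <- p$score$favorable_direction; break }
  tab <- data.frame(rank = vapply(plist, function(p) p$rank, numeric(1)),
                    rmsd = rmsd, score = score)
  cand <- which(rmsd - min(rmsd) < rmsd_tie_tol)
  if (length(cand) > 1 && !all(is.na(score[cand]))) {
    fav <- if (dir == "negative_is_better") score[cand] else -score[cand]
    fav[is.na(fav)] <- Inf
    cand <- cand[which.min(fav)]
  } else {
    cand <- cand[1]
  }
  list(rank = plist[[cand]]$rank, molecule = plist[[cand]]$molecule, table = tab)
}
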