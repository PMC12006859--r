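# Trajectory post-processing: superposition, RMSD, RMSF.

#' @noRd
as_sel3 <- function(selection, n_atoms) {
  if (is.null(selection)) selection <- seq_len(n_atoms)
  as.numeric(t(cbind(3 * selection - 2, 3 * selection - 1, 3 * selection)))
}

#' @noRd
check_selection <- function(ref, selection) {
  if (length(selection) < 3) stopf("superposition needs >= 3 selected atoms")
  m <- matrix(ref[as_sel3(selection, length(ref) / 3)], ncol = 3, byrow = TRUE)
  m <- sweep(m, 2, colMeans(m))
  if (qr(m)$rank < 2) stopf("selected atoms are collinear; superposition is ill-posed")
}

#' Rigid-body superposition of trajectory frames onto a reference
#'
#' Least-squares fits every frame onto the reference over the selected atoms
#' (rotation + translation), the standard preparation step before RMSF/RMSD.
#' By convention the reference is the first frame.
#'
#' @param frames [frame_set()].
#' @param reference numeric xyz vector (length `3*n_atoms`); default the
#'   first frame of `frames`.
#' @param selection integer atom indices used for the fit (e.g.
#'   [select_backbone()]); `NULL` = all atoms. Needs >= 3 non-collinear atoms.
#' @return [frame_set()] with fitted coordinates (all atoms moved).
#' @export
superpose <- function(frames, reference = NULL, selection = NULL) {
  if (is.null(reference)) reference <- frames$xyz[1, ]
  n_at <- ncol(frames$xyz) / 3
  if (length(reference) != ncol(frames$xyz)) stopf("reference/frames atom count mismatch")
  if (is.null(selection)) selection <- seq_len(n_at)
  check_selection(reference, selection)
  sel3 <- as_sel3(selection, n_at)
  fitted <- bio3d::fit.xyz(fixed = reference, mobile = frames$xyz,
                           fixed.inds = sel3, mobile.inds = sel3)
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1)
  out <- frames
  out$xyz <- fitted
  out
}

#' Per-frame RMSD against a reference
#'
#' @param frames [frame_set()] (already superposed, unless `fit = TRUE`).
#' @param reference numeric xyz vector; default first frame.
#' @param selection atom indices entering the RMSD (and the fit when
#'   `fit = TRUE`); `NULL` = all atoms.
#' @param fit re-fit each frame onto the reference before measuring.
#' @return numeric vector, Angstrom, one value per frame.
#' @export
rmsd_series <- function(frames, reference = NULL, selection = NULL, fit = FALSE) {
  if (is.null(reference)) reference <- frames$xyz[1, ]
  if (length(reference) != ncol(frames$xyz)) stopf("reference/frames atom count mismatch")
  n_at <- ncol(frames$xyz) / 3
  if (is.null(selection)) selection <- seq_len(n_at)
  sel3 <- as_sel3(selection, n_at)
  if (fit) {
    frames <- superpose(frames, reference, selection)
  }
  d2 <- sweep(frames$xyz[, sel3, drop = FALSE], 2, reference[sel3])^2
  unname(sqrt(rowSums(d2) / length(selection)))
}

#' Per-residue root-mean-square fluctuation
#'
#' For each selected atom, the RMS deviation from its time-average position;
#' atom values are then averaged within each residue. Backbone atoms
#' (N, CA, C, O) are the conventional selection. Frames must already be
#' superposed ([superpose()]), otherwise rigid drift inflates the result.
#'
#' @param frames [frame_set()], superposed.
#' @param model [structure_model()] mapping atoms to residues.
#' @param selection atom indices; default [select_backbone()].
#' @return data.frame `node`, `label`, `rmsf` (Angstrom), one row per residue
#'   with at least one selected atom.
#' @export
rmsf <- function(frames, model, selection = NULL) {
  if (is.null(selection)) selection <- select_backbone(model)
  if (!length(selection)) stopf("empty atom selection")
  if (n_frames(frames) < 2) {
    warning("single frame: RMSF is identically zero")
  }
  sel3 <- as_sel3(selection, ncol(frames$xyz) / 3)
  x <- frames$xyz[, sel3, drop = FALSE]
  dev2 <- sweep(x, 2, colMeans(x))^2
  percoord <- colMeans(dev2)
  peratom <- sqrt(percoord[seq(1, length(percoord), 3)] +
                  percoord[seq(2, length(percoord), 3)] +
                  percoord[seq(3, length(percoord), 3)])
  node <- model$atoms$node[selection]
  agg <- tapply(peratom, node, mean)
  ids <- as.integer(names(agg))
  data.frame(
    node = ids,
    label = model$nodes$label[match(ids, model$nodes$id)],
    rmsf = as.numeric(agg)
  )
}
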