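# Frame sets: trajectory coordinates for one replica of one ensemble.

#' Construct a frame set
#'
#' Coordinates of a trajectory replica, one frame per row in the bio3d xyz
#' convention (columns x1,y1,z1,x2,...).
#'
#' @param xyz numeric matrix, `n_frames x 3*n_atoms`.
#' @param label ensemble label.
#' @param replica_id integer replica index.
#' @param frame_interval_ps time between stored frames, picoseconds.
#' @return object of class `frame_set` with fields `xyz`, `label`,
#'   `replica_id`, `frame_interval_ps`.
#' @export
frame_set <- function(xyz, label = "ensemble", replica_id = 1L,
                      frame_interval_ps = 1) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) %% 3 != 0) stopf("xyz column count must be a multiple of 3")
  if (frame_interval_ps <= 0) stopf("frame_interval_ps must be positive")
  structure(list(xyz = xyz, label = label, replica_id = as.integer(replica_id),
                 frame_interval_ps = frame_interval_ps),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set '%s' replica %d: %d frames x %d atoms, %g ps/frame (%g us total)\n",
              x$label, x$replica_id, n_frames(x), ncol(x$xyz) / 3,
              x$frame_interval_ps, total_time_us(x)))
  invisible(x)
}

#' Number of frames in a frame set
#' @param frames [frame_set()].
#' @export
n_frames <- function(frames) nrow(frames$xyz)

#' Simulated time spanned by a frame set, in microseconds
#' @param frames [frame_set()].
#' @export
total_time_us <- function(frames) n_frames(frames) * frames$frame_interval_ps * 1e-6

#' Drop the equilibration part of a trajectory
#'
#' Keeps only the trailing portion spanning `keep_last_us`, i.e. the last
#' `floor(keep_last_us / frame_interval)` frames, mirroring the convention of
#' analyzing only the final stretch of each production run.
#'
#' @param frames [frame_set()].
#' @param keep_last_us time to retain, microseconds. Must not exceed the
#'   total simulated time.
#' @return [frame_set()] with the trailing frames.
#' @export
slice_equilibration <- function(frames, keep_last_us) {
  tot <- total_time_us(frames)
  if (keep_last_us > tot + 1e-12) {
    stopf("keep_last_us (%g) exceeds total simulated time (%g us)", keep_last_us, tot)
  }
  n_keep <- floor(keep_last_us * 1e6 / frames$frame_interval_ps + 1e-9)
  nf <- n_frames(frames)
  out <- frames
  out$xyz <- frames$xyz[seq.int(nf - n_keep + 1, length.out = n_keep), , drop = FALSE]
  out
}

#' Read a multi-model PDB as a frame set
#'
#' @param path multi-model PDB (MODEL/ENDMDL records).
#' @param ... passed to [frame_set()] (`label`, `replica_id`,
#'   `frame_interval_ps`).
#' @return [frame_set()].
#' @export
read_frames_pdb <- function(path, ...) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  frame_set(xyz, ...)
}

#' Write a frame set as a multi-model PDB
#'
#' @param frames [frame_set()].
#' @param model [structure_model()] supplying the atom records.
#' @param file output path.
#' @export
write_frames_pdb <- function(frames, model, file) {
  at <- model$atoms
  bio3d::write.pdb(
    file = file, xyz = frames$xyz,
    type = ifelse(at$is_polymer, "ATOM", "HETATM"),
    resno = at$resno, resid = at$resname, eleno = seq_len(nrow(at)),
    elety = at$atom_name, chain = at$chain, elesy = at$element
  )
  invisible(file)
}

#' Read / write the plain-text coordinate frame format
#'
#' A long CSV with columns `frame`, `atom`, `x`, `y`, `z` (Angstrom), frames
#' numbered from 1 in time order. A lighter-weight alternative to multi-model
#' PDB for synthetic ensembles.
#'
#' @param path CSV file.
#' @param ... passed to [frame_set()].
#' @return [frame_set()].
#' @export
read_frames_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  req <- c("frame", "atom", "x", "y", "z")
  if (!all(req %in% names(d))) stopf("frame CSV needs columns: %s", paste(req, collapse = ", "))
  d <- d[order(d$frame, d$atom), ]
  nf <- length(unique(d$frame))
  na <- length(unique(d$atom))
  if (nrow(d) != nf * na) stopf("frame CSV is ragged: %d rows != %d frames x %d atoms", nrow(d), nf, na)
  xyz <- matrix(0, nf, 3 * na)
  coords <- as.matrix(d[, c("x", "y", "z")])
  for (f in seq_len(nf)) {
    block <- coords[seq.int((f - 1) * na + 1, length.out = na), , drop = FALSE]
    xyz[f, ] <- as.numeric(t(block))
  }
  frame_set(xyz, ...)
}

#' @rdname read_frames_csv
#' @param frames [frame_set()] to serialize.
#' @export
write_frames_csv <- function(frames, path) {
  nf <- n_frames(frames)
  na <- ncol(frames$xyz) / 3
  d <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom = rep(seq_len(na), times = nf),
    x = as.numeric(t(frames$xyz[, seq(1, 3 * na, 3), drop = FALSE])),
    y = as.numeric(t(frames$xyz[, seq(2, 3 * na, 3), drop = FALSE])),
    z = as.numeric(t(frames$xyz[, seq(3, 3 * na, 3), drop = FALSE]))
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
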