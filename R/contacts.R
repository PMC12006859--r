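# Contact detection and per-ensemble contact probability estimation.
#
# A contact exists between two network nodes in a frame when ANY pair of
# their heavy atoms is within the cutoff (4.5 A by default, boundary
# inclusive). Polymer residues on the same chain must be separated by at
# least `min_sep` positions (i to i+n, n >= 3); pairs involving a ligand
# node are exempt from the separation rule.

#' Detect node-node contacts in a single frame
#'
#' @param coords numeric xyz vector (length `3*n_atoms`) or `n_atoms x 3`
#'   matrix, matching `model`.
#' @param model [structure_model()].
#' @param cutoff heavy-atom distance cutoff, Angstrom (inclusive).
#' @param min_sep minimum sequence separation for same-chain polymer pairs.
#' @param method `"grid"` (cell list, default) or `"brute"` (all atom pairs).
#'   Both give identical results; brute force is the reference path.
#' @return data.frame `node_i`, `node_j` (`node_i < node_j`), sorted.
#' @export
detect_contacts <- function(coords, model, cutoff = 4.5, min_sep = 3,
                            method = c("grid", "brute")) {
  method <- match.arg(method)
  if (is.matrix(coords)) coords <- as.numeric(t(coords))
  if (length(coords) != 3L * nrow(model$atoms)) stopf("coords length mismatch with model")
  heavy <- which(model$atoms$is_heavy)
  if (!length(heavy)) return(empty_pairs())
  xyz <- matrix(coords, ncol = 3, byrow = TRUE)[heavy, , drop = FALSE]
  node <- model$atoms$node[heavy]

  apairs <- if (method == "brute") {
    atom_pairs_brute(xyz, cutoff)
  } else {
    atom_pairs_grid(xyz, cutoff)
  }
  if (!nrow(apairs)) return(empty_pairs())

  ni <- node[apairs[, 1]]
  nj <- node[apairs[, 2]]
  keep <- ni != nj
  pd <- unique(canonical_pair_df(ni[keep], nj[keep]))
  filter_pair_rules(pd, model, min_sep)
}

#' @noRd
empty_pairs <- function() data.frame(node_i = integer(0), node_j = integer(0))

#' @noRd
filter_pair_rules <- function(pd, model, min_sep) {
  if (!nrow(pd)) return(empty_pairs())
  nodes <- model$nodes
  mi <- match(pd$node_i, nodes$id)
  mj <- match(pd$node_j, nodes$id)
  both_poly <- nodes$kind[mi] == "residue" & nodes$kind[mj] == "residue"
  same_chain <- nodes$chain[mi] == nodes$chain[mj]
  sep <- abs(nodes$seq[mi] - nodes$seq[mj])
  keep <- !(both_poly & same_chain) | sep >= min_sep
  pd <- pd[keep, , drop = FALSE]
  pd <- pd[order(pd$node_i, pd$node_j), , drop = FALSE]
  rownames(pd) <- NULL
  pd
}

#' All heavy-atom pairs within cutoff, O(n^2) reference scan
#' @noRd
atom_pairs_brute <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  unname(hit)
}

#' Cell-list neighbor search: atoms binned into cutoff-sized cells, only the
#' 27 neighboring cells are scanned per cell.
#' @noRd
atom_pairs_grid <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  members <- split(seq_len(n), key)
  cellpos <- do.call(rbind, lapply(strsplit(names(members), ","), as.numeric))
  out_i <- integer(0); out_j <- integer(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keymap <- stats::setNames(seq_along(members), names(members))
  for (c1 in seq_along(members)) {
    a <- members[[c1]]
    for (o in seq_len(nrow(offs))) {
      nb <- cellpos[c1, ] + offs[o, ]
      nbkey <- paste(nb[1], nb[2], nb[3], sep = ",")
      c2 <- keymap[nbkey]
      if (is.na(c2) || c2 < c1) next
      b <- members[[c2]]
      if (c2 == c1) {
        if (length(a) < 2) next
        cmb <- utils::combn(a, 2)
        ii <- cmb[1, ]; jj <- cmb[2, ]
      } else {
        g <- expand.grid(ii = a, jj = b)
        ii <- g$ii; jj <- g$jj
      }
      dd <- sqrt(rowSums((xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE])^2))
      sel <- dd <= cutoff
      out_i <- c(out_i, pmin(ii[sel], jj[sel]))
      out_j <- c(out_j, pmax(ii[sel], jj[sel]))
    }
  }
  unique(cbind(out_i, out_j))
}

# ---------------------------------------------------------------------------
# Contact probability tables

#' Construct a contact table
#'
#' Per-pair contact probabilities for one ensemble (or one replica). Pairs
#' absent from the table have probability 0 by convention.
#'
#' @param pairs data.frame `node_i`, `node_j`, `p_c`.
#' @param label ensemble label.
#' @param n_frames frames behind each probability (vector over replicas or
#'   scalar).
#' @param nodes integer vector: the node universe of this ensemble (nodes
#'   that exist in the system, contacted or not).
#' @param replicas optional matrix of per-replica p_c (rows = pairs in table
#'   order, cols = replicas).
#' @return data.frame of class `contact_table` with attributes `label`,
#'   `n_frames`, `nodes`, `replicas`.
#' @export
contact_table <- function(pairs, label, n_frames, nodes, replicas = NULL) {
  stopifnot(all(c("node_i", "node_j", "p_c") %in% names(pairs)))
  if (any(pairs$p_c < 0 | pairs$p_c > 1)) stopf("p_c outside [0,1]")
  if (any(pairs$node_i >= pairs$node_j)) stopf("pairs must be canonical (node_i < node_j)")
  pairs <- pairs[order(pairs$node_i, pairs$node_j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("contact_table", "data.frame"),
            label = label, n_frames = n_frames, nodes = nodes,
            replicas = replicas)
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact_table '%s': %d pairs, %s frames\n",
              attr(x, "label"), nrow(x),
              paste(attr(x, "n_frames"), collapse = "+")))
  NextMethod()
}

#' Estimate per-pair contact probability from trajectory frames
#'
#' p_c(pair) = number of frames containing the contact / number of frames.
#'
#' @param frames [frame_set()].
#' @param model [structure_model()].
#' @inheritParams detect_contacts
#' @return single-replica [contact_table()]; pairs never formed are absent
#'   (implicit 0).
#' @export
contact_probability <- function(frames, model, cutoff = 4.5, min_sep = 3,
                                method = "grid") {
  nf <- n_frames(frames)
  if (nf < 1) stopf("no frames")
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    pd <- detect_contacts(frames$xyz[f, ], model, cutoff, min_sep, method)
    if (!nrow(pd)) next
    keys <- pair_key(pd$node_i, pd$node_j)
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    tab <- data.frame(node_i = integer(0), node_j = integer(0), p_c = numeric(0))
  } else {
    ij <- do.call(rbind, strsplit(keys, "-"))
    tab <- data.frame(node_i = as.integer(ij[, 1]), node_j = as.integer(ij[, 2]),
                      p_c = vapply(keys, function(k) counts[[k]], 0L) / nf)
  }
  contact_table(tab, label = frames$label, n_frames = nf, nodes = model$nodes$id)
}

#' Average replica contact tables into one ensemble table
#'
#' Unweighted mean of per-replica probabilities; a pair missing from a
#' replica contributes 0 there.
#'
#' @param tables list of [contact_table()] for the same ensemble.
#' @return ensemble-level [contact_table()] carrying the per-replica matrix
#'   in attribute `"replicas"`.
#' @export
aggregate_replicas <- function(tables) {
  if (!length(tables)) stopf("no replica tables to aggregate")
  labs <- unique(vapply(tables, function(t) attr(t, "label"), ""))
  if (length(labs) > 1) stopf("replica tables belong to different ensembles: %s",
                              paste(labs, collapse = ", "))
  keys <- sort(unique(unlist(lapply(tables, function(t) pair_key(t$node_i, t$node_j)))))
  rep_mat <- matrix(0, length(keys), length(tables),
                    dimnames = list(keys, NULL))
  for (r in seq_along(tables)) {
    t <- tables[[r]]
    rep_mat[pair_key(t$node_i, t$node_j), r] <- t$p_c
  }
  ij <- do.call(rbind, strsplit(keys, "-"))
  tab <- data.frame(node_i = as.integer(ij[, 1]), node_j = as.integer(ij[, 2]),
                    p_c = rowMeans(rep_mat))
  ord <- order(tab$node_i, tab$node_j)
  nodes <- sort(unique(unlist(lapply(tables, attr, "nodes"))))
  contact_table(tab[ord, , drop = FALSE], label = labs, nodes = nodes,
                n_frames = vapply(tables, function(t) sum(attr(t, "n_frames")), 0),
                replicas = rep_mat[ord, , drop = FALSE])
}

#' Remove contacts too rare for meaningful comparison
#'
#' A pair is retained iff its probability reaches `floor` in at least one
#' ensemble; pairs below the floor everywhere are dropped from every table.
#' Contacts that are rare in all states carry no comparative signal, while a
#' contact rare in one state but common in another is exactly the object of
#' interest and is kept.
#'
#' @param tables named list of ensemble [contact_table()]s.
#' @param floor probability floor (default 0.10).
#' @return list of filtered tables; attribute `"retained"` holds the kept
#'   pair keys.
#' @export
filter_rare <- function(tables, floor = 0.10) {
  if (!length(tables)) stopf("no ensemble tables")
  allkeys <- sort(unique(unlist(lapply(tables, function(t) pair_key(t$node_i, t$node_j)))))
  mx <- stats::setNames(rep(0, length(allkeys)), allkeys)
  for (t in tables) {
    k <- pair_key(t$node_i, t$node_j)
    mx[k] <- pmax(mx[k], t$p_c)
  }
  keep <- names(mx)[mx >= floor]
  out <- lapply(tables, function(t) {
    sel <- pair_key(t$node_i, t$node_j) %in% keep
    rep_mat <- attr(t, "replicas")
    if (!is.null(rep_mat)) rep_mat <- rep_mat[sel, , drop = FALSE]
    contact_table(as.data.frame(t)[sel, , drop = FALSE], label = attr(t, "label"),
                  n_frames = attr(t, "n_frames"), nodes = attr(t, "nodes"),
                  replicas = rep_mat)
  })
  attr(out, "retained") <- keep
  out
}

#' Serialize / read contact tables
#'
#' Long CSV with columns `ensemble`, `node_i`, `node_j`, `p_c`.
#'
#' @param tables named list of [contact_table()]s.
#' @param path CSV file.
#' @export
write_contact_tables <- function(tables, path) {
  rows <- lapply(names(tables), function(lab) {
    t <- tables[[lab]]
    if (!nrow(t)) return(NULL)
    data.frame(ensemble = lab, node_i = t$node_i, node_j = t$node_j, p_c = t$p_c)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(ensemble = character(0), node_i = integer(0),
                                  node_j = integer(0), p_c = numeric(0))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contact_tables
#' @return `read_contact_tables`: named list of [contact_table()]s (node
#'   universe = nodes appearing in the file).
#' @export
read_contact_tables <- function(path) {
  d <- utils::read.csv(path)
  nodes <- sort(unique(c(d$node_i, d$node_j)))
  out <- lapply(split(d, d$ensemble), function(s) {
    contact_table(s[, c("node_i", "node_j", "p_c")], label = s$ensemble[1],
                  n_frames = NA_real_, nodes = nodes)
  })
  out[unique(d$ensemble)]
}

#' Contact probabilities from frame-major contact snapshots
#'
#' @param snapshots data.frame `frame`, `node_i`, `node_j`: one row per
#'   contact observed in a frame.
#' @param n_frames total number of frames (frames with no contacts carry no
#'   rows, so it cannot be inferred).
#' @param label,nodes as in [contact_table()].
#' @return single-replica [contact_table()].
#' @export
contact_table_from_snapshots <- function(snapshots, n_frames, label, nodes) {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  key <- pair_key(snapshots$node_i, snapshots$node_j)
  cnt <- table(key)
  ij <- do.call(rbind, strsplit(names(cnt), "-"))
  tab <- data.frame(node_i = as.integer(ij[, 1]), node_j = as.integer(ij[, 2]),
                    p_c = as.numeric(cnt) / n_frames)
  contact_table(tab, label = label, n_frames = n_frames, nodes = nodes)
}
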