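# Synthetic ensembles with known ground truth.
#
# The generator emulates the statistical structure the network analysis
# assumes: per-contact Bernoulli formation with ensemble-specific
# probabilities, block (community) structure in the high-probability contact
# graph, and a subset of "responder" contacts whose probability varies
# linearly with log-activity across ensembles, plus Gaussian noise.

#' Specification of a synthetic study
#'
#' Defaults reflect the study design the package targets: 8 modulator-bound
#' ensembles of 3 replicas each, activity constants spanning 2-34 uM,
#' 4 planted communities, and 1500 stored frames per replica (the analyzed
#' 1.5 us tail of a production run sampled every nanosecond).
#'
#' @param n_residues polymer length (>= 4).
#' @param n_communities number of planted contiguous residue blocks.
#' @param n_ensembles number of modulator-bound ensembles (>= 3).
#' @param n_replicas replicas per ensemble.
#' @param n_frames frames per replica.
#' @param p_within baseline contact probability inside a block.
#' @param p_between baseline contact probability between blocks
#'   (0 <= p_between < p_within <= 1).
#' @param n_responders number of planted activity-responsive contacts.
#' @param responder_slope slope(s) of p_c vs log10 K for responders
#'   (recycled; default alternating +/-0.1).
#' @param responder_intercept intercept of the responder linear model.
#' @param noise_sd sd of the Gaussian perturbation added to responder
#'   probabilities (probability scale).
#' @param clip range responder probabilities are clipped to; keeps every
#'   column away from the degenerate all/none limits so correlations stay
#'   finite.
#' @param activity_range (min, max) modulator K in uM, positive.
#' @param seed global seed; expanded deterministically into per-ensemble and
#'   per-replica child seeds.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 60, n_communities = 4, n_ensembles = 8,
                           n_replicas = 3, n_frames = 1500,
                           p_within = 0.95, p_between = 0.02,
                           n_responders = 5, responder_slope = c(-0.1, 0.1),
                           responder_intercept = 0.5, noise_sd = 0.02,
                           clip = c(0.02, 0.98), activity_range = c(2, 34),
                           seed = 1) {
  if (n_residues < 4) stopf("n_residues must be >= 4")
  if (n_communities < 1 || n_communities > n_residues) stopf("invalid n_communities")
  if (n_ensembles < 3) stopf("n_ensembles must be >= 3 (correlation needs 3 points)")
  if (n_replicas < 1 || n_frames < 1) stopf("counts must be >= 1")
  if (!(p_between >= 0 && p_between < p_within && p_within <= 1)) {
    stopf("need 0 <= p_between < p_within <= 1")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (any(activity_range <= 0)) stopf("activity bounds must be positive")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Planted community labels: contiguous near-equal blocks
#' @noRd
planted_labels <- function(n_residues, n_communities) {
  sizes <- rep(n_residues %/% n_communities, n_communities)
  extra <- n_residues %% n_communities
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(n_communities), sizes)
}

# within-block residue placements (octahedron + centre + outer shell)
block_offsets <- function(k) {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  pts <- rbind(3 * oct, c(0, 0, 0), 6.5 * oct)
  if (k > nrow(pts)) stopf("toy blocks support at most %d residues", nrow(pts))
  pts[seq_len(k), , drop = FALSE]
}

#' Generate a toy structure with planted spatial communities
#'
#' A linear pseudo-polymer whose residues are grouped into spatial blocks,
#' one per planted community, 30 Angstrom apart so blocks never touch.
#' Each residue carries six heavy atoms named N, CA, C, O, CB, CG placed at
#' +/-1.5 Angstrom along the axes; blocks of up to 7 residues are mutual
#' cliques under the 4.5 Angstrom heavy-atom contact criterion. Optionally
#' one ligand node (3 carbon atoms) is placed in a pocket adjacent to the
#' first block; as a non-polymer node it is exempt from the
#' sequence-separation rule.
#'
#' @param spec [synthetic_spec()].
#' @param ligand add a ligand node.
#' @return [structure_model()] with attribute `"community_labels"` (named
#'   integer vector over node ids).
#' @export
gen_toy_structure <- function(spec, ligand = FALSE) {
  labels <- planted_labels(spec$n_residues, spec$n_communities)
  anames <- c("N", "CA", "C", "O", "CB", "CG")
  aele <- c("N", "C", "C", "O", "C", "C")
  aoff <- 1.5 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  atoms <- list(); coords <- list()
  for (b in seq_len(spec$n_communities)) {
    res <- which(labels == b)
    pos <- block_offsets(length(res))
    centre <- c(30 * (b - 1), 0, 0)
    for (r in seq_along(res)) {
      atoms[[length(atoms) + 1]] <- data.frame(
        atom_name = anames, element = aele, resno = res[r],
        resname = "GLY", chain = "A", is_polymer = TRUE)
      coords[[length(coords) + 1]] <- sweep(aoff, 2, centre + pos[r, ], "+")
    }
  }
  if (ligand) {
    atoms[[length(atoms) + 1]] <- data.frame(
      atom_name = c("C1", "C2", "C3"), element = "C", resno = 1,
      resname = "LIG", chain = "B", is_polymer = FALSE)
    coords[[length(coords) + 1]] <- rbind(c(-1, 0, 5), c(0, 0, 5), c(1, 0, 5))
  }
  model <- structure_model(do.call(rbind, atoms), do.call(rbind, coords))
  lab <- labels
  if (ligand) lab <- c(lab, spec$n_communities + 1L)  # ligand = own community
  attr(model, "community_labels") <- stats::setNames(as.integer(lab), model$nodes$id)
  model
}

#' Generate a two-state coordinate ensemble
#'
#' Frames are the reference coordinates plus isotropic Gaussian jitter; in a
#' designated "open" fraction of frames one set of nodes is rigidly
#' translated, breaking whatever contacts bridged the moving and static
#' parts. Frame order is randomized by the seed; exactly
#' `round(open_fraction * n_frames)` frames are open, so detected contact
#' probabilities of broken pairs are deterministic given the fraction.
#'
#' @param model [structure_model()].
#' @param open_fraction fraction of frames in the open state, in [0, 1].
#' @param jitter_sd per-coordinate Gaussian noise, Angstrom (>= 0).
#' @param n_frames number of frames.
#' @param seed RNG seed (fixed seed => bitwise-identical frames).
#' @param moving node ids translated in open frames; default: the residues
#'   of the last planted community when the model carries labels.
#' @param translation displacement vector applied in open frames, Angstrom.
#' @param ... passed to [frame_set()].
#' @return [frame_set()].
#' @export
gen_coordinate_ensemble <- function(model, open_fraction, jitter_sd, n_frames,
                                    seed = 1, moving = NULL,
                                    translation = c(10, 0, 0), ...) {
  if (open_fraction < 0 || open_fraction > 1) stopf("open_fraction must be in [0,1]")
  if (jitter_sd < 0) stopf("jitter_sd must be >= 0")
  if (n_frames < 1) stopf("n_frames must be >= 1")
  if (is.null(moving)) {
    lab <- attr(model, "community_labels")
    if (!is.null(lab)) moving <- as.integer(names(lab)[lab == max(lab)])
  }
  mov_atoms <- which(model$atoms$node %in% moving)
  ref <- model$xyz
  n3 <- length(ref)
  n_open <- round(open_fraction * n_frames)
  with_seed(seed, {
    open <- seq_len(n_frames) %in% sample.int(n_frames, n_open)
    xyz <- matrix(rep(ref, each = n_frames), n_frames, n3)
    if (jitter_sd > 0) xyz <- xyz + stats::rnorm(n_frames * n3, 0, jitter_sd)
    if (n_open > 0 && length(mov_atoms)) {
      cols <- as_sel3(mov_atoms, n3 / 3)
      shift <- rep(translation, times = length(mov_atoms))
      xyz[open, cols] <- sweep(xyz[open, cols, drop = FALSE], 2, shift, "+")
    }
    frame_set(xyz, ...)
  })
}

#' Generate per-ensemble contact snapshot ensembles with ground truth
#'
#' The pair universe is every residue pair at sequence separation >= 3 (the
#' same rule contact detection applies). Baseline probabilities are
#' `p_within` inside a planted block and `p_between` across blocks.
#' Responder pairs (sampled among cross-block pairs) instead follow
#' `p = clip(intercept + slope * x_e + eps)` with `x_e = log10 K_e` of the
#' ensemble's modulator and `eps ~ N(0, noise_sd)` drawn once per ensemble
#' and pair. Snapshots are independent Bernoulli draws per frame and
#' replica; per-replica contact counts are drawn as the equivalent binomial
#' unless `snapshots = "frames"` materializes the frame-level matrix.
#'
#' A modulator-free reference ensemble (label `"apo"`) is included when
#' `include_reference` is TRUE; its responder probabilities sit at the
#' clipped intercept (the x = 0 extrapolation of the planted line).
#'
#' @param spec [synthetic_spec()].
#' @param snapshots `"counts"` (default) or `"frames"`.
#' @param include_reference add the modulator-free ensemble.
#' @return list with elements
#'   \describe{
#'     \item{tables}{named list of ensemble [contact_table()]s (replica
#'       means, per-replica matrix attached)}
#'     \item{activity}{`activity_table` for the modulator ensembles}
#'     \item{truth}{`ground_truth`: `community_labels`, `responder_pairs`
#'       (node_i, node_j, slope, intercept), `ensemble_log_activity`, `seed`}
#'     \item{frames}{when `snapshots = "frames"`: per ensemble, per replica
#'       logical frame x pair matrices}
#'   }
#' @export
gen_contact_ensembles <- function(spec, snapshots = c("counts", "frames"),
                                  include_reference = TRUE) {
  snapshots <- match.arg(snapshots)
  labels <- planted_labels(spec$n_residues, spec$n_communities)
  pairs <- pair_universe(spec$n_residues, min_sep = 3)
  same <- labels[pairs$node_i] == labels[pairs$node_j]
  base_p <- ifelse(same, spec$p_within, spec$p_between)

  activity <- gen_activity_table(spec$n_ensembles, range = spec$activity_range,
                                 seed = child_seed(spec$seed, 1))
  x <- transform_activity(activity, base = 10)

  cross <- which(!same)
  n_resp <- min(spec$n_responders, length(cross))
  resp_idx <- with_seed(child_seed(spec$seed, 2),
                        if (n_resp > 0) sort(sample(cross, n_resp)) else integer(0))
  slopes <- rep_len(spec$responder_slope, max(n_resp, 1))[seq_len(n_resp)]
  truth <- list(
    community_labels = stats::setNames(as.integer(labels), seq_len(spec$n_residues)),
    responder_pairs = data.frame(node_i = pairs$node_i[resp_idx],
                                 node_j = pairs$node_j[resp_idx],
                                 slope = slopes,
                                 intercept = rep(spec$responder_intercept, n_resp)),
    ensemble_log_activity = stats::setNames(as.numeric(x), activity$name),
    seed = spec$seed
  )
  class(truth) <- "ground_truth"

  ens_labels <- activity$name
  xs <- as.numeric(x)
  if (include_reference) {
    ens_labels <- c(ens_labels, "apo")
    xs <- c(xs, NA_real_)
  }
  tables <- list()
  frames_out <- if (snapshots == "frames") list() else NULL
  for (e in seq_along(ens_labels)) {
    p <- base_p
    if (n_resp > 0) {
      eff <- if (is.na(xs[e])) {
        spec$responder_intercept  # reference: planted line at x = 0
      } else {
        eps <- with_seed(child_seed(spec$seed, 3, e), stats::rnorm(n_resp, 0, spec$noise_sd))
        spec$responder_intercept + slopes * xs[e] + eps
      }
      p[resp_idx] <- pmin(pmax(eff, spec$clip[1]), spec$clip[2])
    }
    reps <- list()
    for (r in seq_len(spec$n_replicas)) {
      rs <- child_seed(spec$seed, 4, e, r)
      if (snapshots == "frames") {
        snap <- with_seed(rs, matrix(stats::runif(spec$n_frames * nrow(pairs)) < rep(p, each = spec$n_frames),
                                     spec$n_frames, nrow(pairs)))
        colnames(snap) <- pair_key(pairs$node_i, pairs$node_j)
        frames_out[[ens_labels[e]]][[r]] <- snap
        cnt <- colSums(snap)
      } else {
        cnt <- with_seed(rs, stats::rbinom(nrow(pairs), spec$n_frames, p))
      }
      formed <- cnt > 0
      reps[[r]] <- contact_table(
        data.frame(node_i = pairs$node_i[formed], node_j = pairs$node_j[formed],
                   p_c = cnt[formed] / spec$n_frames),
        label = ens_labels[e], n_frames = spec$n_frames,
        nodes = seq_len(spec$n_residues))
    }
    tables[[ens_labels[e]]] <- aggregate_replicas(reps)
  }
  out <- list(tables = tables, activity = activity, truth = truth)
  if (!is.null(frames_out)) out$frames <- frames_out
  out
}

#' All residue pairs at sequence separation >= min_sep
#' @noRd
pair_universe <- function(n_residues, min_sep = 3) {
  cmb <- utils::combn(n_residues, 2)
  keep <- cmb[2, ] - cmb[1, ] >= min_sep
  data.frame(node_i = cmb[1, keep], node_j = cmb[2, keep])
}

#' Write contact snapshots in the frame-major CSV format
#'
#' Columns `frame`, `node_i`, `node_j`: one row per contact present in a
#' frame (frames with no contacts contribute no rows).
#'
#' @param snap logical frame x pair matrix with "i-j" column names (one
#'   replica from `gen_contact_ensembles(..., snapshots = "frames")`).
#' @param path CSV file.
#' @export
write_contact_snapshots <- function(snap, path) {
  hit <- which(snap, arr.ind = TRUE)
  keys <- colnames(snap)[hit[, 2]]
  ij <- do.call(rbind, strsplit(keys, "-"))
  d <- data.frame(frame = hit[, 1],
                  node_i = as.integer(ij[, 1]), node_j = as.integer(ij[, 2]))
  d <- d[order(d$frame, d$node_i, d$node_j), ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#' @param truth `ground_truth` from [gen_contact_ensembles()].
#' @param path JSON file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(community_labels = as.list(truth$community_labels),
         responder_pairs = truth$responder_pairs,
         ensemble_log_activity = as.list(truth$ensemble_log_activity),
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
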