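# Consensus contact network and Girvan-Newman community detection.

#' Build the consensus contact network
#'
#' An edge joins two nodes iff the contact is highly probable in EVERY
#' ensemble (min over ensembles of p_c >= threshold, a pair missing from an
#' ensemble counting as 0). Edge weight is the mean p_c across ensembles.
#' The result is the stable scaffold shared by all states, on which residue
#' communities are defined.
#'
#' @param tables named list of ensemble [contact_table()]s (normally already
#'   passed through [filter_rare()]).
#' @param threshold consensus probability threshold (default 0.9).
#' @return object of class `consensus_network`: list with `graph` (igraph,
#'   vertex names = node ids), `edges` (data.frame `node_i`, `node_j`,
#'   `weight`), `nodes` (integer vector).
#' @export
build_consensus <- function(tables, threshold = 0.9) {
  if (!length(tables)) stopf("no ensemble tables")
  allkeys <- sort(unique(unlist(lapply(tables, function(t) pair_key(t$node_i, t$node_j)))))
  mn <- stats::setNames(rep(Inf, length(allkeys)), allkeys)
  sm <- stats::setNames(rep(0, length(allkeys)), allkeys)
  for (t in tables) {
    p <- stats::setNames(rep(0, length(allkeys)), allkeys)
    p[pair_key(t$node_i, t$node_j)] <- t$p_c
    mn <- pmin(mn, p)
    sm <- sm + p
  }
  keep <- allkeys[mn >= threshold]
  nodes <- sort(unique(unlist(lapply(tables, attr, "nodes"))))
  if (!length(keep)) {
    warning("consensus network has no edges at threshold ", threshold)
    edges <- data.frame(node_i = integer(0), node_j = integer(0), weight = numeric(0))
  } else {
    ij <- do.call(rbind, strsplit(keep, "-"))
    edges <- data.frame(node_i = as.integer(ij[, 1]), node_j = as.integer(ij[, 2]),
                        weight = as.numeric(sm[keep]) / length(tables))
    edges <- edges[order(edges$node_i, edges$node_j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$node_i), to = as.character(edges$node_j),
               weight = edges$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes))
  )
  structure(list(graph = g, edges = edges, nodes = nodes),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @noRd
as_dcna_graph <- function(network) {
  if (inherits(network, "consensus_network")) network$graph
  else if (igraph::is_igraph(network)) network
  else stopf("expected a consensus_network or igraph object")
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over communities of (e_ii - a_i^2), where e_ii is the fraction of
#' edges falling inside community i and a_i the fraction of edge ends
#' attached to it. Unweighted by default; with `weighted = TRUE` edge weights
#' replace edge counts.
#'
#' @param network [build_consensus()] result or igraph graph.
#' @param membership named vector (names = node ids) assigning every node a
#'   community.
#' @param weighted use edge weights.
#' @return numeric Q in [-0.5, 1].
#' @export
modularity_q <- function(network, membership, weighted = FALSE) {
  g <- as_dcna_graph(network)
  vnames <- igraph::V(g)$name
  miss <- setdiff(vnames, names(membership))
  if (length(miss)) stopf("membership missing node(s): %s", paste(miss, collapse = ", "))
  if (igraph::ecount(g) == 0) return(0)
  ends <- igraph::ends(g, igraph::E(g))
  w <- if (weighted) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  W <- sum(w)
  ci <- membership[ends[, 1]]
  cj <- membership[ends[, 2]]
  comms <- unique(membership[vnames])
  q <- 0
  for (cc in comms) {
    e_in <- sum(w[ci == cc & cj == cc]) / W
    ends_in <- (sum(w[ci == cc]) + sum(w[cj == cc])) / (2 * W)
    q <- q + e_in - ends_in^2
  }
  q
}

#' @noRd
components_membership <- function(g) {
  comp <- igraph::components(g)
  m <- comp$membership
  stats::setNames(as.integer(m), igraph::V(g)$name)
}

#' Girvan-Newman edge-removal partition series
#'
#' Iteratively removes the edge of highest betweenness (recomputed after
#' every removal). Each time the number of connected components increases,
#' the component partition is recorded together with its modularity on the
#' ORIGINAL network. Ties in betweenness are broken deterministically toward
#' the lexicographically smallest (node_i, node_j) pair. Disconnected input
#' is processed jointly and its component partition is the first entry; for
#' connected input the series starts at the first split (the undivided
#' network is not a candidate partition, so community detection always
#' divides it).
#'
#' @param network [build_consensus()] result or igraph graph with >= 1 edge.
#' @param weighted_q compute the recorded Q values from edge weights.
#' @return list of class `gn_series`; each element has `membership` (named,
#'   community ids contiguous from 1), `n_communities`, `q`, `edges_removed`.
#' @export
girvan_newman <- function(network, weighted_q = FALSE) {
  g0 <- as_dcna_graph(network)
  if (igraph::ecount(g0) < 1) stopf("Girvan-Newman needs a network with at least one edge")
  g <- g0
  series <- list()
  record <- function(g, removed) {
    m <- relabel_membership(components_membership(g))
    list(membership = m,
         n_communities = max(m),
         q = modularity_q(g0, m, weighted = weighted_q),
         edges_removed = removed)
  }
  ncomp <- igraph::components(g)$no
  if (ncomp > 1) series[[1]] <- record(g, 0L)
  removed <- 0L
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NULL)
    ends <- igraph::ends(g, igraph::E(g))
    ei <- suppressWarnings(as.integer(ends[, 1]))
    ej <- suppressWarnings(as.integer(ends[, 2]))
    if (anyNA(ei) || anyNA(ej)) {   # non-numeric node names: string order
      a <- pmin(ends[, 1], ends[, 2])
      b <- pmax(ends[, 1], ends[, 2])
    } else {
      a <- pmin(ei, ej)
      b <- pmax(ei, ej)
    }
    mx <- max(eb)
    tie <- which(eb >= mx - 1e-9 * max(1, mx))
    pick <- tie[order(a[tie], b[tie])][1]
    g <- igraph::delete_edges(g, pick)
    removed <- removed + 1L
    ncomp_new <- igraph::components(g)$no
    if (ncomp_new > ncomp) {
      series[[length(series) + 1]] <- record(g, removed)
      ncomp <- ncomp_new
    }
  }
  structure(series, class = "gn_series")
}

#' Relabel community ids contiguously from 1 in order of first appearance
#' @noRd
relabel_membership <- function(m) {
  u <- unique(as.integer(m))
  stats::setNames(match(as.integer(m), u), names(m))
}

#' @export
print.gn_series <- function(x, ...) {
  cat("Girvan-Newman partition series:\n")
  for (s in x) {
    cat(sprintf("  %3d communities after %4d removals, Q = %.4f\n",
                s$n_communities, s$edges_removed, s$q))
  }
  invisible(x)
}

#' Select the maximum-modularity partition from a series
#'
#' Ties in Q are broken toward fewer communities (then toward the earlier
#' entry).
#'
#' @param series [girvan_newman()] output.
#' @return object of class `community_partition`: list with `membership`
#'   (named integer vector, ids contiguous from 1), `n_communities`, `q`,
#'   and the full `series`.
#' @export
select_partition <- function(series) {
  if (!length(series)) stopf("empty partition series")
  qs <- vapply(series, `[[`, 0, "q")
  ks <- vapply(series, `[[`, 0, "n_communities")
  best_q <- max(qs)
  cand <- which(qs >= best_q - 1e-12)
  best <- cand[order(ks[cand])][1]
  s <- series[[best]]
  structure(list(membership = s$membership, n_communities = s$n_communities,
                 q = s$q, series = series),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities over %d nodes, Q = %.4f\n",
              x$n_communities, length(x$membership), x$q))
  invisible(x)
}

#' Detect communities on a consensus network
#'
#' Convenience wrapper: [girvan_newman()] followed by [select_partition()].
#'
#' @inheritParams girvan_newman
#' @return [select_partition()] result.
#' @export
detect_communities <- function(network, weighted_q = FALSE) {
  select_partition(girvan_newman(network, weighted_q = weighted_q))
}

# ---------------------------------------------------------------------------
# Exports

#' Write a consensus network as GraphML
#' @param network [build_consensus()] result.
#' @param file output path.
#' @export
write_consensus_graphml <- function(network, file) {
  igraph::write_graph(network$graph, file, format = "graphml")
  invisible(file)
}

#' Write a consensus network as a 3-column edge list
#' @param network [build_consensus()] result.
#' @param file output path (CSV: node_i, node_j, weight).
#' @export
write_edge_list <- function(network, file) {
  utils::write.csv(network$edges, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a community partition as CSV (node, community)
#' @param partition [select_partition()] result or named membership vector.
#' @param file output path.
#' @export
write_partition_csv <- function(partition, file) {
  m <- if (inherits(partition, "community_partition")) partition$membership else partition
  d <- data.frame(node = names(m), community = as.integer(m))
  d <- d[order(suppressWarnings(as.integer(d$node)), d$node), ]
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a PDB with community ids in the B-factor column
#'
#' @param model [structure_model()].
#' @param partition [select_partition()] result or named membership vector.
#' @param file output path.
#' @export
write_community_pdb <- function(model, partition, file) {
  m <- if (inherits(partition, "community_partition")) partition$membership else partition
  write_structure_pdb(model, file, node_values = stats::setNames(as.numeric(m), names(m)))
}
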