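# Difference contact network analysis (dCNA): community-level net contact
# probability changes between a perturbed (bound) and a reference (free)
# ensemble.

#' Community-level contact probability differences
#'
#' For every unordered community pair (A, B), including A = B,
#' Delta f(A,B) = sum over node pairs (i in A, j in B, i < j) of
#' p_c^bound(i,j) - p_c^free(i,j). A pair absent from a table contributes 0
#' for that table. Node pairs involving a node that exists in only one
#' ensemble's node universe (typically the modulator itself, absent from the
#' free system) are excluded from Delta f and reported separately as binding
#' contacts, so binding-site occupancy is not conflated with allosteric
#' change.
#'
#' @param table_bound,table_free [contact_table()]s filtered by the same
#'   rare-contact rule.
#' @param partition [select_partition()] result or named membership vector
#'   covering every node appearing in either table.
#' @return object of class `difference_network`: data.frame `community_a`,
#'   `community_b` (a <= b), `delta_f`, `n_pairs`, with attributes
#'   `contributions` (per node pair), `binding_contacts`, `labels`
#'   (bound/free ensemble labels).
#' @export
community_delta <- function(table_bound, table_free, partition) {
  m <- if (inherits(partition, "community_partition")) partition$membership else partition
  keys_b <- pair_key(table_bound$node_i, table_bound$node_j)
  keys_f <- pair_key(table_free$node_i, table_free$node_j)
  keys <- sort(unique(c(keys_b, keys_f)))
  pb <- stats::setNames(rep(0, length(keys)), keys)
  pf <- pb
  pb[keys_b] <- table_bound$p_c
  pf[keys_f] <- table_free$p_c
  ij <- do.call(rbind, strsplit(keys, "-"))
  ni <- as.integer(ij[, 1]); nj <- as.integer(ij[, 2])

  nodes_b <- attr(table_bound, "nodes")
  nodes_f <- attr(table_free, "nodes")
  shared_ok <- if (is.null(nodes_b) || is.null(nodes_f)) {
    rep(TRUE, length(ni))
  } else {
    shared <- intersect(nodes_b, nodes_f)
    ni %in% shared & nj %in% shared
  }

  need <- unique(c(ni, nj))
  missing_nodes <- setdiff(as.character(need), names(m))
  if (length(missing_nodes)) {
    stopf("node(s) without community assignment: %s", paste(missing_nodes, collapse = ", "))
  }
  ci <- as.integer(m[as.character(ni)])
  cj <- as.integer(m[as.character(nj)])
  d <- pb - pf
  contrib <- data.frame(node_i = ni, node_j = nj,
                        community_a = pmin(ci, cj), community_b = pmax(ci, cj),
                        p_bound = as.numeric(pb), p_free = as.numeric(pf),
                        delta = as.numeric(d))
  binding <- contrib[!shared_ok, , drop = FALSE]
  contrib <- contrib[shared_ok, , drop = FALSE]

  # all community pairs (including within-community) over assigned communities
  comms <- sort(unique(as.integer(m)))
  grid <- expand.grid(community_a = comms, community_b = comms)
  grid <- grid[grid$community_a <= grid$community_b, ]
  ckey_all <- paste(grid$community_a, grid$community_b)
  ckey <- paste(contrib$community_a, contrib$community_b)
  df <- data.frame(
    community_a = grid$community_a,
    community_b = grid$community_b,
    delta_f = vapply(ckey_all, function(k) sum(contrib$delta[ckey == k]), 0),
    n_pairs = vapply(ckey_all, function(k) sum(ckey == k), 0L)
  )
  df <- df[order(df$community_a, df$community_b), ]
  rownames(df) <- NULL
  structure(df, class = c("difference_network", "data.frame"),
            contributions = contrib[order(contrib$node_i, contrib$node_j), ],
            binding_contacts = binding,
            labels = c(bound = attr(table_bound, "label"),
                       free = attr(table_free, "label")))
}

#' Flag significant community-level changes
#'
#' Labels each community pair `"enhanced"` (Delta f >= threshold),
#' `"reduced"` (Delta f <= -threshold, boundary inclusive) or `"neutral"`.
#'
#' @param network [community_delta()] result.
#' @param threshold significance threshold on |Delta f| (default 0.1).
#' @return the network with added columns `label` and `significant`.
#' @export
classify_deltas <- function(network, threshold = 0.1) {
  lab <- ifelse(network$delta_f >= threshold, "enhanced",
                ifelse(network$delta_f <= -threshold, "reduced", "neutral"))
  network$label <- lab
  network$significant <- lab != "neutral"
  network
}

#' Residue pairs driving a community-pair change
#'
#' Node pairs between two communities ranked by |p_bound - p_free|,
#' descending; ties broken by (node_i, node_j).
#'
#' @param network [community_delta()] result.
#' @param community_a,community_b community ids.
#' @param k number of pairs to return (all pairs if larger than available).
#' @return data.frame of the top contributions.
#' @export
top_changing_pairs <- function(network, community_a, community_b, k = 3) {
  if (k < 1) stopf("k must be >= 1")
  contrib <- attr(network, "contributions")
  a <- min(community_a, community_b); b <- max(community_a, community_b)
  known <- unique(c(network$community_a, network$community_b))
  if (!(a %in% known) || !(b %in% known)) {
    stopf("unknown community pair (%s, %s)", community_a, community_b)
  }
  s <- contrib[contrib$community_a == a & contrib$community_b == b, , drop = FALSE]
  s <- s[order(-abs(s$delta), s$node_i, s$node_j), , drop = FALSE]
  utils::head(s, k)
}

#' Write a difference network to CSV
#' @param network [community_delta()] (optionally [classify_deltas()]) result.
#' @param file output path.
#' @export
write_difference_csv <- function(network, file) {
  utils::write.csv(as.data.frame(network), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a difference network (with per-pair contributions) to JSON
#' @param network [community_delta()] result.
#' @param file output path.
#' @export
write_difference_json <- function(network, file) {
  jsonlite::write_json(
    list(labels = as.list(attr(network, "labels")),
         communities = as.data.frame(network),
         contributions = attr(network, "contributions"),
         binding_contacts = attr(network, "binding_contacts")),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
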