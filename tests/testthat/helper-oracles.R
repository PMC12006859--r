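# Independent oracles and small fixture builders used across the suite.

# --- closed-form quaternion superposition (Horn 1987) -----------------------
# Minimum RMSD of point set B fitted onto A over all rotations/translations,
# via the largest eigenvalue of the 4x4 quaternion matrix. Independent of the
# package's superposition path.
quaternion_rmsd_oracle <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- t(Bc) %*% Ac
  N <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2], M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3], M[1, 2] + M[2, 1], M[3, 1] + M[1, 3],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1], -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[3, 1] + M[1, 3], M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]
  ), 4, 4, byrow = TRUE)
  lmax <- max(eigen(N, symmetric = TRUE)$values)
  sqrt(max(sum(Ac^2) + sum(Bc^2) - 2 * lmax, 0) / nrow(A))
}

# --- degree-formula modularity ----------------------------------------------
# Q = sum_c [ L_c/m - (d_c / 2m)^2 ] from within-community edge counts and
# community degree sums; a different route than the package's edge-end sums.
modularity_oracle <- function(edges, membership) {
  m <- nrow(edges)
  ci <- membership[as.character(edges[[1]])]
  cj <- membership[as.character(edges[[2]])]
  deg <- table(c(as.character(edges[[1]]), as.character(edges[[2]])))
  q <- 0
  for (cc in unique(membership)) {
    lc <- sum(ci == cc & cj == cc)
    dc <- sum(deg[names(membership)[membership == cc]], na.rm = TRUE)
    q <- q + lc / m - (dc / (2 * m))^2
  }
  q
}

# --- edge betweenness by explicit shortest-path enumeration ------------------
# Enumerates all shortest s-t paths (tiny graphs only) and splits one unit of
# flow per unordered (s,t) pair equally among them.
betweenness_oracle <- function(edges, nodes) {
  adj <- lapply(nodes, function(v) {
    c(edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v])
  })
  names(adj) <- nodes
  all_paths <- function(s, t) {
    best <- Inf; found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (length(path) - 1 > best) return()
      if (v == t) {
        if (length(path) - 1 < best) { best <<- length(path) - 1; found <<- list() }
        if (length(path) - 1 == best) found[[length(found) + 1]] <<- path
        return()
      }
      for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    found
  }
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  score <- setNames(rep(0, nrow(edges)), ekey(edges[[1]], edges[[2]]))
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- all_paths(nodes[i], nodes[j])
    if (!length(paths)) next
    for (p in paths) {
      for (k in seq_len(length(p) - 1)) {
        score[ekey(p[k], p[k + 1])] <- score[ekey(p[k], p[k + 1])] + 1 / length(paths)
      }
    }
  }
  score
}

# --- Pearson correlation from the covariance formula -------------------------
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# --- planted-partition Bernoulli graph ---------------------------------------
# Blocks of given sizes; each within-block pair is an edge with prob p_in,
# each cross-block pair with prob p_out. Returns list(graph, labels).
gen_planted_graph <- function(sizes, p_in, p_out, seed) {
  n <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  set.seed(seed)
  cmb <- utils::combn(n, 2)
  p <- ifelse(labels[cmb[1, ]] == labels[cmb[2, ]], p_in, p_out)
  on <- stats::runif(ncol(cmb)) < p
  edges <- data.frame(from = as.character(cmb[1, on]), to = as.character(cmb[2, on]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = as.character(1:n)))
  list(graph = g, labels = setNames(labels, as.character(1:n)))
}

# --- quick contact-table builder ---------------------------------------------
# make_table(list(c(1, 4, 0.9), c(2, 5, 0.4)), "bound")
make_table <- function(pairs, label, nodes = NULL, n_frames = 100) {
  d <- as.data.frame(do.call(rbind, pairs))
  names(d) <- c("node_i", "node_j", "p_c")
  if (is.null(nodes)) nodes <- sort(unique(c(d$node_i, d$node_j)))
  contact_table(d, label = label, n_frames = n_frames, nodes = nodes)
}

# --- random toy structure with arbitrary coordinates -------------------------
random_toy_model <- function(n_residues, atoms_per_res = 3, box = 15, seed = 1) {
  set.seed(seed)
  n_at <- n_residues * atoms_per_res
  atoms <- data.frame(
    atom_name = rep(paste0("C", seq_len(atoms_per_res)), n_residues),
    element = "C",
    resno = rep(seq_len(n_residues), each = atoms_per_res),
    resname = "GLY", chain = "A", is_polymer = TRUE
  )
  structure_model(atoms, matrix(runif(3 * n_at, 0, box), n_at, 3))
}

# single-atom-per-residue model at given residue positions
point_model <- function(positions, resno = seq_len(nrow(positions))) {
  atoms <- data.frame(atom_name = "CA", element = "C", resno = resno,
                      resname = "GLY", chain = "A", is_polymer = TRUE)
  structure_model(atoms, positions)
}
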