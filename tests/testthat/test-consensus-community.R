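# Consensus network construction and Girvan-Newman community detection.

test_that("consensus edges require the threshold in every ensemble; weight is the mean", {
  t1 <- make_table(list(c(1, 4, 0.95), c(2, 5, 0.95)), "e1", nodes = 1:6)
  t2 <- make_table(list(c(1, 4, 0.93), c(2, 5, 0.85)), "e2", nodes = 1:6)
  t3 <- make_table(list(c(1, 4, 0.91), c(2, 5, 0.99)), "e3", nodes = 1:6)
  net <- build_consensus(list(e1 = t1, e2 = t2, e3 = t3), threshold = 0.9)
  expect_equal(nrow(net$edges), 1)                     # (2,5) fails in e2
  expect_equal(net$edges$node_i, 1L)
  expect_equal(net$edges$weight, 0.93)
  expect_equal(length(net$nodes), 6)                   # isolated nodes kept

  # threshold 0 reproduces the retained pair set
  net0 <- build_consensus(list(e1 = t1, e2 = t2), threshold = 0)
  expect_equal(nrow(net0$edges), 2)
  expect_warning(build_consensus(list(e1 = t1), threshold = 0.99), "no edges")
})

test_that("raising the consensus threshold never adds edges", {
  spec <- synthetic_spec(n_residues = 16, n_communities = 2, n_ensembles = 4,
                         n_replicas = 1, n_frames = 200, seed = 31)
  gen <- gen_contact_ensembles(spec)
  tabs <- filter_rare(gen$tables)
  prev <- Inf
  for (th in c(0.5, 0.7, 0.9, 0.95)) {
    suppressWarnings(n_e <- nrow(build_consensus(tabs, threshold = th)$edges))
    expect_lte(n_e, prev)
    prev <- n_e
  }
})

two_triangle_bridge <- function() {
  edges <- data.frame(from = c("1", "1", "2", "4", "4", "5", "3"),
                      to   = c("2", "3", "3", "5", "6", "6", "4"))
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

test_that("the bridge between two triangles is removed first (betweenness oracle)", {
  g <- two_triangle_bridge()
  edges <- igraph::as_data_frame(g)
  oracle <- betweenness_oracle(edges, as.character(1:6))
  expect_equal(names(which.max(oracle)), "3 4")        # the bridge dominates
  expect_equal(unname(oracle["3 4"]), 9)               # 3x3 cross pairs each use it

  series <- girvan_newman(g)
  two <- series[[1]]                                   # connected input: series starts at first split
  expect_equal(two$edges_removed, 1)                   # first removal splits
  expect_equal(two$n_communities, 2)
  expect_equal(unname(two$membership[c("1", "2", "3")]), rep(1L, 3))
  expect_equal(unname(two$membership[c("4", "5", "6")]), rep(2L, 3))
})

test_that("a single triangle decays to singletons with non-decreasing communities", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("1", "1", "2"), to = c("2", "3", "3")), directed = FALSE)
  series <- girvan_newman(g)
  ks <- vapply(series, `[[`, 0, "n_communities")
  expect_equal(ks[1], 2)                               # first split of the triangle
  expect_equal(ks[length(ks)], 3)                      # ends at singletons
  expect_true(all(diff(ks) >= 0))
})

test_that("modularity matches hand values, the degree-formula oracle and igraph", {
  # two disconnected triangles, partitioned as the triangles: Q = 0.5
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("1", "1", "2", "4", "4", "5"),
               to   = c("2", "3", "3", "5", "6", "6")), directed = FALSE)
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), as.character(1:6))
  expect_equal(modularity_q(g2, memb), 0.5)
  # brute force over all 2^6 labelings confirms 0.5 is the maximum
  best <- max(vapply(0:63, function(code) {
    m <- setNames(as.integer(intToBits(code)[1:6]) + 1L, as.character(1:6))
    modularity_q(g2, m)
  }, 0))
  expect_equal(best, 0.5)

  expect_equal(modularity_q(g2, setNames(rep(1L, 6), as.character(1:6))), 0)

  # random graphs: package Q == degree-formula oracle == igraph, to 1e-12
  for (s in 1:10) {
    pg <- gen_planted_graph(c(5, 5, 5), 0.8, 0.2, seed = s)
    set.seed(s)
    memb <- setNames(sample(1:3, 15, replace = TRUE), as.character(1:15))
    edges <- igraph::as_data_frame(pg$graph)
    q <- modularity_q(pg$graph, memb)
    expect_equal(q, modularity_oracle(edges, memb), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(pg$graph, memb[igraph::V(pg$graph)$name]),
                 tolerance = 1e-12)
  }
})

test_that("maximum-modularity selection finds the planted split", {
  # barbell of two 5-cliques: best partition is the two cliques
  cl <- utils::combn(5, 2)
  edges <- data.frame(from = as.character(c(cl[1, ], cl[1, ] + 5, 5)),
                      to   = as.character(c(cl[2, ], cl[2, ] + 5, 6)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = as.character(1:10)))
  # exhaustive search over all 2-partitions for the best Q
  codes <- 0:(2^10 - 1)
  qs <- vapply(codes, function(code) {
    m <- setNames(as.integer(intToBits(code)[1:10]) + 1L, as.character(1:10))
    modularity_q(g, m)
  }, 0)
  bestm <- setNames(as.integer(intToBits(codes[which.max(qs)])[1:10]) + 1L,
                    as.character(1:10))
  expect_equal(adjusted_rand_index(bestm, rep(1:2, each = 5)), 1)

  part <- detect_communities(g)
  expect_equal(part$n_communities, 2)
  expect_equal(adjusted_rand_index(part$membership[as.character(1:10)],
                                   rep(1:2, each = 5)), 1)
  expect_equal(part$q, max(qs), tolerance = 1e-12)
})

test_that("partition selection breaks Q ties toward fewer communities", {
  series <- list(
    list(membership = setNames(1L, "1"), n_communities = 1, q = 0, edges_removed = 0),
    list(membership = setNames(c(1L, 2L), c("1", "2")), n_communities = 2, q = 0.45, edges_removed = 1),
    list(membership = setNames(c(1L, 2L, 3L), c("1", "2", "3")), n_communities = 3, q = 0.45, edges_removed = 2)
  )
  class(series) <- "gn_series"
  expect_equal(select_partition(series)$n_communities, 2)
  expect_error(select_partition(list()), "empty")
})

test_that("a single-edge network splits into two singletons", {
  g <- igraph::graph_from_data_frame(data.frame(from = "1", to = "2"), directed = FALSE)
  part <- detect_communities(g)
  expect_equal(part$n_communities, 2)
  expect_true(all(table(part$membership) == 1))
})

test_that("planted two-block consensus networks are recovered exactly", {
  spec <- synthetic_spec(n_residues = 20, n_communities = 2, n_ensembles = 4,
                         n_replicas = 2, n_frames = 400, p_within = 0.95,
                         p_between = 0.02, n_responders = 0, seed = 17)
  gen <- gen_contact_ensembles(spec)
  tabs <- filter_rare(gen$tables)
  net <- build_consensus(tabs, threshold = 0.9)
  # consensus edges are exactly the within-block eligible pairs (w.h.p.)
  lab <- gen$truth$community_labels
  expect_true(all(lab[as.character(net$edges$node_i)] ==
                  lab[as.character(net$edges$node_j)]))
  part <- detect_communities(net)
  expect_equal(adjusted_rand_index(part$membership[names(lab)], lab), 1)
  # and the package ARI agrees with mclust on the same pair of labelings
  expect_equal(adjusted_rand_index(part$membership[names(lab)], lab),
               mclust::adjustedRandIndex(part$membership[names(lab)], lab))
})

test_that("partition and network exports are written and readable", {
  t1 <- make_table(list(c(1, 4, 0.95), c(2, 5, 0.92)), "e1", nodes = 1:6)
  net <- build_consensus(list(e1 = t1), threshold = 0.9)
  part <- detect_communities(net)
  d <- withr::local_tempdir()
  write_edge_list(net, file.path(d, "edges.csv"))
  write_consensus_graphml(net, file.path(d, "net.graphml"))
  write_partition_csv(part, file.path(d, "part.csv"))
  expect_equal(nrow(utils::read.csv(file.path(d, "edges.csv"))), 2)
  expect_equal(nrow(utils::read.csv(file.path(d, "part.csv"))), 6)
  g2 <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g2), 2)

  spec <- synthetic_spec(n_residues = 8, n_communities = 2)
  m <- gen_toy_structure(spec)
  write_community_pdb(m, attr(m, "community_labels"), file.path(d, "comm.pdb"))
  b <- bio3d::read.pdb(file.path(d, "comm.pdb"), verbose = FALSE)$atom$b
  expect_equal(sort(unique(b)), c(1, 2))
})
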