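# Multiensemble correlation of contact probabilities with log activity.

test_that("log transform and its base invariance", {
  tab <- data.frame(name = c("a", "b", "c"), type = "AC50", value_uM = c(10, 1, 100))
  x <- transform_activity(tab)
  expect_equal(as.numeric(x), c(1, 0, 2))
  expect_error(transform_activity(data.frame(name = "a", type = "AC50", value_uM = -1)),
               "positive")

  # Pearson rho is identical under base 10 and natural log
  set.seed(1)
  tabs <- lapply(1:4, function(i) make_table(list(c(1, 4, runif(1)), c(2, 5, runif(1))),
                                             paste0("m", i), nodes = 1:5))
  names(tabs) <- paste0("m", 1:4)
  act <- data.frame(name = names(tabs), type = "AC50", value_uM = c(2, 5, 11, 30))
  r10 <- pair_correlation(tabs, transform_activity(act, base = 10))
  rln <- pair_correlation(tabs, transform_activity(act, base = exp(1)))
  expect_equal(r10$rho, rln$rho, tolerance = 1e-12)
})

test_that("pair correlation: exact linear response, undefined cases, oracle", {
  xs <- c(0.5, 1.0, 1.5, 2.0)
  tabs <- lapply(seq_along(xs), function(i) {
    make_table(list(c(1, 4, 0.2 + 0.3 * xs[i]),   # increasing in x
                    c(2, 5, 0.5),                 # constant: undefined
                    c(3, 6, 0.9 - 0.2 * xs[i])),  # decreasing
               paste0("m", i), nodes = 1:6)
  })
  names(tabs) <- paste0("m", 1:4)
  x <- setNames(xs, names(tabs))
  pr <- pair_correlation(tabs, x)
  expect_equal(pr$rho[pr$node_i == 1], 1)
  expect_equal(pr$rho[pr$node_i == 3], -1)
  expect_true(is.na(pr$rho[pr$node_i == 2]) && !pr$defined[pr$node_i == 2])

  expect_error(pair_correlation(tabs[1:2], x[1:2]), ">= 3")
  expect_error(pair_correlation(tabs, setNames(rep(1, 4), names(tabs))), "constant")

  # random tables: rho equals the covariance-formula oracle to 1e-12
  for (s in 1:10) {
    set.seed(s)
    rt <- lapply(1:6, function(i) make_table(list(c(1, 4, runif(1)), c(2, 6, runif(1))),
                                             paste0("m", i), nodes = 1:6))
    names(rt) <- paste0("m", 1:6)
    rx <- setNames(rnorm(6), names(rt))
    pr <- pair_correlation(rt, rx)
    p14 <- vapply(rt, function(t) t$p_c[t$node_i == 1], 0)
    expect_equal(pr$rho[pr$node_i == 1], pearson_oracle(p14, rx), tolerance = 1e-12)
  }
})

test_that("community correlation sums inter-community pairs before correlating", {
  memb <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), as.character(1:6))
  xs <- c(0.2, 0.8, 1.4, 2.0)
  tabs <- lapply(seq_along(xs), function(i) {
    make_table(list(c(1, 4, 0.1 + 0.2 * xs[i]),   # communities 1-2
                    c(2, 3, 0.5 + 0.1 * xs[i]),   # communities 1-2
                    c(1, 5, 0.4)),                # communities 1-3, constant
               paste0("m", i), nodes = 1:6)
  })
  names(tabs) <- paste0("m", 1:4)
  x <- setNames(xs, names(tabs))
  cc <- community_correlation(tabs, x, memb)
  expect_equal(cc$rho[cc$community_a == 1 & cc$community_b == 2], 1)   # sum linear in x
  expect_true(is.na(cc$rho[cc$community_a == 1 & cc$community_b == 3]))
  expect_true(is.na(cc$rho[cc$community_a == 2 & cc$community_b == 3]))  # no pairs

  # sums equal an explicit pair loop to 1e-12
  for (s in 1:5) {
    set.seed(s)
    rt <- lapply(1:5, function(i) {
      u <- dcna:::pair_universe(6, 1)
      keep <- runif(nrow(u)) < 0.7
      make_table(Map(c, u$node_i[keep], u$node_j[keep], runif(sum(keep))),
                 paste0("m", i), nodes = 1:6)
    })
    names(rt) <- paste0("m", 1:5)
    rx <- setNames(rnorm(5), names(rt))
    cc <- community_correlation(rt, rx, memb)
    sums <- vapply(rt, function(t) {
      tot <- 0
      for (r in seq_len(nrow(t))) {
        ca <- memb[as.character(t$node_i[r])]; cb <- memb[as.character(t$node_j[r])]
        if (min(ca, cb) == 1 && max(ca, cb) == 2) tot <- tot + t$p_c[r]
      }
      tot
    }, 0)
    expect_equal(cc$rho[cc$community_a == 1 & cc$community_b == 2],
                 pearson_oracle(sums, rx), tolerance = 1e-12)
  }
})

test_that("planted responders exceed the Fisher-z lower bound with the planted sign", {
  spec <- synthetic_spec(n_residues = 12, n_communities = 2, n_ensembles = 8,
                         n_replicas = 1, n_frames = 5000, n_responders = 2,
                         responder_slope = -0.1, noise_sd = 0.01, seed = 33)
  gen <- gen_contact_ensembles(spec, include_reference = FALSE)
  x <- gen$truth$ensemble_log_activity
  pr <- pair_correlation(gen$tables, setNames(as.numeric(x), names(x)))
  # population rho implied by the planted model + sampling noise
  var_sig <- (0.1 * stats::sd(x))^2
  var_eps <- 0.01^2 + 0.25 / spec$n_frames
  rho_pop <- sqrt(var_sig / (var_sig + var_eps))
  lower <- tanh(atanh(rho_pop) - 1.96 / sqrt(length(x) - 3))
  for (r in seq_len(nrow(gen$truth$responder_pairs))) {
    rp <- gen$truth$responder_pairs[r, ]
    rho <- pr$rho[pr$node_i == rp$node_i & pr$node_j == rp$node_j]
    expect_lt(rho, 0)
    expect_gt(abs(rho), lower)
  }
})

test_that("null community pairs concentrate near zero correlation", {
  meds <- vapply(1:20, function(s) {
    spec <- synthetic_spec(n_residues = 10, n_communities = 2, n_ensembles = 8,
                           n_replicas = 1, n_frames = 300, p_within = 0.9,
                           p_between = 0.3, n_responders = 0, seed = 100 + s)
    gen <- gen_contact_ensembles(spec, include_reference = FALSE)
    x <- gen$truth$ensemble_log_activity
    cc <- community_correlation(gen$tables, setNames(as.numeric(x), names(x)),
                                gen$truth$community_labels)
    abs(cc$rho[cc$community_a == 1 & cc$community_b == 2])
  }, 0)
  expect_lt(stats::median(meds), 0.4)
})

test_that("function-linked ranking applies the cut and per-sign top-k", {
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 2L), as.character(1:7))
  pr <- data.frame(node_i = c(1, 2, 3, 1), node_j = c(4, 5, 6, 7),
                   rho = c(0.8, -1.0, -0.9, 0.3), n = 6,
                   defined = TRUE)
  out <- rank_function_linked(pr, memb, cut = 0.5, top_k = 3)
  expect_setequal(out$rho[out$above_cut], c(0.8, -1.0, -0.9))
  expect_equal(out$rho[!is.na(out$rank_negative)][order(out$rank_negative[!is.na(out$rank_negative)])],
               c(-1.0, -0.9))
  expect_equal(out$rho[which(out$rank_positive == 1)], 0.8)
  expect_true(0.3 %in% out$rho)                       # top-k keeps sub-cut pairs

  # all |rho| <= cut: threshold list empty, top-k still reported
  pr2 <- data.frame(node_i = c(1, 2), node_j = c(4, 5), rho = c(0.2, -0.3),
                    n = 6, defined = TRUE)
  out2 <- rank_function_linked(pr2, memb, cut = 0.5, top_k = 3)
  expect_false(any(out2$above_cut))
  expect_equal(nrow(out2), 2)

  # planted responders among ~100 pairs surface in the top-3 of their sign
  spec <- synthetic_spec(n_residues = 18, n_communities = 2, n_ensembles = 8,
                         n_replicas = 1, n_frames = 5000, n_responders = 3,
                         responder_slope = c(-0.1, 0.1, -0.1), noise_sd = 0.01,
                         seed = 55)
  gen <- gen_contact_ensembles(spec, include_reference = FALSE)
  x <- gen$truth$ensemble_log_activity
  pr3 <- pair_correlation(gen$tables, setNames(as.numeric(x), names(x)))
  ranked <- rank_function_linked(pr3, gen$truth$community_labels, cut = 0.5, top_k = 3)
  for (r in seq_len(3)) {
    rp <- gen$truth$responder_pairs[r, ]
    row <- ranked[ranked$node_i == rp$node_i & ranked$node_j == rp$node_j, ]
    expect_equal(nrow(row), 1)
    rank_col <- if (rp$slope > 0) row$rank_positive else row$rank_negative
    expect_lte(rank_col, 3)
  }
})
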