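# Multiensemble contact network analysis: Pearson correlation of contact
# probabilities across modulator-bound ensembles against log K.

#' The eight-modulator activity table
#'
#' Allosteric activity constants (K, micromolar) of the PIF-pocket
#' modulators used throughout: PS48, PS210, COM1, RS2, PSE10, RF4, com17 and
#' SS7. The measurement type differs by compound (AC50, EC50, IC50 or Kd),
#' pooled on one micromolar scale; a `type` column records which. PS48 also
#' has a dissociation constant (Kd = 10.3 uM) but its AC50 is used, so it is
#' not a "Kd-only" compound.
#'
#' @return data.frame of class `activity_table`: `name`, `type`, `value_uM`.
#' @export
activity_fixture <- function() {
  d <- data.frame(
    name = c("PS48", "PS210", "COM1", "RS2", "PSE10", "RF4", "com17", "SS7"),
    type = c("AC50", "AC50", "AC50", "Kd", "AC50", "Kd", "EC50", "IC50"),
    value_uM = c(7.95, 2.0, 34.0, 9.0, 18.75, 8.4, 23.0, 7.0),
    stringsAsFactors = FALSE
  )
  class(d) <- c("activity_table", "data.frame")
  d
}

#' Generate a random modulator activity table
#'
#' K values are log-uniform over `range`; useful for synthetic ensembles.
#'
#' @param n_modulators number of modulators (>= 3; Pearson correlation needs
#'   at least 3 points).
#' @param range (min, max) K in micromolar, both positive.
#' @param types measurement types to assign (recycled).
#' @param seed RNG seed.
#' @return `activity_table` data.frame.
#' @export
gen_activity_table <- function(n_modulators, range = c(2, 34),
                               types = "AC50", seed = 1) {
  if (n_modulators < 3) stopf("need at least 3 modulators for correlation analysis")
  if (any(range <= 0) || range[2] < range[1]) stopf("activity range must be positive and ordered")
  k <- with_seed(seed, 10^stats::runif(n_modulators, log10(range[1]), log10(range[2])))
  d <- data.frame(
    name = sprintf("M%02d", seq_len(n_modulators)),
    type = rep_len(types, n_modulators),
    value_uM = k,
    stringsAsFactors = FALSE
  )
  class(d) <- c("activity_table", "data.frame")
  d
}

#' Read an activity table from CSV (name, type, value_uM)
#' @param path CSV file.
#' @export
read_activity_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "type", "value_uM") %in% names(d))) {
    stopf("activity CSV needs columns name, type, value_uM")
  }
  if (any(d$value_uM <= 0)) stopf("activity values must be positive")
  if (anyDuplicated(d$name)) stopf("modulator names must be unique")
  class(d) <- c("activity_table", "data.frame")
  d
}

#' Exclude modulators characterized only by a dissociation constant
#'
#' Kd measures binding, not the activation readout of AC50/EC50/IC50;
#' dropping Kd-only compounds makes the functional axis more comparable. A
#' modulator whose recorded type is AC50/EC50/IC50 is retained even if a Kd
#' also exists for it.
#'
#' @param table `activity_table`.
#' @param exclude_kd_only apply the exclusion (default TRUE).
#' @return filtered `activity_table`; error if fewer than 3 rows remain.
#' @export
filter_activity <- function(table, exclude_kd_only = TRUE) {
  out <- if (exclude_kd_only) table[table$type != "Kd", , drop = FALSE] else table
  if (nrow(out) < 3) stopf("fewer than 3 modulators remain; correlation is undefined")
  rownames(out) <- NULL
  out
}

#' Log-transform activity constants
#'
#' x = log_base(K). Pearson correlation downstream is invariant to the base
#' (any base change is a positive linear map), so the choice is cosmetic;
#' base 10 is the default.
#'
#' @param table `activity_table`.
#' @param base logarithm base.
#' @return named numeric vector (names = modulator names), attribute
#'   `"transform"` recording the base.
#' @export
transform_activity <- function(table, base = 10) {
  if (any(table$value_uM <= 0)) stopf("activity values must be positive")
  x <- stats::setNames(log(table$value_uM, base = base), table$name)
  attr(x, "transform") <- sprintf("log%g(K/uM)", base)
  x
}

#' @noRd
check_x <- function(x) {
  if (length(x) < 3) stopf("correlation needs >= 3 ensembles")
  if (stats::sd(x) == 0) stopf("activity values are constant; correlation is undefined")
}

#' Pair probability matrix across ensembles (rows = pair keys, cols = x names)
#' @noRd
pair_matrix <- function(tables, x) {
  miss <- setdiff(names(x), names(tables))
  if (length(miss)) stopf("no contact table for modulator(s): %s", paste(miss, collapse = ", "))
  tables <- tables[names(x)]
  keys <- sort(unique(unlist(lapply(tables, function(t) pair_key(t$node_i, t$node_j)))))
  m <- matrix(0, length(keys), length(x), dimnames = list(keys, names(x)))
  for (lab in names(x)) {
    t <- tables[[lab]]
    m[pair_key(t$node_i, t$node_j), lab] <- t$p_c
  }
  m
}

#' Correlate residue-pair contact probabilities with log activity
#'
#' Sample Pearson correlation between each retained pair's p_c across the
#' modulator-bound ensembles and x = log K. The modulator-free ensemble has
#' no K and must not be among `tables`. Pairs with zero variance in p_c get
#' `rho = NA` (undefined, never coerced to 0).
#'
#' @param tables named list of ensemble [contact_table()]s, one per
#'   modulator; names must cover `names(x)`.
#' @param x named log-activity vector from [transform_activity()].
#' @return data.frame of class `correlation_result`: `node_i`, `node_j`,
#'   `rho`, `n`, `defined`.
#' @export
pair_correlation <- function(tables, x) {
  check_x(x)
  m <- pair_matrix(tables, x)
  sds <- apply(m, 1, stats::sd)
  rho <- rep(NA_real_, nrow(m))
  ok <- sds > 0
  if (any(ok)) rho[ok] <- as.numeric(stats::cor(t(m[ok, , drop = FALSE]), x))
  ij <- do.call(rbind, strsplit(rownames(m), "-"))
  out <- data.frame(node_i = as.integer(ij[, 1]), node_j = as.integer(ij[, 2]),
                    rho = rho, n = length(x), defined = ok)
  out <- out[order(out$node_i, out$node_j), ]
  rownames(out) <- NULL
  attr(out, "transform") <- attr(x, "transform")
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Correlate community-pair contact sums with log activity
#'
#' For each community pair (A, B), the per-ensemble scalar is the sum of
#' inter-community pair probabilities (for A = B, the within-community sum);
#' rho is its Pearson correlation with x. Community pairs with no retained
#' pairs, or a constant sum, are reported undefined (`rho = NA`).
#'
#' @inheritParams pair_correlation
#' @param partition [select_partition()] result or named membership vector.
#' @return data.frame of class `correlation_result`: `community_a`,
#'   `community_b`, `n_pairs`, `rho`, `n`, `defined`.
#' @export
community_correlation <- function(tables, x, partition) {
  check_x(x)
  m <- pair_matrix(tables, x)
  memb <- if (inherits(partition, "community_partition")) partition$membership else partition
  ij <- do.call(rbind, strsplit(rownames(m), "-"))
  miss <- setdiff(unique(as.character(ij)), names(memb))
  if (length(miss)) stopf("node(s) without community assignment: %s", paste(miss, collapse = ", "))
  ci <- as.integer(memb[ij[, 1]])
  cj <- as.integer(memb[ij[, 2]])
  ca <- pmin(ci, cj); cb <- pmax(ci, cj)
  comms <- sort(unique(as.integer(memb)))
  grid <- expand.grid(community_a = comms, community_b = comms)
  grid <- grid[grid$community_a <= grid$community_b, ]
  rho <- rep(NA_real_, nrow(grid))
  npairs <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    sel <- ca == grid$community_a[r] & cb == grid$community_b[r]
    npairs[r] <- sum(sel)
    if (!npairs[r]) next
    s <- colSums(m[sel, , drop = FALSE])
    if (stats::sd(s) > 0) rho[r] <- as.numeric(stats::cor(s, x))
  }
  out <- data.frame(community_a = grid$community_a, community_b = grid$community_b,
                    n_pairs = npairs, rho = rho, n = length(x),
                    defined = !is.na(rho))
  out <- out[order(out$community_a, out$community_b), ]
  rownames(out) <- NULL
  attr(out, "transform") <- attr(x, "transform")
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Rank function-linked residue pairs per community pair
#'
#' For every community pair: all residue pairs with |rho| strictly above
#' `cut`, plus the `top_k` strongest positive and `top_k` strongest negative
#' correlations. Undefined correlations never enter. Ties broken by
#' (node_i, node_j).
#'
#' @param pair_results [pair_correlation()] output.
#' @param partition [select_partition()] result or named membership vector.
#' @param cut absolute-correlation threshold (default 0.5, strict).
#' @param top_k per-sign count (default 3).
#' @return data.frame: `community_a`, `community_b`, `node_i`, `node_j`,
#'   `rho`, `above_cut`, `rank_positive`, `rank_negative` (NA when outside
#'   the top k of that sign).
#' @export
rank_function_linked <- function(pair_results, partition, cut = 0.5, top_k = 3) {
  memb <- if (inherits(partition, "community_partition")) partition$membership else partition
  pr <- pair_results[pair_results$defined, , drop = FALSE]
  if (!nrow(pr)) {
    return(data.frame(community_a = integer(0), community_b = integer(0),
                      node_i = integer(0), node_j = integer(0), rho = numeric(0),
                      above_cut = logical(0), rank_positive = integer(0),
                      rank_negative = integer(0)))
  }
  miss <- setdiff(as.character(unique(c(pr$node_i, pr$node_j))), names(memb))
  if (length(miss)) stopf("node(s) without community assignment: %s", paste(miss, collapse = ", "))
  ci <- as.integer(memb[as.character(pr$node_i)])
  cj <- as.integer(memb[as.character(pr$node_j)])
  pr$community_a <- pmin(ci, cj)
  pr$community_b <- pmax(ci, cj)
  parts <- split(pr, paste(pr$community_a, pr$community_b))
  out <- lapply(parts, function(s) {
    s$above_cut <- abs(s$rho) > cut
    pos <- s$rho > 0
    neg <- s$rho < 0
    s$rank_positive <- NA_integer_
    s$rank_negative <- NA_integer_
    if (any(pos)) {
      op <- order(-s$rho[pos], s$node_i[pos], s$node_j[pos])
      s$rank_positive[pos][op] <- seq_len(sum(pos))
    }
    if (any(neg)) {
      on <- order(s$rho[neg], s$node_i[neg], s$node_j[neg])
      s$rank_negative[neg][on] <- seq_len(sum(neg))
    }
    s$rank_positive[!is.na(s$rank_positive) & s$rank_positive > top_k] <- NA_integer_
    s$rank_negative[!is.na(s$rank_negative) & s$rank_negative > top_k] <- NA_integer_
    s[s$above_cut | !is.na(s$rank_positive) | !is.na(s$rank_negative), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  cols <- c("community_a", "community_b", "node_i", "node_j", "rho",
            "above_cut", "rank_positive", "rank_negative")
  out <- out[order(out$community_a, out$community_b, -abs(out$rho), out$node_i, out$node_j), cols]
  rownames(out) <- NULL
  out
}
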