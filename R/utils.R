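# Internal helpers shared across modules.

#' Canonical unordered pair key
#'
#' Node pairs are stored with `node_i < node_j`; the key "i-j" indexes pair
#' tables and replica matrices.
#' @noRd
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "-")
}

#' @noRd
canonical_pair_df <- function(i, j) {
  data.frame(node_i = pmin(i, j), node_j = pmax(i, j))
}

#' Evaluate code with a temporary RNG state
#'
#' Seeds the generator, runs `code`, then restores the caller's RNG state so
#' library calls never perturb user-level randomness.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic child seed
#'
#' Expands one user seed into per-ensemble / per-replica seeds so replicas are
#' individually reproducible. Arithmetic kept in doubles below 2^53, result
#' below 2^31 (R integer range).
#' @noRd
child_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1009 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same node set
#' (1 = identical up to relabeling, ~0 = random). Used to score recovery of
#' planted community structure.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
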