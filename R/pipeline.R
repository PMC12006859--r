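# End-to-end orchestration: contacts -> consensus communities -> dCNA ->
# multiensemble correlation, from a single config.

#' Default pipeline parameters
#'
#' The standard parameterization of the analysis: 4.5 Angstrom heavy-atom
#' cutoff, sequence separation 3, 10% rare-contact floor, 0.9 consensus
#' threshold, 0.1 Delta f significance, 0.5 correlation cut, top-3 ranking,
#' log base 10.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    cutoff = 4.5,
    min_separation = 3,
    rare_floor = 0.10,
    consensus_threshold = 0.9,
    delta_threshold = 0.1,
    correlation_cut = 0.5,
    top_k = 3,
    log_base = 10,
    exclude_kd_only = FALSE,
    reference = "apo",
    seed = 1
  )
}

#' Read a run configuration from YAML
#'
#' Flat keys as in [default_config()], plus either `synthetic:` (arguments
#' for [synthetic_spec()]) or `contact_tables:` (path to a CSV readable by
#' [read_contact_tables()]), an optional `activity:` (path to a CSV for
#' [read_activity_csv()], or the string `"fixture"`), and `out_dir`.
#' Unspecified keys take their defaults.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @noRd
validate_config <- function(config) {
  for (k in c("rare_floor", "consensus_threshold", "delta_threshold")) {
    v <- config[[k]]
    if (!is.numeric(v) || v < 0 || v > 1) stopf("%s must be in [0,1], got %s", k, v)
  }
  if (config$cutoff <= 0) stopf("cutoff must be positive")
  if (config$min_separation < 0) stopf("min_separation must be >= 0")
  if (config$top_k < 1) stopf("top_k must be >= 1")
  if (config$log_base <= 0 || config$log_base == 1) stopf("log_base must be positive and != 1")
  invisible(config)
}

#' Validate an ensemble manifest
#'
#' Checks a replica manifest and reports the accumulated simulation time:
#' total = sum over replicas of their simulated time (e.g. 8 ensembles x 3
#' replicas x 2.0 us = 48.0 us).
#'
#' @param manifest data.frame with columns `label`, `replica`, `time_us` and
#'   optionally `path`.
#' @return list: `n_ensembles`, `replicas_per_ensemble` (named), `total_time_us`,
#'   `errors` (character vector; empty when valid).
#' @export
validate_manifest <- function(manifest) {
  errors <- character(0)
  req <- c("label", "replica", "time_us")
  if (!is.data.frame(manifest) || !all(req %in% names(manifest))) {
    stopf("manifest must be a data.frame with columns %s", paste(req, collapse = ", "))
  }
  if (!nrow(manifest)) stopf("empty manifest")
  dup <- duplicated(manifest[, c("label", "replica")])
  if (any(dup)) {
    stopf("duplicate ensemble/replica entries: %s",
          paste(unique(manifest$label[dup]), collapse = ", "))
  }
  if (any(manifest$time_us <= 0)) errors <- c(errors, "non-positive replica time")
  if ("path" %in% names(manifest)) {
    missing <- manifest$path[!is.na(manifest$path) & !file.exists(manifest$path)]
    if (length(missing)) errors <- c(errors, paste("missing file:", missing))
  }
  list(
    n_ensembles = length(unique(manifest$label)),
    replicas_per_ensemble = vapply(split(manifest, manifest$label), nrow, 0L),
    total_time_us = sum(manifest$time_us),
    errors = errors
  )
}

#' Run the full contact-network analysis pipeline
#'
#' Stages: obtain per-ensemble contact tables (synthetic generation or a
#' precomputed CSV) -> rare-contact filter -> consensus network ->
#' Girvan-Newman communities -> difference network of every modulator-bound
#' ensemble against the reference -> multiensemble correlation (pair and
#' community level, reference excluded) -> function-linked ranking. All
#' stage outputs are written to `out_dir` together with a machine-readable
#' provenance record; outputs are deterministic for a fixed config and seed.
#'
#' @param config list (see [default_config()] / [read_run_config()]) or a
#'   YAML path.
#' @param out_dir output directory (created); overrides `config$out_dir`.
#' @return invisibly, a list with `tables`, `consensus`, `partition`,
#'   `differences`, `pair_correlations`, `community_correlations`, `ranked`,
#'   `counts`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stopf("no out_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # --- stage: input tables -------------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_spec, utils::modifyList(config$synthetic,
                                                      list(seed = config$seed)))
    gen <- gen_contact_ensembles(spec, include_reference = TRUE)
    tables <- gen$tables
    activity <- gen$activity
    write_ground_truth(gen$truth, file.path(out_dir, "ground_truth.json"))
    say("stage input: synthetic, %d ensembles (+apo), %d residues",
        spec$n_ensembles, spec$n_residues)
  } else if (!is.null(config$contact_tables)) {
    tables <- read_contact_tables(config$contact_tables)
    activity <- if (is.null(config$activity) || identical(config$activity, "fixture")) {
      activity_fixture()
    } else {
      read_activity_csv(config$activity)
    }
    say("stage input: %d ensemble tables from %s", length(tables), config$contact_tables)
  } else {
    stopf("config needs either 'synthetic' or 'contact_tables'")
  }
  if (!is.null(config$activity) && !identical(config$activity, "fixture") &&
      is.character(config$activity)) {
    activity <- read_activity_csv(config$activity)
  }
  reference <- config$reference
  if (!reference %in% names(tables)) {
    stopf("reference ensemble '%s' not among tables (%s)", reference,
          paste(names(tables), collapse = ", "))
  }

  # --- stage: contacts filter ---------------------------------------------
  tables <- filter_rare(tables, floor = config$rare_floor)
  write_contact_tables(tables, file.path(out_dir, "contact_tables.csv"))
  say("stage contacts: %d pairs retained at floor %.2f",
      length(attr(tables, "retained")), config$rare_floor)

  # --- stage: consensus + communities --------------------------------------
  consensus <- build_consensus(tables, threshold = config$consensus_threshold)
  partition <- detect_communities(consensus)
  write_edge_list(consensus, file.path(out_dir, "consensus_edges.csv"))
  write_consensus_graphml(consensus, file.path(out_dir, "consensus.graphml"))
  write_partition_csv(partition, file.path(out_dir, "partition.csv"))
  say("stage communities: %d edges, %d communities, Q = %.4f",
      nrow(consensus$edges), partition$n_communities, partition$q)

  # --- stage: dCNA ----------------------------------------------------------
  free <- tables[[reference]]
  bound_labels <- setdiff(names(tables), reference)
  differences <- list()
  drows <- list()
  for (lab in bound_labels) {
    dn <- classify_deltas(community_delta(tables[[lab]], free, partition),
                          threshold = config$delta_threshold)
    differences[[lab]] <- dn
    drows[[lab]] <- cbind(comparison = lab, as.data.frame(dn))
  }
  dcna_df <- do.call(rbind, drows)
  rownames(dcna_df) <- NULL
  utils::write.csv(dcna_df, file.path(out_dir, "dcna.csv"),
                   row.names = FALSE, quote = FALSE)
  say("stage dcna: %d comparisons vs '%s', %d significant community pairs",
      length(bound_labels), reference, sum(dcna_df$significant))

  # --- stage: multiensemble correlation ------------------------------------
  activity_used <- filter_activity(activity, exclude_kd_only = config$exclude_kd_only)
  activity_used <- activity_used[activity_used$name %in% bound_labels, , drop = FALSE]
  if (nrow(activity_used) < 3) stopf("fewer than 3 modulator ensembles with activity values")
  x <- transform_activity(activity_used, base = config$log_base)
  pc <- pair_correlation(tables[activity_used$name], x)
  cc <- community_correlation(tables[activity_used$name], x, partition)
  ranked <- rank_function_linked(pc, partition, cut = config$correlation_cut,
                                 top_k = config$top_k)
  utils::write.csv(pc, file.path(out_dir, "pair_correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cc, file.path(out_dir, "community_correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ranked, file.path(out_dir, "ranked_pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  say("stage mecna: %d modulators, %d defined pair correlations, %d ranked",
      nrow(activity_used), sum(pc$defined), nrow(ranked))

  counts <- list(
    pairs_retained = length(attr(tables, "retained")),
    consensus_edges = nrow(consensus$edges),
    n_communities = partition$n_communities,
    modularity = partition$q,
    significant_deltas = sum(dcna_df$significant),
    modulators_used = nrow(activity_used)
  )
  provenance <- list(
    package = "dcna",
    version = as.character(utils::packageVersion("dcna")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    counts = counts
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(tables = tables, consensus = consensus, partition = partition,
                 differences = differences, pair_correlations = pc,
                 community_correlations = cc, ranked = ranked, counts = counts))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
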