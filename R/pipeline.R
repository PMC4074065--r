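# End-to-end orchestration of the two phases with one master seed and a
# serializable configuration.

#' Pipeline configuration
#'
#' Aggregates every tunable of the two-phase pipeline. All stochastic stages
#' derive their streams from the master seed, so a full rerun with the same
#' configuration is deterministic.
#'
#' @param seed master seed.
#' @param acceptance_threshold variance-weighted error acceptance threshold
#'   (default 0.75).
#' @param k_max max regulators per subnetwork (default 3).
#' @param ensemble_cap accepted members per ensemble (default 100).
#' @param attempt_budget fit attempts per target (default 500).
#' @param n_networks putative networks sampled (default 1000).
#' @param n_starts optimizer starts per subset.
#' @param hill Hill exponent (default 2).
#' @param var_floor variance floor (default 0.01).
#' @param som_runs pooled SOM runs (default 200 at benchmark scale; the
#'   study pooled 2,240).
#' @param grid_min,grid_max SOM square-grid side range (defaults 3, 50).
#' @param som_epochs batch epochs per SOM run.
#' @param dispersion_cutoff dispersion pre-filter cutoff (default 0.20).
#' @param coincidence_threshold cluster partition threshold (default 0.70).
#' @param w fidelity weight (default 1).
#' @param cutoffs fidelity cutoffs for the Phase 1 filtration sweep
#'   (default `c(2, 2.5, 3)`).
#' @param scaffold_cutoff cutoff of the Phase 1 network used as the Phase 2
#'   scaffold (default 2).
#' @param phase2_cutoff fidelity cutoff after expansion (default 2.5).
#' @param max_cluster_product secondary prioritization filter (default 30).
#' @return a list of class `grn_config`.
#' @export
pipeline_config <- function(seed = 1L, acceptance_threshold = 0.75, k_max = 3L,
                            ensemble_cap = 100L, attempt_budget = 500L,
                            n_networks = 1000L, n_starts = 3L, hill = 2,
                            var_floor = 0.01, som_runs = 200L, grid_min = 3L,
                            grid_max = 50L, som_epochs = 20L,
                            dispersion_cutoff = 0.20,
                            coincidence_threshold = 0.70, w = 1,
                            cutoffs = c(2, 2.5, 3), scaffold_cutoff = 2,
                            phase2_cutoff = 2.5, max_cluster_product = 30) {
  cfg <- mget(names(formals(pipeline_config)))
  structure(cfg, class = "grn_config")
}

#' Configuration hash
#'
#' MD5 of the JSON-serialized configuration; stamped into output headers so
#' artifacts from different configurations are never silently mixed.
#'
#' @param cfg a `grn_config`.
#' @return hex digest string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a `grn_config` (unspecified fields take their defaults).
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop_invalid("unknown config fields: ",
                                    paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration
#'
#' @param cfg a `grn_config`.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(cfg), path)
  } else {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

search_config_of <- function(cfg) {
  ensemble_config(k_max = cfg$k_max, cap = cfg$ensemble_cap,
                  budget = cfg$attempt_budget,
                  threshold = cfg$acceptance_threshold,
                  n_starts = cfg$n_starts, hill = cfg$hill,
                  var_floor = cfg$var_floor)
}

#' Run Phase 1: infer, score and filter the scaffold network
#'
#' Row-scales the expression matrix if needed, builds a subnetwork ensemble
#' per gene, samples putative networks, pools edge statistics, attaches
#' semantic similarity, computes fidelity scores at weight `w` and filters
#' at each configured cutoff (a nested filtration).
#'
#' @param m a [grn_expr] of the genes of interest.
#' @param annotations named list of term sets.
#' @param cfg a [pipeline_config()].
#' @return list of class `grn_phase1`: `records` (scored edge table),
#'   `networks` (one `grn_network` per cutoff), `ensembles`, `counts`
#'   (stage-by-stage bookkeeping), `config_hash`.
#' @export
run_phase1 <- function(m, annotations, cfg = pipeline_config()) {
  if (!m$scaled) m <- scale_rows(m)
  ensembles <- build_ensembles(m, search_config_of(cfg),
                               seed = derive_seed(cfg$seed, 101L))
  networks <- sample_networks(ensembles, cfg$n_networks,
                              seed = derive_seed(cfg$seed, 102L))
  records <- edge_statistics(networks)
  records <- pairwise_similarity(annotations, records)
  records <- score_fidelity(records, cfg$w)
  nets <- lapply(cfg$cutoffs, function(ct) filter_network(records, ct))
  names(nets) <- as.character(cfg$cutoffs)
  counts <- list(
    genes = nrow(m$values),
    nonempty_ensembles = sum(vapply(ensembles, function(e) length(e$members) > 0, logical(1))),
    edges_called = nrow(records),
    edges_per_cutoff = vapply(nets, function(n) nrow(n$edges), integer(1))
  )
  structure(list(records = records, networks = nets, ensembles = ensembles,
                 expression = m, counts = counts,
                 config_hash = config_hash(cfg)),
            class = "grn_phase1")
}

#' Run Phase 2: cluster, expand, rescore and prioritize
#'
#' Co-clusters the full gene set (after the dispersion pre-filter, when
#' unscaled measurement-scale data are supplied), expands the scaffold over
#' the resulting partition, recomputes fidelity over the expanded
#' population, filters at the Phase 2 cutoff and applies the
#' cluster-product prioritization.
#'
#' @param phase1 a `grn_phase1` result.
#' @param m_full [grn_expr] over the full gene universe (superset of the
#'   scaffold genes).
#' @param annotations annotation set over the full universe.
#' @param cfg the same [pipeline_config()] used for Phase 1.
#' @param partition optional precomputed `grn_partition` (skips SOM
#'   co-clustering).
#' @param raw optional unscaled [grn_expr] for the dispersion pre-filter;
#'   when omitted the filter is skipped (scaled data carry no dispersion
#'   information).
#' @return list of class `grn_phase2`: `expanded` (rescored edge table),
#'   `network` (filtered), `prioritized`, `partition`, `config_hash`.
#' @export
run_phase2 <- function(phase1, m_full, annotations, cfg = pipeline_config(),
                       partition = NULL, raw = NULL) {
  if (!inherits(phase1, "grn_phase1")) stop_invalid("phase1 result required")
  if (phase1$config_hash != config_hash(cfg)) {
    stop("configuration hash mismatch: Phase 1 artifacts come from a different config")
  }
  if (!m_full$scaled) m_full <- scale_rows(m_full)
  if (is.null(partition)) {
    keep <- gene_ids(m_full)
    if (!is.null(raw)) {
      keep <- dispersion_filter(raw, cfg$dispersion_cutoff)$included
      keep <- intersect(gene_ids(m_full), keep)
    }
    cc <- co_cluster(subset_expr(m_full, keep), n_runs = cfg$som_runs,
                     grid_min = cfg$grid_min, grid_max = cfg$grid_max,
                     epochs = cfg$som_epochs,
                     seed = derive_seed(cfg$seed, 103L))
    partition <- partition_clusters(cc, cfg$coincidence_threshold)
  }
  scaffold <- filter_network(phase1$records, cfg$scaffold_cutoff)
  expanded <- expand_network(scaffold, partition, annotations)
  network <- rescore_and_filter(expanded, cfg$w, cfg$phase2_cutoff)
  prioritized <- prioritize_edges(network, cfg$max_cluster_product)
  structure(list(expanded = score_fidelity(expanded, cfg$w), network = network,
                 prioritized = prioritized, partition = partition,
                 config_hash = config_hash(cfg)),
            class = "grn_phase2")
}
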