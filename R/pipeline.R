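#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the four-step procedure (similarity network,
#' clustering, disease assignment, plant assignment) plus evaluation and
#' baseline options. The defaults are the operating point used throughout
#' the package: top 0.7% of ranked pairs, cluster density 0.9, cluster
#' property 0.5, minimum reported cluster size 3, matching-score threshold
#' 0.6 (strict).
#'
#' @param top_fraction fraction of ranked pairs kept as edges.
#' @param d_in,cp_in clustering thresholds, see [dpcluso_params()].
#' @param min_cluster_size clusters below this size are dropped before the
#'   supervised stage.
#' @param matching_threshold matching-score threshold (strict `>`).
#' @param exclude_ids formula ids to drop; `exclude_stage` chooses whether
#'   they are dropped before network construction (`"pre_network"`,
#'   default) or only ignored at evaluation (`"evaluation_only"`).
#' @param random_models run size-matched ER/BA/CNN baselines (logical).
#' @param replicates baseline replicates per model.
#' @param seed master seed (only the random baselines consume randomness;
#'   the core pipeline is deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(top_fraction = 0.007, d_in = 0.9, cp_in = 0.5,
                            min_cluster_size = 3, matching_threshold = 0.6,
                            exclude_ids = character(0),
                            exclude_stage = c("pre_network", "evaluation_only"),
                            random_models = FALSE, replicates = 10, seed = 1) {
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]")
  if (matching_threshold < 0 || matching_threshold >= 1)
    stop("matching_threshold must be in [0, 1)")
  structure(list(top_fraction = top_fraction,
                 params = dpcluso_params(d_in, cp_in, min_cluster_size),
                 min_cluster_size = as.integer(min_cluster_size),
                 matching_threshold = matching_threshold,
                 exclude_ids = as.character(exclude_ids),
                 exclude_stage = match.arg(exclude_stage),
                 random_models = isTRUE(random_models),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full prediction pipeline on a formula dataset
#'
#' Executes: optional formula exclusion, pairwise phi correlations,
#' top-fraction edge selection, network construction and statistics,
#' density-periphery clustering with coverage, size filtering, dominant
#' disease and plant assignment, relation prediction, and (when a gold
#' standard is supplied) TPR evaluation. When `out_dir` is given, every
#' intermediate artifact is written with a stable filename together with a
#' `manifest.json` logging the parameters and the counts at each stage.
#'
#' @param ds a labeled `formula_dataset`.
#' @param config a [pipeline_config()].
#' @param gold optional gold standard (named list plant -> efficacy ids).
#' @param emap efficacy map, required when `gold` is given.
#' @param out_dir optional output directory (created if missing).
#' @return list with `dataset`, `pairs_n`, `edges`, `network`, `stats`,
#'   `random_stats` (NULL unless requested), `clusters`, `filtered`,
#'   `prediction` (relations + per-cluster assignments), `curve`,
#'   `evaluation` (NULL without gold), `manifest`.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), gold = NULL,
                         emap = NULL, out_dir = NULL) {
  stopifnot(inherits(ds, "formula_dataset"))
  full_labels <- ds$labels
  if (length(config$exclude_ids) && config$exclude_stage == "pre_network")
    ds <- exclude_formulas(ds, intersect(config$exclude_ids,
                                         rownames(ds$incidence)))
  pairs <- pairwise_correlations(ds)
  edges <- select_top_fraction(pairs, config$top_fraction)
  net <- build_network(edges)
  stats <- network_statistics(net)
  random_stats <- NULL
  if (config$random_models) {
    random_stats <- lapply(c(ER = "ER", BA = "BA", CNN = "CNN"), function(m)
      replicate_statistics(m, stats$n_nodes, stats$n_edges,
                           replicates = config$replicates,
                           seed = config$seed)$summary)
  }
  clusters <- cluster_network(net, config$params)
  filtered <- filter_clusters(clusters, config$min_cluster_size)
  labels <- ds$labels
  if (config$exclude_stage == "evaluation_only" && length(config$exclude_ids))
    labels[intersect(config$exclude_ids, names(labels))] <-
      list(integer(0))
  prediction <- predict_relations(filtered, ds, labels,
                                  config$matching_threshold)
  curve <- success_rate_curve(filtered, labels)
  evaluation <- NULL
  if (!is.null(gold)) {
    if (is.null(emap)) stop("supply emap together with gold")
    evaluation <- evaluate_predictions(prediction$relations, gold, emap)
  }
  manifest <- list(
    parameters = list(
      top_fraction = config$top_fraction, d_in = config$params$d_in,
      cp_in = config$params$cp_in, min_cluster_size = config$min_cluster_size,
      matching_threshold = config$matching_threshold,
      exclude_stage = config$exclude_stage,
      n_excluded = length(config$exclude_ids), seed = config$seed),
    counts = list(
      formulas = nrow(ds$incidence), plants = ncol(ds$incidence),
      pairs = nrow(pairs), edges = nrow(edges),
      min_retained_corr = attr(edges, "min_corr"),
      nodes = stats$n_nodes,
      clusters = length(clusters$clusters),
      clusters_min_size = length(filtered$clusters),
      qualified_clusters = sum(prediction$assignments$qualified),
      predictions = nrow(prediction$relations),
      distinct_predicted_plants = length(unique(prediction$relations$plant_id)))
  )
  result <- list(dataset = ds, pairs_n = nrow(pairs), edges = edges,
                 network = net, stats = stats, random_stats = random_stats,
                 clusters = clusters, filtered = filtered,
                 prediction = prediction, curve = curve,
                 evaluation = evaluation, manifest = manifest,
                 labels = labels, full_labels = full_labels)
  if (!is.null(out_dir)) write_run_dir(result, config, out_dir)
  result
}

# Internal: persist all pipeline artifacts with stable filenames.
write_run_dir <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_edge_list(result$network, p("edges.tsv"))
  write_network_graphml(result$network, p("network.graphml"))
  jsonlite::write_json(result$stats, p("network_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(degree_distribution_table(result$network),
                     p("degree_distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_clusters(result$clusters, p("clusters.json"), p("clusters.tsv"))
  utils::write.table(result$prediction$assignments, p("assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$prediction$relations, p("predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$curve$curve, p("success_rate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$curve$histogram, p("matching_score_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$random_stats)) {
    cmp <- do.call(rbind, lapply(names(result$random_stats), function(m) {
      s <- result$random_stats[[m]]; s$model <- m; s
    }))
    utils::write.table(cmp, p("random_model_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$evaluation)) {
    utils::write.table(result$evaluation$by_efficacy, p("evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
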