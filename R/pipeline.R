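#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults mirror the
#' analysis conditions: STRING high-confidence cutoff 0.7, DEG thresholds
#' FDR <= 0.01 and |log2FC| >= 0.5, cluster size > 20, enrichment FDR
#' 0.01, inflation grid 1.2-5.0, hub rule top-3 in >= 3 of 4 metrics.
#'
#' @param ppi_threshold Minimum interaction confidence.
#' @param deg_fdr_max,deg_abs_log2fc_min DEG significance thresholds.
#' @param cluster_min_size Cluster size filter (strictly greater).
#' @param enrichment_fdr Term/pathway significance cutoff.
#' @param inflation_grid MCL inflation grid.
#' @param hub_top_k,hub_min_metrics Hub selection rule.
#' @param association_ess,association_threshold Bayesian association
#'   prior strength and acceptance threshold.
#' @param seed Seed for any randomness (synthetic generation).
#' @param ... Unknown keys are rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ppi_threshold = 0.7,
                            deg_fdr_max = 0.01,
                            deg_abs_log2fc_min = 0.5,
                            cluster_min_size = 20,
                            enrichment_fdr = 0.01,
                            inflation_grid = seq(1.2, 5, by = 0.2),
                            hub_top_k = 3,
                            hub_min_metrics = 3,
                            association_ess = 1,
                            association_threshold = 0,
                            seed = 1L,
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  stopifnot(ppi_threshold >= 0, ppi_threshold <= 1,
            deg_fdr_max > 0, deg_abs_log2fc_min >= 0,
            cluster_min_size >= 0, enrichment_fdr > 0,
            all(inflation_grid > 1), hub_top_k >= 1,
            hub_min_metrics >= 1, hub_min_metrics <= 4,
            association_ess > 0)
  structure(list(ppi_threshold = ppi_threshold,
                 deg_fdr_max = deg_fdr_max,
                 deg_abs_log2fc_min = deg_abs_log2fc_min,
                 cluster_min_size = cluster_min_size,
                 enrichment_fdr = enrichment_fdr,
                 inflation_grid = inflation_grid,
                 hub_top_k = hub_top_k,
                 hub_min_metrics = hub_min_metrics,
                 association_ess = association_ess,
                 association_threshold = association_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline on a study
#'
#' Stages in order: enhance (DEG filter + attribute-enhanced graph) ->
#' cluster (inflation-tuned MCL) -> hubs/enrichment -> phenotype
#' association -> variant classification -> multi-omics integration.
#'
#' @param study Input bundle as produced by [generate_study()] (or
#'   assembled from files via the readers): needs `edges`, `degs`,
#'   `expression`, `phenotypes`, `vcf`, `consequences`, `terms`,
#'   `perturbations`.
#' @param config A [pipeline_config()].
#' @param phenotype_directions Optional named vector phenotype ->
#'   "up"/"down" for the integration layer.
#' @param out_dir Optional directory; when given, every stage's artifact
#'   is written there (TSV/CSV/GMT/VCF/GraphML/JSON report).
#' @return List: `graph`, `solution`, `selected_clusters`,
#'   `cluster_stats`, `centralities`, `hubs`, `enrichment` (per selected
#'   cluster), `labels`, `associations`, `variants`, `variant_summary`,
#'   `network`, `anchored`, `model_table`, `report` (counts, chosen
#'   inflation, Q, warnings).
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         phenotype_directions = NULL, out_dir = NULL) {
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }

  degs <- filter_degs(study$degs,
                      deg_filter(config$deg_fdr_max,
                                 config$deg_abs_log2fc_min))
  graph <- build_enhanced_graph(study$edges, degs,
                                confidence_threshold = config$ppi_threshold)
  if (igraph::vcount(graph) == 0) {
    note("empty enhanced graph; downstream network stages skipped")
  }

  tuned <- tune_inflation(graph, grid = config$inflation_grid)
  solution <- tuned$solution
  log2fc <- stats::setNames(degs$log2FC, degs$gene)
  cstats <- cluster_stats(solution, log2fc)
  selected <- filter_clusters(solution, log2fc,
                              min_size = config$cluster_min_size)

  cent <- centralities(graph, solution)
  hubs <- select_hubs(cent, top_k = config$hub_top_k,
                      min_metrics = config$hub_min_metrics)

  universe <- study$degs$gene
  enrichment <- lapply(stats::setNames(selected, paste0("C", selected)),
                       function(cl) {
    genes_cl <- names(solution$membership)[solution$membership == cl]
    enrich_terms(genes_cl, universe, study$terms)
  })
  labels <- vapply(enrichment, label_cluster,
                   fdr_max = config$enrichment_fdr, FUN.VALUE = "")

  assoc <- associate_all(study$expression, study$phenotypes,
                         ess = config$association_ess,
                         threshold = config$association_threshold)

  classified <- classify_variants(study$vcf, study$consequences)
  vsummary <- summarize_variants(classified)

  memberships <- do.call(rbind, lapply(names(study$terms), function(tn) {
    data.frame(gene = study$terms[[tn]], pathway = tn,
               stringsAsFactors = FALSE)
  }))
  gene_tab <- data.frame(gene = degs$gene, log2FC = degs$log2FC,
                         cluster = unname(solution$membership[degs$gene]),
                         stringsAsFactors = FALSE)
  network <- assemble(gene_tab, memberships, study$perturbations,
                      assoc, classified,
                      phenotype_directions = phenotype_directions,
                      fdr_max = config$enrichment_fdr)
  anchored <- extract_anchor_subnetwork(network, hubs$gene)
  model <- tabulate_model(anchored)

  report <- list(
    n_degs = nrow(degs),
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    inflation = tuned$inflation,
    Q = tuned$Q,
    n_clusters = solution$n_clusters,
    n_selected_clusters = length(selected),
    n_hubs = nrow(hubs),
    n_passing_associations = sum(assoc$passes),
    n_variant_rows = vsummary$n_rows,
    n_variants = vsummary$n_variants,
    n_network_edges = nrow(network$edges),
    n_anchored_edges = nrow(anchored$edges),
    n_positive = model$n_positive,
    n_negative = model$n_negative,
    seed = config$seed,
    warnings = warnings_log
  )

  out <- list(graph = graph, solution = solution,
              selected_clusters = selected, cluster_stats = cstats,
              centralities = cent, hubs = hubs, enrichment = enrichment,
              labels = labels, associations = assoc,
              variants = classified, variant_summary = vsummary,
              network = network, anchored = anchored,
              model_table = model$table, report = report)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(out, out_dir)
  }
  out
}

#' Write every pipeline artifact to a directory
#'
#' @param result Output of [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  assign_tab <- data.frame(gene = names(result$solution$membership),
                           cluster = unname(result$solution$membership))
  utils::write.table(assign_tab, p("clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$cluster_stats, p("cluster_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$centralities, p("centralities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$hubs, p("hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$associations, p("associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$variants, p("variants_classified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$model_table, p("model_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(result$graph, p("enhanced_graph.graphml"),
                      format = "graphml")
  igraph::write_graph(integration_igraph(result$network),
                      p("integration_network.graphml"), format = "graphml")
  jsonlite::write_json(result$report, p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
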