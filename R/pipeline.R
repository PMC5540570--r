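#' Pipeline configuration
#'
#' Collects every stage parameter with the study-scale defaults: FPKM
#' filter threshold 20, 25,000 iterations of 2,000-gene subsets, edge
#' thresholds Pcor 0.035 / PCC 0.35, MCL inflation 1.5, minimum module size
#' 5. Round-trips losslessly through [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param min_max_fpkm low-expression filter threshold.
#' @param n_iterations,subset_size sampling plan for Pcor estimation.
#' @param pcor_threshold,pcc_threshold edge selection thresholds.
#' @param inflation,min_module_size MCL granularity and module size floor.
#' @param seed global seed; stage seeds are derived from it by stable
#'   hashing of stage names, so adding a stage never perturbs the
#'   randomness of earlier stages.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(min_max_fpkm = 20, n_iterations = 25000L,
                            subset_size = 2000L, pcor_threshold = 0.035,
                            pcc_threshold = 0.35, inflation = 1.5,
                            min_module_size = 5L, seed = 1L) {
  structure(list(min_max_fpkm = min_max_fpkm,
                 n_iterations = as.integer(n_iterations),
                 subset_size = as.integer(subset_size),
                 pcor_threshold = pcor_threshold,
                 pcc_threshold = pcc_threshold,
                 inflation = inflation,
                 min_module_size = as.integer(min_module_size),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as flat YAML
#' @param config a `PipelineConfig`.
#' @param path file path.
#' @return `read_pipeline_config`: a `PipelineConfig`;
#'   `write_pipeline_config`: `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the network-construction pipeline end to end
#'
#' filter -> log transform -> subset-sampled shrinkage Pcor -> PCC -> signed
#' edge selection -> network stats -> MCL modules, with optional GO
#' enrichment, cross-species conservation, and module expression profiles
#' when their inputs are supplied. Every output is a deterministic function
#' of (inputs, config, seed). If `output_dir` is given, the edge list,
#' module table, network stats and a run manifest are written there as
#' plain-text files.
#'
#' @param expression an `ExpressionMatrix` on the FPKM scale, or a path to
#'   an expression TSV.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for artifacts.
#' @param annotations optional data.frame(gene, term) to run per-module GO
#'   enrichment.
#' @param partner_network,homolog_map optional second network and homolog
#'   table to run conservation scoring.
#' @param groups optional data.frame(sample_id, group_label, group_order)
#'   to compute module expression profiles.
#' @return list with `network`, `modules`, `stats`, `assoc`, `pcc`,
#'   optional `enrichment`, `conservation`, `profile`, and `manifest` (the
#'   config plus all bookkeeping counts).
#' @export
run_pipeline <- function(expression, config = pipeline_config(),
                         output_dir = NULL, annotations = NULL,
                         partner_network = NULL, homolog_map = NULL,
                         groups = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  m <- run_stage("read_expression", {
    if (is.character(expression)) read_expression_matrix(expression)
    else if (inherits(expression, "ExpressionMatrix")) expression
    else stop("expression must be an ExpressionMatrix or a TSV path")
  })
  genes_in <- nrow(expr_values(m))
  kept <- run_stage("filter_low_expression",
                    filter_low_expression(m, config$min_max_fpkm))
  logm <- run_stage("log_transform", log_transform(kept))
  assoc <- run_stage("pcor_estimation", {
    plan <- sampling_plan(config$n_iterations, config$subset_size,
                          seed = derive_seed(config$seed, "pcor_sampling"))
    sampled_pcor_estimation(logm, plan)
  })
  pcc <- run_stage("pearson_correlation", pearson_correlation(logm))
  network <- run_stage("edge_selection",
                       select_edges(assoc, pcc, config$pcor_threshold,
                                    config$pcc_threshold))
  stats <- run_stage("network_stats", network_stats(network))
  modules <- run_stage("mcl_clustering",
                       mcl_cluster(network, mcl_params(
                         inflation = config$inflation,
                         min_module_size = config$min_module_size)))

  enrichment <- NULL
  if (!is.null(annotations))
    enrichment <- run_stage("go_enrichment", {
      ids <- as.integer(names(modules$module_sizes))
      res <- lapply(ids, function(id) {
        mg <- names(modules$membership)[modules$membership == id]
        r <- go_enrichment(mg, network$nodes, annotations)
        if (nrow(r)) cbind(module_id = id, r) else NULL
      })
      do.call(rbind, res)
    })
  conservation <- NULL
  if (!is.null(partner_network) && !is.null(homolog_map))
    conservation <- run_stage("conservation", {
      flags <- conserved_interactions(network, partner_network, homolog_map)
      module_conservation(flags, modules)
    })
  profile <- NULL
  if (!is.null(groups))
    profile <- run_stage("module_profiles",
                         module_mean_expression(logm, modules, groups))

  manifest <- list(
    config = unclass(config),
    counts = list(
      genes_in = genes_in,
      genes_kept = nrow(expr_values(kept)),
      pair_coverage = assoc$coverage,
      n_network_genes = length(network$nodes),
      n_edges = nrow(network$edges),
      n_positive = attr(network, "n_positive"),
      n_negative = attr(network, "n_negative"),
      n_modules = length(modules$module_sizes),
      n_retained_module_genes = length(modules$membership),
      n_small_module_genes = length(modules$small_module_genes),
      clustering_coefficient = stats$clustering_coefficient,
      random_expected_c = stats$random_expected_c))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_network(network, file.path(output_dir, "edges.tsv"))
    write_modules(modules, file.path(output_dir, "modules.tsv"))
    yaml::write_yaml(stats, file.path(output_dir, "network_stats.yml"))
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yml"))
    if (!is.null(enrichment))
      data.table::fwrite(enrichment, file.path(output_dir, "go_enrichment.tsv"),
                         sep = "\t")
    if (!is.null(conservation))
      data.table::fwrite(conservation$per_module,
                         file.path(output_dir, "module_conservation.tsv"),
                         sep = "\t")
    if (!is.null(profile))
      write_module_profile(profile, file.path(output_dir, "module_profiles.tsv"))
  }

  list(network = network, modules = modules, stats = stats, assoc = assoc,
       pcc = pcc, enrichment = enrichment, conservation = conservation,
       profile = profile, manifest = manifest)
}
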