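#' Run the full analysis pipeline on a dataset
#'
#' Wires the stages in dependency order: (optional) protein clustering and
#' small-cluster filtering, membership matrix and network projection, MCL
#' inflation sweep with ICCC selection on the gene network, host profiles and
#' topology-versus-host-distance regressions, chi construction at boosted
#' granularity, mimax, and leave-one-out host prediction. Artifacts (edge
#' lists, TSV tables) and a manifest recording parameters, seeds, and
#' per-stage sizes are written under `out_dir`; a rerun with the same config
#' reproduces them.
#'
#' @param dataset a `phage_dataset` or `phage_sim` (must carry cluster
#'   assignments unless sequences are present).
#' @param host_tree a genus-level `host_tree`; defaults to the tree carried by
#'   a `phage_sim`.
#' @param out_dir output directory; `NULL` skips file output.
#' @param identity_threshold clustering identity threshold (used only when
#'   the dataset has no cluster assignments); default 0.35.
#' @param min_cluster_size small-cluster filter; default 3.
#' @param inflation_grid MCL inflation sweep grid; default `seq(1.4, 6, 0.4)`.
#' @param mimax_inflation inflation for the granularity-boosted clustering
#'   fed to mimax; default 15.
#' @param edges_per_node random edges per node before the boosted MCL;
#'   default 5.
#' @param seed global seed; stage seeds are derived from it.
#' @return list with the intermediate objects (`clusters`, `P`, `networks`,
#'   `sweep`, `mcl_gene`, `profiles`, `topology`, `regression`, `chi`,
#'   `mimax`, `predictions`, `accuracy`) and `manifest`.
#' @export
run_pipeline <- function(dataset, host_tree = NULL, out_dir = NULL,
                         identity_threshold = 0.35, min_cluster_size = 3L,
                         inflation_grid = seq(1.4, 6, by = 0.4),
                         mimax_inflation = 15, edges_per_node = 5L,
                         seed = 1L) {
  host_tree <- host_tree %||% dataset$host_tree
  if (is.null(host_tree)) stop("host_tree required", call. = FALSE)
  genes <- dataset$genes
  genomes <- dataset$genomes
  manifest <- list(parameters = list(
    identity_threshold = identity_threshold,
    min_cluster_size = min_cluster_size,
    inflation_grid = inflation_grid,
    mimax_inflation = mimax_inflation,
    edges_per_node = edges_per_node,
    seed = seed
  ), stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  clusters <- if (!is.null(dataset$clusters)) {
    dataset$clusters
  } else if (!is.null(genes$cluster_id) && !anyNA(genes$cluster_id)) {
    as_gene_clusters(genes[, c("gene_id", "cluster_id")])
  } else {
    cluster_proteins(genes, identity_threshold)
  }
  filt <- filter_clusters(clusters, min_cluster_size, genes)
  clusters <- filt$clusters
  note("cluster", n_clusters = length(clusters$centroids),
       excluded_genomes = filt$excluded_genomes)

  genes_kept <- genes[genes$genome_id %in%
                        unique(genes$genome_id[genes$gene_id %in%
                                                 clusters$assignments$gene_id]), ,
                      drop = FALSE]
  P <- build_membership(genes_kept, clusters)
  networks <- project_networks(P)
  note("build", n_genomes = nrow(P), n_gene_clusters = ncol(P),
       genome_edges = igraph::ecount(networks$genome),
       gene_edges = igraph::ecount(networks$gene))

  sweep <- sweep_inflation(networks$gene, inflation_grid)
  best_infl <- attr(sweep, "recommended_inflation")
  mcl_gene <- mcl_cluster(networks$gene, mcl_params(inflation = best_infl))
  note("mcl", recommended_inflation = best_infl,
       n_clusters = mcl_gene$n_clusters)

  profiles <- host_profiles(P, genomes)
  topology <- pairwise_topology(networks$gene, P, genomes, host_tree)
  regression <- host_distance_regression(topology)
  note("hosts", n_pairs = nrow(topology),
       similarity_slope = regression$similarity$slope,
       path_slope = regression$shortest_path$slope)

  boosted <- granularity_boost(networks$gene, inflation = mimax_inflation,
                               edges_per_node = edges_per_node,
                               seed = seed + 1L)
  chi <- build_chi(boosted, profiles$cluster)
  mx <- mimax_search(chi, P, seed = seed + 2L)
  note("mimax", n_chi_rows = nrow(chi$counts),
       n_retained = length(mx$retained_rows),
       mi_initial = mx$initial_mi, mi_final = mx$current_mi)

  retained <- retained_gene_clusters(mx, chi)
  predictions <- predict_hosts(P, profiles$cluster, genomes, host_tree,
                               retained_clusters = retained)
  accuracy <- accuracy_report(predictions)
  note("predict", n_scored = attr(accuracy, "n_scored"),
       overall_accuracy = attr(accuracy, "overall_accuracy"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_network(networks$genome, file.path(out_dir, "genome.edges"))
    export_network(networks$gene, file.path(out_dir, "gene.edges"))
    utils::write.table(sweep, file.path(out_dir, "inflation_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(topology, file.path(out_dir, "pairstats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(manifest$parameters, cfg_path)
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  list(clusters = clusters, P = P, networks = networks, sweep = sweep,
       mcl_gene = mcl_gene, profiles = profiles, topology = topology,
       regression = regression, chi = chi, mimax = mx,
       predictions = predictions, accuracy = accuracy, manifest = manifest)
}
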