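#' Build the binary genome-by-gene-cluster membership matrix
#'
#' The membership (presence/absence) matrix `P` has one row per genome and one
#' column per retained gene cluster; entry `{i,j}` is 1 iff genome `i`
#' contains at least one gene of cluster `j` (paralogs collapse to 1). `P` is
#' the adjacency matrix of the bipartite genome-gene network and the pivot of
#' the whole pipeline: both co-occurrence networks are sign-thresholded
#' products of `P` with its transpose ([project_networks()]).
#'
#' @param genes data frame with columns `gene_id`, `genome_id`.
#' @param clusters a filtered `gene_clusters` object (see [filter_clusters()]).
#' @return binary integer matrix with genome ids as row names and cluster ids
#'   as column names. Errors if any supplied genome would have an all-zero
#'   row: such genomes must be excluded upstream.
#' @export
build_membership <- function(genes, clusters) {
  asg <- clusters$assignments
  genomes <- unique(genes$genome_id)
  cl_ids <- sort(unique(asg$cluster_id))
  if (length(cl_ids) == 0L) stop("no clusters to build from", call. = FALSE)
  m <- genes[genes$gene_id %in% asg$gene_id, c("gene_id", "genome_id")]
  m$cluster_id <- asg$cluster_id[match(m$gene_id, asg$gene_id)]
  P <- matrix(0L, length(genomes), length(cl_ids),
              dimnames = list(genomes, cl_ids))
  P[cbind(match(m$genome_id, genomes), match(m$cluster_id, cl_ids))] <- 1L
  empty <- rownames(P)[rowSums(P) == 0L]
  if (length(empty)) {
    stop("genome(s) with no retained clusters (exclude upstream): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  P
}

#' Project the membership matrix into genome- and gene-level networks
#'
#' The genome network is `sign(P %*% t(P))` with the diagonal zeroed: two
#' genomes are adjacent iff they share at least one gene cluster. The gene
#' network is `sign(t(P) %*% P)` likewise: two clusters are adjacent iff some
#' genome contains both. Both are simple unweighted undirected graphs.
#'
#' @param P binary membership matrix from [build_membership()].
#' @return list with igraph graphs `genome` and `gene`.
#' @export
project_networks <- function(P) {
  stopifnot(is.matrix(P), all(P %in% c(0L, 1L)))
  a_genome <- sign(P %*% t(P))
  a_gene <- sign(t(P) %*% P)
  diag(a_genome) <- 0
  diag(a_gene) <- 0
  list(
    genome = igraph::graph_from_adjacency_matrix(a_genome,
                                                 mode = "undirected"),
    gene = igraph::graph_from_adjacency_matrix(a_gene, mode = "undirected")
  )
}

#' Add random edges to a network
#'
#' For each node in turn, up to `edges_per_node` new edges are drawn to
#' uniformly sampled distinct current non-neighbors (self-loops and duplicate
#' edges never created; pairs proposed from both endpoints collapse to one
#' edge because sampling sees the updated graph). Artificial edges create
#' distinctions between nodes with near-identical neighborhoods and so
#' increase the number of clusters MCL can resolve; used by
#' [granularity_boost()]. Deterministic for a fixed seed.
#'
#' @param network igraph undirected graph with named vertices.
#' @param edges_per_node nonnegative integer; 0 returns the network unchanged.
#' @param seed integer seed for the sampling stream.
#' @return the augmented igraph graph, with attribute `edges_added` recording
#'   the realized number of new edges.
#' @export
augment_edges <- function(network, edges_per_node, seed = 1L) {
  stopifnot(edges_per_node >= 0)
  if (edges_per_node == 0L) return(network)
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  adj <- lapply(igraph::as_adj_list(network), function(v) v$name)
  names(adj) <- nodes
  added <- 0L
  new_edges <- character()
  with_seed(seed, {
    for (v in nodes) {
      candidates <- setdiff(nodes, c(v, adj[[v]]))
      k <- min(edges_per_node, length(candidates))
      if (k < edges_per_node) {
        message("node ", v, ": only ", k, " non-neighbors available")
      }
      if (k > 0L) {
        picks <- sample(candidates, k)
        for (u in picks) {
          adj[[v]] <- c(adj[[v]], u)
          adj[[u]] <- c(adj[[u]], v)
        }
        new_edges <- c(new_edges, as.vector(rbind(v, picks)))
        added <- added + k
      }
    }
  })
  out <- network
  if (length(new_edges)) out <- igraph::add_edges(out, new_edges)
  out <- igraph::simplify(out)
  igraph::graph_attr(out, "edges_added") <- added
  out
}
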