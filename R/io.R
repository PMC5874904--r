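#' Load a phage dataset from protein FASTA files or a cluster map
#'
#' Assembles the core dataset: one record per genome (with its host genus, or
#' unknown) and one record per protein-coding gene. Genes are attached to
#' exactly one genome. Input is either a set of per-genome protein FASTA files
#' or, when clustering has been done upstream, a gene-to-cluster map whose gene
#' identifiers encode the source genome as `"<genome_id>|<ordinal>"`.
#'
#' Genomes whose host genus is absent from the metadata are retained with an
#' unknown host: they participate in network construction but are excluded
#' from host-linked analyses (profiles, MPD, mutual information, prediction
#' scoring).
#'
#' @param fasta_paths character vector of protein FASTA files, one per genome;
#'   the genome id is the file name without extension.
#' @param cluster_map optional path to a gene-to-cluster TSV (columns
#'   `gene_id`, `cluster_id`) or USEARCH UC file; see [read_cluster_map()].
#' @param host_metadata path to a TSV with columns `genome_id`, `host_genus`.
#' @return an object of class `phage_dataset`: a list with data frames
#'   `genomes` (`genome_id`, `host_genus`; `NA` = unknown) and `genes`
#'   (`gene_id`, `genome_id`, `sequence`, and `cluster_id` when a map was
#'   given).
#' @export
load_dataset <- function(fasta_paths = NULL, cluster_map = NULL,
                         host_metadata = NULL) {
  if (is.null(fasta_paths) && is.null(cluster_map)) {
    stop("provide fasta_paths and/or cluster_map", call. = FALSE)
  }
  genes <- NULL
  if (!is.null(fasta_paths)) {
    missing <- fasta_paths[!file.exists(fasta_paths)]
    if (length(missing)) {
      stop("FASTA file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    genome_ids <- sub("\\.[^.]*$", "", basename(fasta_paths))
    if (anyDuplicated(genome_ids)) {
      stop("duplicate genome_id: ",
           paste(unique(genome_ids[duplicated(genome_ids)]), collapse = ", "),
           call. = FALSE)
    }
    per_genome <- lapply(seq_along(fasta_paths), function(i) {
      aa <- Biostrings::readAAStringSet(fasta_paths[i])
      if (length(aa) == 0L) {
        stop("genome ", genome_ids[i], " has no genes", call. = FALSE)
      }
      hdr <- sub("\\s.*$", "", names(aa))
      data.frame(
        gene_id   = hdr,
        genome_id = genome_ids[i],
        sequence  = toupper(as.character(aa)),
        stringsAsFactors = FALSE
      )
    })
    genes <- do.call(rbind, per_genome)
    # FASTA headers are only unique within a file; namespace on collision.
    if (anyDuplicated(genes$gene_id)) {
      ord <- stats::ave(seq_len(nrow(genes)), genes$genome_id, FUN = seq_along)
      genes$gene_id <- paste0(genes$genome_id, "|", ord)
    }
    assert_aa(genes$sequence, genes$gene_id)
  }

  map <- NULL
  if (!is.null(cluster_map)) {
    map <- read_cluster_map(cluster_map)
    if (is.null(genes)) {
      genome_id <- sub("\\|[^|]*$", "", map$gene_id)
      if (any(genome_id == map$gene_id)) {
        stop("cluster-map gene ids must encode the genome as ",
             "\"<genome_id>|<ordinal>\" when no FASTA is given", call. = FALSE)
      }
      genes <- data.frame(gene_id = map$gene_id, genome_id = genome_id,
                          sequence = NA_character_, stringsAsFactors = FALSE)
    } else {
      absent <- setdiff(map$gene_id, genes$gene_id)
      if (length(absent)) {
        stop("cluster map references gene id(s) absent from input: ",
             paste(absent, collapse = ", "), call. = FALSE)
      }
    }
    genes$cluster_id <- map$cluster_id[match(genes$gene_id, map$gene_id)]
  }

  genomes <- data.frame(genome_id = unique(genes$genome_id),
                        stringsAsFactors = FALSE)
  genomes$host_genus <- NA_character_
  if (!is.null(host_metadata)) {
    meta <- utils::read.delim(host_metadata, stringsAsFactors = FALSE)
    if (!all(c("genome_id", "host_genus") %in% names(meta))) {
      stop("host metadata needs columns genome_id and host_genus",
           call. = FALSE)
    }
    if (anyDuplicated(meta$genome_id)) {
      stop("duplicate genome_id in host metadata: ",
           paste(unique(meta$genome_id[duplicated(meta$genome_id)]),
                 collapse = ", "), call. = FALSE)
    }
    genomes$host_genus <-
      normalize_genus(meta$host_genus[match(genomes$genome_id,
                                            meta$genome_id)])
  }
  structure(list(genomes = genomes, genes = genes), class = "phage_dataset")
}

#' @export
print.phage_dataset <- function(x, ...) {
  n_known <- sum(!is.na(x$genomes$host_genus))
  cat("phage_dataset:", nrow(x$genomes), "genomes (", n_known,
      "with known host ),", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Read a gene-to-cluster assignment map
#'
#' Accepts either a two-column TSV (`gene_id`, `cluster_id`, with header) or a
#' USEARCH UC file (detected by `S`/`H`/`C` record types in the first column).
#' UC cluster numbers become cluster ids `"C<number>"`.
#'
#' @param path file path.
#' @return data frame with columns `gene_id`, `cluster_id`.
#' @export
read_cluster_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(fields) >= 9 && fields[1] %in% c("S", "H", "C", "N")) {
    uc <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    rec <- uc[uc[[1]] %in% c("S", "H"), , drop = FALSE]
    # query label is column 9; strip FASTA description if present
    gene_id <- sub("\\s.*$", "", rec[[9]])
    data.frame(gene_id = gene_id,
               cluster_id = paste0("C", rec[[2]]),
               stringsAsFactors = FALSE)
  } else {
    map <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "cluster_id") %in% names(map))) {
      stop("cluster map needs columns gene_id and cluster_id", call. = FALSE)
    }
    map[, c("gene_id", "cluster_id")]
  }
}

#' Read a host phylogeny with branch lengths
#'
#' Reads a newick tree, requires branch lengths on every edge, midpoint-roots
#' unrooted input (with a message), and precomputes the cophenetic (patristic)
#' distance matrix over the leaves.
#'
#' @param path newick file.
#' @return object of class `host_tree`: list with `tree` (an [ape::phylo]) and
#'   `dist` (symmetric cophenetic matrix over leaf labels).
#' @export
read_host_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick: ", path, call. = FALSE)
  host_tree(tree)
}

#' Construct a `host_tree` from an [ape::phylo] object
#'
#' @param tree a phylo object with complete branch lengths.
#' @return a `host_tree` (see [read_host_tree()]).
#' @export
host_tree <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("host tree must have branch lengths on all edges", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    message("unrooted input tree: rooting at midpoint")
    tree <- phangorn::midpoint(tree)
  }
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label, drop = FALSE]
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    warning("zero cophenetic distance between distinct leaves ",
            "(zero-length terminal branches)", call. = FALSE)
  }
  structure(list(tree = tree, dist = d), class = "host_tree")
}

#' @export
print.host_tree <- function(x, ...) {
  cat("host_tree:", length(x$tree$tip.label), "leaves, max pairwise distance",
      format(max(x$dist)), "\n")
  invisible(x)
}

#' Export a network as an edge list or SIF file
#'
#' Writes one line per undirected edge with endpoints in lexicographic order,
#' plus a `<path>.nodes` sidecar listing every node (so isolated nodes survive
#' a round trip). `edge_tsv` lines are `node<TAB>node`; `sif` lines are
#' `node<TAB>co<TAB>node`.
#'
#' @param network an igraph undirected graph with named vertices.
#' @param path output file.
#' @param format `"edge_tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("edge_tsv", "sif")) {
  format <- match.arg(format)
  if (igraph::vcount(network) == 0L) stop("empty network", call. = FALSE)
  el <- igraph::as_edgelist(network)
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  lines <- if (format == "edge_tsv") {
    paste(el[, 1], el[, 2], sep = "\t")
  } else {
    paste(el[, 1], "co", el[, 2], sep = "\t")
  }
  writeLines(lines, path)
  writeLines(sort(igraph::V(network)$name), paste0(path, ".nodes"))
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path edge-list or SIF file; a `<path>.nodes` sidecar, if present,
#'   supplies the full node set (including isolated nodes).
#' @return an igraph undirected graph.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  edges <- NULL
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- t(vapply(parts, function(p) {
      if (length(p) == 3L) p[c(1, 3)] else p[1:2]
    }, character(2)))
  }
  nodes_file <- paste0(path, ".nodes")
  nodes <- if (file.exists(nodes_file)) readLines(nodes_file) else character()
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  igraph::simplify(g)
}
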