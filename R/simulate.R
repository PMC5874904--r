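#' Configuration for the synthetic phage dataset generator
#'
#' The generator emulates the statistical structure the network analyses
#' rely on: a genus-level host tree; one pool of gene clusters per host
#' genus; mosaic phage genomes drawing mostly from their own host's pool,
#' with a tunable horizontal-transfer rate pulling genes from foreign pools
#' weighted by phylogenetic proximity (`exp(-d / phylo_decay)`); and rare
#' singleton genes to exercise the small-cluster filter.
#'
#' Defaults describe a moderately sampled community: 8 host genera on a
#' balanced unit-branch-length tree, 10 genomes per host, 30 genes per
#' genome drawn from per-host pools of 60 clusters, a 10% HGT rate with
#' decay constant 2 (so the nearest foreign genus is favored about 7:1 over
#' the most distant), and a 5% singleton rate.
#'
#' @param n_hosts number of host genera (>= 2).
#' @param tree_shape `"balanced"` (unit branch lengths; `n_hosts` a power of
#'   2) or `"coalescent"` (random coalescent, seeded).
#' @param n_genomes_per_host genomes simulated per host genus.
#' @param genes_per_genome gene clusters drawn per genome (distinct).
#' @param pool_size_per_host clusters in each host's pool.
#' @param hgt_rate probability a gene is drawn from a foreign host pool.
#' @param phylo_decay decay constant of the foreign-pool weighting, in units
#'   of tree distance (> 0).
#' @param singleton_rate expected fraction of extra genome-private genes.
#' @param seed integer seed; a fixed seed yields a bit-identical dataset.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_hosts = 8L,
                              tree_shape = c("balanced", "coalescent"),
                              n_genomes_per_host = 10L,
                              genes_per_genome = 30L,
                              pool_size_per_host = 60L,
                              hgt_rate = 0.1,
                              phylo_decay = 2,
                              singleton_rate = 0.05,
                              seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_hosts >= 2L, n_genomes_per_host >= 1L, genes_per_genome >= 1L,
            pool_size_per_host >= 1L, hgt_rate >= 0, hgt_rate <= 1,
            phylo_decay > 0, singleton_rate >= 0, singleton_rate <= 1)
  if (genes_per_genome > pool_size_per_host) {
    stop("genes_per_genome exceeds pool_size_per_host: infeasible",
         call. = FALSE)
  }
  structure(list(n_hosts = as.integer(n_hosts), tree_shape = tree_shape,
                 n_genomes_per_host = as.integer(n_genomes_per_host),
                 genes_per_genome = as.integer(genes_per_genome),
                 pool_size_per_host = as.integer(pool_size_per_host),
                 hgt_rate = hgt_rate, phylo_decay = phylo_decay,
                 singleton_rate = singleton_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a host-structured phage dataset
#'
#' Generates a genus-level host tree, per-host gene-cluster pools, and mosaic
#' genomes: each of a genome's gene slots draws from its own host's pool with
#' probability `1 - hgt_rate`, otherwise from a foreign host's pool chosen
#' with probability proportional to `exp(-d / phylo_decay)` (d = tree
#' distance), then uniformly within the pool; duplicate draws are discarded
#' so each genome carries distinct clusters. Extra genome-private singleton
#' clusters are injected at `singleton_rate` per gene slot. Optional
#' sequences place each cluster around a random ancestor protein with 10%
#' per-site substitutions per gene, so the built-in clusterer recovers the
#' ground truth at the default 35% identity threshold.
#'
#' @param config a [simulation_config()].
#' @param with_sequences also generate amino-acid sequences (slower; only
#'   needed to exercise the clustering module).
#' @param ancestor_length protein length used when generating sequences.
#' @param mutation_rate per-site substitution probability per gene.
#' @return list of class `phage_sim` with elements `genomes` (data frame
#'   `genome_id`, `host_genus`), `genes` (data frame `gene_id`, `genome_id`,
#'   `cluster_id`, `sequence`), `clusters` (ground-truth `gene_clusters`),
#'   `host_tree` (a `host_tree`), and `config`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             with_sequences = FALSE,
                             ancestor_length = 120L,
                             mutation_rate = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    hosts <- sprintf("Genus%02d", seq_len(config$n_hosts))
    tree <- if (config$tree_shape == "balanced") {
      if (log2(config$n_hosts) %% 1 != 0) {
        stop("balanced tree needs n_hosts to be a power of 2", call. = FALSE)
      }
      t <- ape::stree(config$n_hosts, type = "balanced")
      t$edge.length <- rep(1, nrow(t$edge))
      t
    } else {
      ape::rcoal(config$n_hosts)
    }
    tree$tip.label <- hosts
    htree <- host_tree(tree)
    d <- htree$dist

    pools <- lapply(hosts, function(h) {
      sprintf("%s_c%03d", tolower(h), seq_len(config$pool_size_per_host))
    })
    names(pools) <- hosts

    genome_ids <- character()
    genome_hosts <- character()
    gene_rows <- vector("list", config$n_hosts * config$n_genomes_per_host)
    gi <- 0L
    for (h in hosts) {
      foreign <- setdiff(hosts, h)
      w <- exp(-d[h, foreign] / config$phylo_decay)
      w <- w / sum(w)
      for (g in seq_len(config$n_genomes_per_host)) {
        gi <- gi + 1L
        gid <- sprintf("%s_p%02d", tolower(h), g)
        genome_ids <- c(genome_ids, gid)
        genome_hosts <- c(genome_hosts, h)
        picked <- character()
        guard <- 0L
        while (length(picked) < config$genes_per_genome &&
                 guard < 50L * config$genes_per_genome) {
          guard <- guard + 1L
          src <- if (stats::runif(1) < config$hgt_rate) {
            sample(foreign, 1, prob = w)
          } else h
          cand <- sample(pools[[src]], 1)
          if (!cand %in% picked) picked <- c(picked, cand)
        }
        n_single <- stats::rbinom(1, config$genes_per_genome,
                                  config$singleton_rate)
        if (n_single > 0L) {
          picked <- c(picked,
                      sprintf("%s_s%02d", gid, seq_len(n_single)))
        }
        gene_rows[[gi]] <- data.frame(
          gene_id = sprintf("%s|%d", gid, seq_along(picked)),
          genome_id = gid,
          cluster_id = picked,
          stringsAsFactors = FALSE
        )
      }
    }
    genes <- do.call(rbind, gene_rows)
    genes$sequence <- NA_character_
    if (with_sequences) {
      ab <- setdiff(aa_alphabet(), "X")
      cl_ids <- unique(genes$cluster_id)
      ancestors <- vapply(cl_ids, function(cl) {
        paste(sample(ab, ancestor_length, replace = TRUE), collapse = "")
      }, character(1))
      names(ancestors) <- cl_ids
      genes$sequence <- vapply(seq_len(nrow(genes)), function(i) {
        s <- strsplit(ancestors[[genes$cluster_id[i]]], "")[[1]]
        mut <- stats::runif(length(s)) < mutation_rate
        if (any(mut)) {
          s[mut] <- vapply(s[mut], function(old) {
            sample(setdiff(ab, old), 1)
          }, character(1))
        }
        paste(s, collapse = "")
      }, character(1))
    }
    genomes <- data.frame(genome_id = genome_ids, host_genus = genome_hosts,
                          stringsAsFactors = FALSE)
    clusters <- as_gene_clusters(genes[, c("gene_id", "cluster_id")])
    structure(list(genomes = genomes, genes = genes, clusters = clusters,
                   host_tree = htree, config = config),
              class = "phage_sim")
  })
}

#' @export
print.phage_sim <- function(x, ...) {
  cat("phage_sim:", nrow(x$genomes), "genomes,", nrow(x$genes), "genes,",
      length(unique(x$genes$cluster_id)), "gene clusters,",
      x$config$n_hosts, "host genera (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Permute host labels (null model)
#'
#' Uniformly permutes the host-genus column of the genome table, preserving
#' the marginal host frequencies. Used as the null model for mutual
#' information and regression checks.
#'
#' @param genomes data frame with `genome_id`, `host_genus`.
#' @param seed integer seed.
#' @return the data frame with `host_genus` permuted.
#' @export
permute_labels <- function(genomes, seed = 1L) {
  with_seed(seed, {
    genomes$host_genus <- sample(genomes$host_genus)
  })
  genomes
}

#' Write a simulated dataset to the on-disk formats the readers accept
#'
#' Emits per-genome protein FASTA files (when sequences were generated), the
#' host metadata TSV, the gene-to-cluster map TSV, and the host tree in
#' newick, so a round trip through [load_dataset()] / [read_host_tree()] is
#' possible.
#'
#' @param sim a `phage_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sim$genomes, file.path(dir, "hosts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes[, c("gene_id", "cluster_id")],
                     file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$host_tree$tree, file.path(dir, "host_tree.nwk"))
  if (!anyNA(sim$genes$sequence)) {
    fasta_dir <- file.path(dir, "proteomes")
    dir.create(fasta_dir, showWarnings = FALSE)
    for (g in sim$genomes$genome_id) {
      rows <- sim$genes[sim$genes$genome_id == g, , drop = FALSE]
      aa <- Biostrings::AAStringSet(rows$sequence)
      names(aa) <- rows$gene_id
      Biostrings::writeXStringSet(aa, file.path(fasta_dir,
                                                paste0(g, ".faa")))
    }
  }
  invisible(dir)
}
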