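#' Global pairwise amino-acid identity
#'
#' Needleman-Wunsch global alignment with fixed scoring (match +1, mismatch
#' -1, gap open 5, gap extend 1, both as costs) followed by
#' `identity = matched columns / alignment columns`, where columns made of a
#' terminal gap in either sequence are excluded from the denominator. This is
#' the identity definition used by greedy centroid clustering
#' ([cluster_proteins()]); it is symmetric in its arguments.
#'
#' @param a,b nonempty amino-acid strings (20 standard residues plus X).
#' @return fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  assert_aa(c(a, b), c("a", "b"))
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = .identity_submat(),
    gapOpening = 5, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- pa == "-" | ps == "-"
  n <- length(pa)
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- seq.int(lead + 1L, n - trail)
  denom <- length(keep)
  if (denom == 0L) return(0)
  sum(pa[keep] == ps[keep] & pa[keep] != "-") / denom
}

.identity_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ab <- aa_alphabet()
      m <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
      diag(m) <- 1
      cache <<- m
    }
    cache
  }
})

#' Greedy centroid clustering of protein sequences
#'
#' A deterministic stand-in for length-sorted greedy centroid clustering (the
#' UCLUST/`cluster_fast` scheme): genes are processed in order of decreasing
#' sequence length (ties broken by gene id); each gene joins the first
#' existing centroid whose [pairwise_identity()] to it is at least
#' `identity_threshold`, otherwise it founds a new cluster with itself as
#' centroid. Intended for synthetic and desk-scale data, not for
#' corpus-scale clustering.
#'
#' @param genes data frame with columns `gene_id` and `sequence`.
#' @param identity_threshold fraction in (0, 1); default 0.35.
#' @return object of class `gene_clusters`: list with `assignments`
#'   (data frame `gene_id`, `cluster_id`), `centroids` (named character,
#'   cluster id -> centroid gene id), and `identity_threshold`.
#' @export
cluster_proteins <- function(genes, identity_threshold = 0.35) {
  stopifnot(identity_threshold > 0, identity_threshold < 1)
  if (is.null(genes) || nrow(genes) == 0L) {
    return(structure(list(assignments = data.frame(gene_id = character(),
                                                   cluster_id = character()),
                          centroids = character(),
                          identity_threshold = identity_threshold),
                     class = "gene_clusters"))
  }
  if (anyNA(genes$sequence)) {
    stop("all genes must carry sequences for clustering", call. = FALSE)
  }
  seqs <- toupper(genes$sequence)
  assert_aa(seqs, genes$gene_id)
  ord <- order(-nchar(seqs), genes$gene_id)
  ids <- genes$gene_id[ord]
  seqs <- seqs[ord]

  centroid_seq <- character()
  centroid_id <- character()
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(centroid_seq)) {
      if (pairwise_identity(seqs[i], centroid_seq[k]) >= identity_threshold) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroid_seq <- c(centroid_seq, seqs[i])
      centroid_id <- c(centroid_id, ids[i])
      assignment[i] <- length(centroid_seq)
    }
  }
  width <- max(3L, nchar(as.character(length(centroid_id))))
  cl_ids <- sprintf(paste0("C%0", width, "d"), seq_along(centroid_id))
  structure(list(
    assignments = data.frame(gene_id = ids,
                             cluster_id = cl_ids[assignment],
                             stringsAsFactors = FALSE),
    centroids = stats::setNames(centroid_id, cl_ids),
    identity_threshold = identity_threshold
  ), class = "gene_clusters")
}

#' Make a `gene_clusters` object from a plain assignment table
#'
#' Wraps an externally produced gene-to-cluster map (e.g. read with
#' [read_cluster_map()]) in the structure [cluster_proteins()] returns, so
#' precomputed clusterings can bypass the built-in clusterer.
#'
#' @param assignments data frame with columns `gene_id`, `cluster_id`.
#' @param identity_threshold the threshold the external tool used, if known.
#' @return a `gene_clusters` object (centroids unknown, `NA`).
#' @export
as_gene_clusters <- function(assignments, identity_threshold = NA_real_) {
  stopifnot(all(c("gene_id", "cluster_id") %in% names(assignments)))
  if (anyDuplicated(assignments$gene_id)) {
    stop("a gene may belong to only one cluster", call. = FALSE)
  }
  cl <- unique(assignments$cluster_id)
  structure(list(
    assignments = assignments[, c("gene_id", "cluster_id")],
    centroids = stats::setNames(rep(NA_character_, length(cl)), cl),
    identity_threshold = identity_threshold
  ), class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  sizes <- table(x$assignments$cluster_id)
  cat("gene_clusters:", length(sizes), "clusters over",
      nrow(x$assignments), "genes;",
      sum(sizes == 1L), "singletons\n")
  invisible(x)
}

#' Drop small gene clusters and report genomes lost
#'
#' Clusters with fewer than `min_size` member genes are removed (the
#' singleton/doubleton filter used before network construction). When the
#' gene-to-genome mapping is supplied, genomes whose every gene fell in a
#' dropped cluster are reported: such genomes cannot appear in the membership
#' matrix and are excluded from all downstream analyses.
#'
#' @param clusters a `gene_clusters` object.
#' @param min_size minimum member count to retain; default 3.
#' @param genes optional data frame with columns `gene_id`, `genome_id`, used
#'   to compute the excluded-genome report.
#' @return list with `clusters` (filtered `gene_clusters`) and
#'   `excluded_genomes` (character vector; empty when `genes` is missing or
#'   nothing was lost).
#' @export
filter_clusters <- function(clusters, min_size = 3L, genes = NULL) {
  stopifnot(min_size >= 1L)
  sizes <- table(clusters$assignments$cluster_id)
  keep <- names(sizes)[sizes >= min_size]
  kept <- clusters$assignments[clusters$assignments$cluster_id %in% keep, ,
                               drop = FALSE]
  out <- structure(list(
    assignments = kept,
    centroids = clusters$centroids[names(clusters$centroids) %in% keep],
    identity_threshold = clusters$identity_threshold
  ), class = "gene_clusters")
  excluded <- character()
  if (!is.null(genes)) {
    assigned <- genes[genes$gene_id %in% clusters$assignments$gene_id, ,
                      drop = FALSE]
    before <- unique(assigned$genome_id)
    after <- unique(genes$genome_id[genes$gene_id %in% kept$gene_id])
    excluded <- setdiff(before, after)
  }
  list(clusters = out, excluded_genomes = excluded)
}
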