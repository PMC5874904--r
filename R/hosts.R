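#' Collapse a strain-level host tree to the genus level
#'
#' Each genus is represented by a single leaf placed at the most recent common
#' ancestor (MRCA) of its strains; the cophenetic distance between two genera
#' is the path length between their MRCAs. A genus whose strains are not
#' monophyletic is still collapsed at the MRCA, with a warning naming the
#' intruding taxa. The genus map may merge taxa (mapping a strain into another
#' genus) and `drop` removes misplaced leaves before collapsing.
#'
#' @param tree a `host_tree` (see [read_host_tree()]).
#' @param genus_map named character vector mapping every leaf label to its
#'   genus; leaves absent from the map are an error.
#' @param drop leaf labels to remove before collapsing.
#' @return a genus-level `host_tree`. Its `dist` matrix is computed exactly
#'   from MRCA depths; the `tree` slot holds one representative tip per genus
#'   with its terminal branch rescaled to sit at the MRCA (exact for
#'   monophyletic genera).
#' @export
collapse_to_genus <- function(tree, genus_map, drop = character()) {
  phy <- tree$tree
  if (length(drop)) {
    phy <- ape::drop.tip(phy, intersect(drop, phy$tip.label))
  }
  tips <- phy$tip.label
  unmapped <- setdiff(tips, names(genus_map))
  if (length(unmapped)) {
    stop("leaves missing from genus map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  genus <- genus_map[tips]
  genera <- sort(unique(unname(genus)))
  ntip <- length(tips)
  depth <- ape::node.depth.edgelength(phy)  # root-to-node path lengths

  # ancestor chains for internal+tip nodes, via the edge table
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  ancestors <- function(node) {
    out <- node
    while (node != root) {
      node <- parent[node]
      out <- c(out, node)
    }
    out
  }

  mrca_node <- vapply(genera, function(g) {
    idx <- which(genus == g)
    if (length(idx) == 1L) return(idx)
    ape::getMRCA(phy, tips[idx])
  }, integer(1))

  # non-monophyly check: tips under the MRCA not belonging to the genus
  for (g in genera) {
    node <- mrca_node[g]
    if (node <= ntip) next
    desc <- phangorn::Descendants(phy, node, type = "tips")[[1]]
    intruders <- tips[desc][genus[desc] != g]
    if (length(intruders)) {
      warning("genus ", g, " is not monophyletic; collapsing at MRCA ",
              "anyway (intruding taxa: ",
              paste(intruders, collapse = ", "), ")", call. = FALSE)
    }
  }

  anc <- lapply(mrca_node, ancestors)
  d <- matrix(0, length(genera), length(genera),
              dimnames = list(genera, genera))
  for (i in seq_along(genera)) {
    for (j in seq_len(i - 1L)) {
      common <- intersect(anc[[i]], anc[[j]])
      lca_depth <- max(depth[common])
      d[i, j] <- d[j, i] <-
        depth[mrca_node[i]] + depth[mrca_node[j]] - 2 * lca_depth
    }
  }

  # representative-tip tree: keep one tip per genus, rescale its terminal
  # branch so the tip sits at the genus MRCA depth
  rep_tip <- vapply(genera, function(g) tips[which(genus == g)[1]],
                    character(1))
  pruned <- ape::keep.tip(phy, rep_tip)
  pruned_depth <- ape::node.depth.edgelength(pruned)
  for (i in seq_along(genera)) {
    tip_idx <- match(rep_tip[i], pruned$tip.label)
    e <- which(pruned$edge[, 2] == tip_idx)
    parent_depth <- pruned_depth[pruned$edge[e, 1]]
    pruned$edge.length[e] <- max(depth[mrca_node[i]] - parent_depth, 0)
  }
  pruned$tip.label <- genera[match(pruned$tip.label, rep_tip)]
  structure(list(tree = pruned, dist = d), class = "host_tree")
}

#' Host-association profiles for gene clusters and genomes
#'
#' For each gene cluster, counts how many known-host genomes carrying the
#' cluster are annotated with each host genus. A genome's profile is the sum
#' of the profiles of its clusters, capturing the mosaic of host associations
#' its genes carry. Genomes with unknown host contribute to no profile.
#'
#' @param P membership matrix from [build_membership()].
#' @param genomes data frame with columns `genome_id`, `host_genus` (`NA` =
#'   unknown).
#' @return list with integer count matrices `cluster` (gene cluster x genus)
#'   and `genome` (genome x genus), plus `orphan_clusters`: clusters found
#'   only in unknown-host genomes (all-zero profile rows, flagged).
#' @export
host_profiles <- function(P, genomes) {
  host <- genomes$host_genus[match(rownames(P), genomes$genome_id)]
  known <- !is_unknown_host(host)
  genera <- sort(unique(host[known]))
  if (!length(genera)) stop("no genomes with known host", call. = FALSE)
  H <- matrix(0L, nrow(P), length(genera),
              dimnames = list(rownames(P), genera))
  H[cbind(which(known), match(host[known], genera))] <- 1L
  cluster_prof <- t(P) %*% H          # cluster x genus
  genome_prof <- P %*% cluster_prof   # genome x genus (sum over its clusters)
  orphans <- colnames(P)[rowSums(cluster_prof) == 0L]
  if (length(orphans)) {
    message(length(orphans),
            " cluster(s) found only in unknown-host genomes")
  }
  list(cluster = cluster_prof, genome = genome_prof,
       orphan_clusters = orphans)
}

#' Abundance-weighted mean pairwise phylogenetic distance
#'
#' Treats a host-association profile as a community of host genera with
#' abundances and computes the abundance-weighted MPD: with relative
#' abundances `f_i`, `MPD = sum_{i != j} d_ij f_i f_j / sum_{i != j} f_i f_j`
#' over the cophenetic distances `d_ij` of the host tree. A profile
#' concentrated on a single genus has MPD exactly 0; an empty profile is
#' undefined and returns `NA` with a warning (distinct from 0).
#'
#' @param profile named nonnegative numeric vector of host-genus counts, or a
#'   single row of a profile matrix.
#' @param host_tree a `host_tree`, or a cophenetic distance matrix whose
#'   dimnames cover the profile's genera.
#' @return nonnegative real, or `NA_real_` for an empty profile.
#' @export
mpd <- function(profile, host_tree) {
  d <- if (inherits(host_tree, "host_tree")) host_tree$dist else host_tree
  profile <- profile[profile > 0]
  if (length(profile) == 0L || sum(profile) == 0) {
    warning("empty host profile: MPD undefined", call. = FALSE)
    return(NA_real_)
  }
  genera <- names(profile)
  missing <- setdiff(genera, rownames(d))
  if (length(missing)) {
    stop("genus not in host tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(genera) == 1L) return(0)
  f <- profile / sum(profile)
  dm <- d[genera, genera]
  W <- outer(f, f)
  diag(W) <- 0
  sum(dm * W) / sum(W)
}

#' Topology statistics for every pair of known-host genomes
#'
#' For each unordered pair of distinct known-host genomes, averages over the
#' rectangular submatrix (rows: first genome's clusters, columns: second
#' genome's clusters) of (a) shortest-path edge counts in the gene network
#' and (b) Jaccard similarity of open neighborhoods, and records the
#' phylogenetic distance between the two annotated host genera. Node pairs in
#' different components contribute no path term; their count is reported per
#' genome pair.
#'
#' @param gene_network igraph gene network from [project_networks()].
#' @param P membership matrix.
#' @param genomes data frame with `genome_id`, `host_genus`.
#' @param host_tree genus-level `host_tree` covering the annotated genera.
#' @return data frame with columns `genome_a`, `genome_b`,
#'   `mean_shortest_path` (`NA` when no finite pair), `n_unreachable`,
#'   `mean_similarity`, `host_distance`.
#' @export
pairwise_topology <- function(gene_network, P, genomes, host_tree) {
  host <- genomes$host_genus[match(rownames(P), genomes$genome_id)]
  keep <- which(!is_unknown_host(host))
  if (length(keep) < 2L) stop("need >= 2 known-host genomes", call. = FALSE)
  d <- if (inherits(host_tree, "host_tree")) host_tree$dist else host_tree
  missing <- setdiff(unique(host[keep]), rownames(d))
  if (length(missing)) {
    stop("host genus not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nodes <- igraph::V(gene_network)$name
  D <- igraph::distances(gene_network)  # BFS on unweighted graphs
  S <- igraph::similarity(gene_network, method = "jaccard", mode = "all",
                          loops = FALSE)
  dimnames(S) <- list(nodes, nodes)
  members <- lapply(keep, function(i) {
    intersect(colnames(P)[P[i, ] == 1L], nodes)
  })
  pairs <- utils::combn(seq_along(keep), 2)
  out <- data.frame(
    genome_a = rownames(P)[keep][pairs[1, ]],
    genome_b = rownames(P)[keep][pairs[2, ]],
    mean_shortest_path = NA_real_,
    n_unreachable = 0L,
    mean_similarity = NA_real_,
    host_distance = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(pairs))) {
    ca <- members[[pairs[1, k]]]
    cb <- members[[pairs[2, k]]]
    sub_d <- D[ca, cb, drop = FALSE]
    finite <- is.finite(sub_d)
    out$n_unreachable[k] <- sum(!finite)
    if (any(finite)) out$mean_shortest_path[k] <- mean(sub_d[finite])
    out$mean_similarity[k] <- mean(S[ca, cb])
    ga <- host[keep][pairs[1, k]]
    gb <- host[keep][pairs[2, k]]
    out$host_distance[k] <- if (ga == gb) 0 else d[ga, gb]
  }
  out
}

#' Regress host phylogenetic distance on gene-network topology
#'
#' Ordinary least squares of host phylogenetic distance on the
#' (log-transformed) mean shortest path and, separately, on the
#' (log-transformed) mean neighborhood similarity of each genome pair. Pairs
#' with a zero or undefined predictor are dropped from the corresponding log
#' fit and counted. A positive path slope / negative similarity slope means
#' phages whose genes sit closer (or share more edges) in the gene network
#' infect more closely related hosts.
#'
#' @param stats data frame from [pairwise_topology()].
#' @param transform `"log"` (natural log of the predictor) or `"none"`.
#' @return list with one element per predictor (`shortest_path`,
#'   `similarity`), each a list `(slope, intercept, r_squared, p_value,
#'   n_used, n_dropped)`.
#' @export
host_distance_regression <- function(stats, transform = c("log", "none")) {
  transform <- match.arg(transform)
  fit_one <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (transform == "log") ok <- ok & x > 0
    n_dropped <- sum(!ok)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("fewer than 3 usable pairs", call. = FALSE)
    if (transform == "log") x <- log(x)
    if (stats::sd(x) == 0) {
      stop("predictor has zero variance: slope undefined", call. = FALSE)
    }
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients[2, 4]),
         n_used = length(x),
         n_dropped = n_dropped)
  }
  list(
    shortest_path = fit_one(stats$mean_shortest_path, stats$host_distance),
    similarity = fit_one(stats$mean_similarity, stats$host_distance)
  )
}
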