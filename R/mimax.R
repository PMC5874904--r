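#' Build the MCL-cluster-by-host association matrix (chi)
#'
#' Row `i`, column `j` of chi counts, summed over the gene clusters that MCL
#' placed in cluster `i`, how many known-host genomes carrying each gene
#' cluster are annotated with host genus `j`. Chi is the contingency table
#' whose mutual information [mimax_search()] maximizes. MCL clusters whose
#' gene clusters occur only in unknown-host genomes would give all-zero rows
#' and are dropped with a message.
#'
#' @param mcl_result an `mcl_result` on the gene network (nodes = gene
#'   cluster ids).
#' @param cluster_profiles gene-cluster-by-genus count matrix from
#'   [host_profiles()].
#' @return object of class `chi_matrix`: list with `counts` (matrix, rows
#'   named by MCL cluster label) and `provenance` (list mapping each retained
#'   row to its gene cluster ids).
#' @export
build_chi <- function(mcl_result, cluster_profiles) {
  part <- mcl_result$partition
  missing <- setdiff(names(part), rownames(cluster_profiles))
  if (length(missing)) {
    stop("no host profile for gene cluster(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- sort(unique(part))
  counts <- t(vapply(labels, function(k) {
    colSums(cluster_profiles[names(part)[part == k], , drop = FALSE])
  }, numeric(ncol(cluster_profiles))))
  rownames(counts) <- as.character(labels)
  colnames(counts) <- colnames(cluster_profiles)
  provenance <- lapply(labels, function(k) names(part)[part == k])
  names(provenance) <- as.character(labels)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " all-zero chi row(s) ",
            "(gene clusters only in unknown-host genomes)")
    counts <- counts[!zero, , drop = FALSE]
    provenance <- provenance[!zero]
  }
  structure(list(counts = counts, provenance = provenance),
            class = "chi_matrix")
}

#' Mutual information of a count matrix
#'
#' Treats the rows and columns of a nonnegative count matrix as two discrete
#' random variables with joint distribution `p(x, y) = n_xy / N` and computes
#' `I(X, Y) = sum p(x, y) log( p(x, y) / (p(x) p(y)) )` in nats (natural
#' logarithm); cells with `p(x, y) = 0` contribute 0 by convention.
#'
#' @param chi a `chi_matrix` or a plain nonnegative matrix.
#' @return nonnegative real (up to floating-point round-off).
#' @export
mutual_information <- function(chi) {
  m <- if (inherits(chi, "chi_matrix")) chi$counts else chi
  N <- sum(m)
  if (N <= 0) stop("all-zero matrix: mutual information undefined",
                   call. = FALSE)
  p <- m / N
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  ratio <- p / outer(px, py)
  sum(p[pos] * log(ratio[pos]))
}

#' Constrained greedy mutual-information maximization (mimax)
#'
#' Stochastic hill climber over subsets of chi rows (MCL clusters). Each
#' iteration samples a retained row uniformly at random and proposes deleting
#' it. The deletion is rejected outright if it would leave any genome with no
#' gene cluster inside the retained rows (no genome may drop out of the data
#' set); otherwise the mutual information of the reduced matrix is computed
#' and the deletion is kept only if it strictly exceeds the current value.
#' The search stops after `patience` consecutive non-accepted proposals or
#' `max_iterations` total proposals. Accepted steps therefore form a strictly
#' increasing MI trajectory.
#'
#' @param chi a `chi_matrix` from [build_chi()] (provenance required).
#' @param P membership matrix; only known-host genomes are subject to the
#'   coverage constraint, so rows of `P` for unknown-host genomes may be
#'   dropped or kept as convenient.
#' @param max_iterations proposal cap; default `1e5`.
#' @param patience stop after this many consecutive non-accepted proposals;
#'   default `10 * nrow(chi)`.
#' @param seed integer seed for the proposal stream.
#' @return object of class `mimax_state`: list with `retained_rows`,
#'   `initial_mi`, `current_mi`, `trace` (data frame `iteration`,
#'   `proposed_row`, `feasible`, `accepted`, `mi`), and `seed`.
#' @export
mimax_search <- function(chi, P, max_iterations = 1e5L, patience = NULL,
                         seed = 1L) {
  stopifnot(inherits(chi, "chi_matrix"))
  counts <- chi$counts
  rows <- rownames(counts)
  patience <- as.integer(patience %||% (10L * nrow(counts)))

  # genome x row coverage counts: how many of genome g's gene clusters sit in
  # row i; a genome is covered while its total over retained rows is positive
  all_gc <- unlist(chi$provenance, use.names = FALSE)
  Psub <- P[, intersect(colnames(P), all_gc), drop = FALSE]
  cover <- vapply(chi$provenance, function(gc) {
    rowSums(Psub[, intersect(gc, colnames(Psub)), drop = FALSE])
  }, numeric(nrow(Psub)))
  if (is.null(dim(cover))) cover <- matrix(cover, nrow = 1)
  colnames(cover) <- rows
  covered <- rownames(P)[rowSums(cover) > 0]
  cover <- cover[covered, , drop = FALSE]
  total_cover <- rowSums(cover)

  current_mi <- mutual_information(counts)
  initial_mi <- current_mi
  retained <- rep(TRUE, length(rows))
  names(retained) <- rows

  trace <- list()
  if (length(rows) > 1L) {
    with_seed(seed, {
      stall <- 0L
      for (it in seq_len(max_iterations)) {
        live <- which(retained)
        i <- live[[sample.int(length(live), 1L)]]
        feasible <- !any(total_cover - cover[, i] == 0 & cover[, i] > 0)
        accepted <- FALSE
        mi <- current_mi
        if (feasible && sum(retained) > 1L) {
          keep <- retained
          keep[i] <- FALSE
          mi_new <- mutual_information(counts[keep, , drop = FALSE])
          if (mi_new > current_mi) {
            retained <- keep
            total_cover <- total_cover - cover[, i]
            current_mi <- mi_new
            accepted <- TRUE
            mi <- mi_new
          }
        }
        trace[[it]] <- data.frame(iteration = it,
                                  proposed_row = rows[i],
                                  feasible = feasible,
                                  accepted = accepted,
                                  mi = mi)
        stall <- if (accepted) 0L else stall + 1L
        if (stall >= patience) break
      }
    })
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(iteration = integer(), proposed_row = character(),
               feasible = logical(), accepted = logical(), mi = numeric())
  structure(list(retained_rows = rows[retained],
                 initial_mi = initial_mi,
                 current_mi = current_mi,
                 trace = trace,
                 seed = seed),
            class = "mimax_state")
}

#' @export
print.mimax_state <- function(x, ...) {
  cat("mimax_state:", length(x$retained_rows), "rows retained; MI",
      format(x$initial_mi, digits = 4), "->",
      format(x$current_mi, digits = 4), "in",
      nrow(x$trace), "proposals (", sum(x$trace$accepted), "accepted )\n")
  invisible(x)
}

#' Gene clusters retained by a mimax run
#'
#' Flattens the provenance of the retained chi rows back to gene-cluster ids,
#' for use with [predict_hosts()].
#'
#' @param state a `mimax_state`.
#' @param chi the `chi_matrix` the search ran on.
#' @return character vector of gene cluster ids.
#' @export
retained_gene_clusters <- function(state, chi) {
  unique(unlist(chi$provenance[state$retained_rows], use.names = FALSE))
}

#' Increase MCL granularity by inflation and random edges
#'
#' mimax deletes whole MCL clusters, so it resolves host signal better when
#' there are many small clusters to choose from. This helper composes
#' [augment_edges()] (random edges create artificial distinctions between
#' near-duplicate nodes, splitting large clusters) with [mcl_cluster()] at a
#' high inflation.
#'
#' @param gene_network igraph gene network.
#' @param inflation MCL inflation; default 15.
#' @param edges_per_node random edges per node; default 5.
#' @param seed seed for the edge sampling.
#' @param params base [mcl_params()]; inflation is overridden.
#' @return an `mcl_result` on the (augmented) network.
#' @export
granularity_boost <- function(gene_network, inflation = 15,
                              edges_per_node = 5L, seed = 1L,
                              params = mcl_params()) {
  g <- augment_edges(gene_network, edges_per_node, seed = seed)
  params$inflation <- inflation
  mcl_cluster(g, params)
}
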