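#' MCL parameter set
#'
#' Parameters for the Markov Cluster algorithm. Defaults follow common MCL
#' practice at desk scale: self-loops of weight 1 added before normalization
#' (prevents oscillation on bipartite-like structures), expansion power 2,
#' pruning of entries below `1e-8`, convergence when the largest entrywise
#' change falls below `1e-6`, at most 200 iterations.
#'
#' @param inflation entrywise inflation exponent, must exceed 1; larger values
#'   give more, smaller clusters.
#' @param expansion_power integer matrix power used in the expansion step.
#' @param pruning_threshold entries below this are zeroed after inflation.
#' @param max_iterations iteration cap.
#' @param convergence_tol stop when `max |M_t+1 - M_t|` drops below this.
#' @param self_loops add unit self-loops before normalization.
#' @return list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2, expansion_power = 2L,
                       pruning_threshold = 1e-8, max_iterations = 200L,
                       convergence_tol = 1e-6, self_loops = TRUE) {
  stopifnot(inflation > 1, expansion_power >= 2L, max_iterations >= 1L,
            pruning_threshold >= 0, convergence_tol > 0)
  structure(list(inflation = inflation,
                 expansion_power = as.integer(expansion_power),
                 pruning_threshold = pruning_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 self_loops = isTRUE(self_loops)),
            class = "mcl_params")
}

#' Markov Cluster algorithm
#'
#' From-scratch MCL: the adjacency matrix (plus unit self-loops) is column
#' normalized into a random-walk transition matrix, then expansion (matrix
#' power) and inflation (entrywise power followed by column renormalization,
#' with pruning of tiny entries) alternate until the matrix stops changing.
#' Clusters are read off as connected components of the nonzero pattern of
#' the limit matrix (the attractor interpretation); labels are contiguous
#' integers numbered by first node appearance, so the result is deterministic.
#'
#' A node attracted to two attractor systems would make two components merge;
#' with the component readout such overlaps resolve to the merged (lowest)
#' label and are not distinguished.
#'
#' @param network igraph undirected graph with named vertices.
#' @param params an [mcl_params()] object.
#' @return object of class `mcl_result`: list with `partition` (named integer
#'   vector, node -> cluster label), `n_clusters`, `params`, `iterations_run`,
#'   and `converged` (FALSE triggers a warning).
#' @export
mcl_cluster <- function(network, params = mcl_params()) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network", call. = FALSE)
  A <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  nodes <- rownames(A)
  if (params$self_loops) diag(A) <- diag(A) + 1
  cs <- colSums(A)
  cs[cs == 0] <- 1  # isolated node without self-loop: leave as zero column
  M <- sweep(A, 2, cs, "/")
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params$max_iterations)) {
    E <- M
    for (p in seq_len(params$expansion_power - 1L)) E <- E %*% M
    E <- E^params$inflation
    E[E < params$pruning_threshold] <- 0
    cs <- colSums(E)
    cs[cs == 0] <- 1
    E <- sweep(E, 2, cs, "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", params$max_iterations,
            " iterations; returning current interpretation", call. = FALSE)
  }
  supp <- (M > 0) | t(M > 0)
  lab <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (lab[i] == 0L) {
      nxt <- nxt + 1L
      frontier <- i
      lab[i] <- nxt
      while (length(frontier)) {
        nb <- which(colSums(supp[frontier, , drop = FALSE]) > 0 & lab == 0L)
        lab[nb] <- nxt
        frontier <- nb
      }
    }
  }
  structure(list(partition = stats::setNames(lab, nodes),
                 n_clusters = nxt,
                 params = params,
                 iterations_run = iter,
                 converged = converged),
            class = "mcl_result")
}

#' @export
print.mcl_result <- function(x, ...) {
  cat("mcl_result:", x$n_clusters, "clusters over", length(x$partition),
      "nodes (inflation", x$params$inflation, ",", x$iterations_run,
      "iterations)\n")
  invisible(x)
}

#' Intracluster clustering coefficient (ICCC)
#'
#' Cohesion score of an MCL partition, used to select the inflation
#' parameter. For each cluster with at least three nodes the mean local
#' clustering coefficient of its induced subgraph is computed (nodes with
#' fewer than two within-cluster neighbors contribute 0); the ICCC is by
#' default the size-weighted mean of those cluster means. Clusters of size
#' one or two carry no triangle information and are excluded from both the
#' numerator and the weights.
#'
#' @param network igraph undirected graph.
#' @param result an `mcl_result` whose partition covers the network.
#' @param weighted if `FALSE`, use the unweighted mean over clusters instead
#'   of the size-weighted mean.
#' @return real in `[0, 1]`; 0 (with a warning) when no cluster reaches
#'   size 3.
#' @export
iccc <- function(network, result, weighted = TRUE) {
  part <- result$partition
  stopifnot(setequal(names(part), igraph::V(network)$name))
  vals <- numeric()
  sizes <- integer()
  for (k in sort(unique(part))) {
    members <- names(part)[part == k]
    if (length(members) < 3L) next
    sub <- igraph::induced_subgraph(network, members)
    cc <- igraph::transitivity(sub, type = "local", isolates = "zero")
    vals <- c(vals, mean(cc))
    sizes <- c(sizes, length(members))
  }
  if (!length(vals)) {
    warning("no cluster of size >= 3; ICCC defined as 0", call. = FALSE)
    return(0)
  }
  if (weighted) sum(vals * sizes) / sum(sizes) else mean(vals)
}

#' Sweep the MCL inflation parameter and score each partition
#'
#' Runs [mcl_cluster()] and [iccc()] at each grid value and recommends the
#' inflation maximizing the ICCC (ties resolved toward the smallest
#' inflation).
#'
#' @param network igraph undirected graph.
#' @param inflation_grid numeric vector of inflation values (> 1).
#' @param params base [mcl_params()]; its inflation entry is overridden.
#' @param weighted passed to [iccc()].
#' @return data frame with columns `inflation`, `n_clusters`, `iccc`, and
#'   attribute `recommended_inflation`.
#' @export
sweep_inflation <- function(network, inflation_grid, params = mcl_params(),
                            weighted = TRUE) {
  stopifnot(length(inflation_grid) >= 1L, all(inflation_grid > 1))
  inflation_grid <- sort(unique(inflation_grid))
  rows <- lapply(inflation_grid, function(infl) {
    p <- params
    p$inflation <- infl
    res <- mcl_cluster(network, p)
    data.frame(inflation = infl, n_clusters = res$n_clusters,
               iccc = suppressWarnings(iccc(network, res, weighted)))
  })
  out <- do.call(rbind, rows)
  best <- out$inflation[which.max(out$iccc)]  # which.max takes first = smallest
  out <- out[order(out$inflation), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "recommended_inflation") <- best
  out
}

#' Read a clustering in the native output format of the external mcl program
#'
#' One cluster per line, tab-separated node names.
#'
#' @param path file path.
#' @param params optional [mcl_params()] to attach (for provenance).
#' @return an `mcl_result`.
#' @export
read_mcl_clusters <- function(path, params = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  members <- strsplit(lines, "\t", fixed = TRUE)
  lab <- rep(seq_along(members), lengths(members))
  nodes <- unlist(members)
  if (anyDuplicated(nodes)) {
    stop("node listed in more than one cluster", call. = FALSE)
  }
  structure(list(partition = stats::setNames(lab, nodes),
                 n_clusters = length(members),
                 params = params, iterations_run = NA_integer_,
                 converged = NA),
            class = "mcl_result")
}
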