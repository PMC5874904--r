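#' Leave-one-out majority-host prediction
#'
#' A phage's predicted host is the genus with the greatest representation
#' among the host associations of its (mimax-reduced) gene clusters, with the
#' focal genome's own contribution removed: for each of the genome's retained
#' clusters, the genome itself added one count to its own annotated genus, so
#' that count is subtracted before taking the argmax. The MPD of the same
#' leave-one-out profile is recorded, since prediction difficulty grows with
#' the phylogenetic breadth of the profile. Ties at the argmax are broken
#' toward the genus with more genomes overall, then lexicographically, and
#' flagged. Genomes whose leave-one-out profile is empty (their clusters
#' occur nowhere else) get no prediction and are excluded from accuracy
#' denominators.
#'
#' @param P membership matrix.
#' @param cluster_profiles gene-cluster-by-genus count matrix from
#'   [host_profiles()].
#' @param genomes data frame with `genome_id`, `host_genus`.
#' @param host_tree genus-level `host_tree` (for the profile MPD).
#' @param retained_clusters optional character vector restricting `P`'s
#'   columns (e.g. from [retained_gene_clusters()]); default: all clusters.
#' @return data frame of class `host_predictions` with columns `genome_id`,
#'   `predicted_genus` (`NA` = no prediction), `annotated_genus`, `correct`,
#'   `profile_mpd`, `tie`.
#' @export
predict_hosts <- function(P, cluster_profiles, genomes, host_tree,
                          retained_clusters = NULL) {
  cl <- retained_clusters %||% colnames(P)
  cl <- intersect(colnames(P), cl)
  if (!length(cl)) stop("no retained clusters", call. = FALSE)
  prof <- cluster_profiles[cl, , drop = FALSE]
  host <- genomes$host_genus[match(rownames(P), genomes$genome_id)]
  known <- which(!is_unknown_host(host))
  genus_freq <- table(host[known])
  genera <- colnames(prof)
  out <- data.frame(genome_id = rownames(P)[known],
                    predicted_genus = NA_character_,
                    annotated_genus = host[known],
                    correct = NA,
                    profile_mpd = NA_real_,
                    tie = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_along(known)) {
    i <- known[r]
    mine <- cl[P[i, cl] == 1L]
    if (!length(mine)) next
    loo <- colSums(prof[mine, , drop = FALSE])
    # remove the focal genome: it contributed one count of its own genus to
    # each of its clusters
    g <- host[i]
    if (g %in% names(loo)) loo[g] <- loo[g] - length(mine)
    loo <- pmax(loo, 0)
    if (sum(loo) == 0) next  # no shared genes: no prediction possible
    top <- names(loo)[loo == max(loo)]
    if (length(top) > 1L) {
      out$tie[r] <- TRUE
      freq <- genus_freq[top]
      freq[is.na(freq)] <- 0
      top <- top[order(-as.numeric(freq), top)]
    }
    out$predicted_genus[r] <- top[1]
    out$correct[r] <- identical(top[1], g)
    out$profile_mpd[r] <- mpd(loo[loo > 0], host_tree)
  }
  class(out) <- c("host_predictions", class(out))
  out
}

#' Assign external query genes to gene clusters by centroid alignment
#'
#' Maps proteins from phages outside the network onto existing gene clusters
#' by aligning each query against every cluster centroid (local alignment,
#' BLOSUM62, gap open 11 / extend 1) and keeping the best hit passing both an
#' E-value ceiling and a bit-score floor. The built-in scorer converts raw
#' Smith-Waterman scores with the standard Karlin-Altschul gapped parameters
#' (lambda 0.267, K 0.041); it is a calibrated surrogate for protein BLAST
#' scores, deterministic but not bit-identical to BLAST. Ties go to the
#' lexicographically smaller cluster id and are logged.
#'
#' @param query_genes data frame with `gene_id`, `sequence`.
#' @param centroids data frame with `gene_id`, `cluster_id`, `sequence` (one
#'   row per cluster centroid).
#' @param max_evalue significance ceiling; default `1e-5`.
#' @param min_bitscore bit-score floor; default 50.
#' @return data frame `gene_id`, `cluster_id` (`NA` = unassigned),
#'   `bitscore`, `evalue`.
#' @export
assign_external_genes <- function(query_genes, centroids,
                                  max_evalue = 1e-5, min_bitscore = 50) {
  out <- data.frame(gene_id = query_genes$gene_id,
                    cluster_id = NA_character_,
                    bitscore = NA_real_, evalue = NA_real_,
                    stringsAsFactors = FALSE)
  if (is.null(centroids) || nrow(centroids) == 0L) return(out)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  db_len <- sum(nchar(centroids$sequence))
  lambda <- 0.267
  logK <- log(0.041)
  for (q in seq_len(nrow(query_genes))) {
    qs <- toupper(query_genes$sequence[q])
    scores <- vapply(seq_len(nrow(centroids)), function(c) {
      Biostrings::pairwiseAlignment(
        pattern = qs, subject = toupper(centroids$sequence[c]),
        type = "local", substitutionMatrix = B62,
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    }, numeric(1))
    bits <- (lambda * scores - logK) / log(2)
    evals <- nchar(qs) * db_len * 2^(-bits)
    pass <- which(bits > min_bitscore & evals < max_evalue)
    if (!length(pass)) next
    best <- pass[bits[pass] == max(bits[pass])]
    if (length(best) > 1L) {
      ids <- centroids$cluster_id[best]
      message("query ", query_genes$gene_id[q], ": tie between clusters ",
              paste(sort(ids), collapse = ", "), "; taking the first")
      best <- best[order(ids)]
    }
    out$cluster_id[q] <- centroids$cluster_id[best[1]]
    out$bitscore[q] <- bits[best[1]]
    out$evalue[q] <- evals[best[1]]
  }
  out
}

#' Per-genus accuracy report for host predictions
#'
#' @param predictions a `host_predictions` data frame; rows without a
#'   prediction are excluded from all denominators and counted separately.
#' @return data frame with one row per annotated genus (`host_genus`,
#'   `accuracy`, `most_common_incorrect`, `n`) ordered by decreasing
#'   accuracy, with attributes `overall_accuracy`, `n_scored`,
#'   `n_unpredicted`.
#' @export
accuracy_report <- function(predictions) {
  scored <- predictions[!is.na(predictions$predicted_genus), , drop = FALSE]
  if (nrow(scored) == 0L) stop("no scored predictions", call. = FALSE)
  split_rows <- split(scored, scored$annotated_genus)
  rows <- lapply(names(split_rows), function(g) {
    s <- split_rows[[g]]
    wrong <- s$predicted_genus[!s$correct]
    modal <- if (length(wrong)) names(sort(table(wrong),
                                           decreasing = TRUE))[1]
             else NA_character_
    data.frame(host_genus = g,
               accuracy = mean(s$correct),
               most_common_incorrect = modal,
               n = nrow(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, out$host_genus), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overall_accuracy") <- mean(scored$correct)
  attr(out, "n_scored") <- nrow(scored)
  attr(out, "n_unpredicted") <- sum(is.na(predictions$predicted_genus))
  out
}

#' Logistic regression of prediction correctness on profile MPD
#'
#' Fits `correct ~ profile_mpd` by maximum-likelihood logistic regression and
#' reports McFadden's pseudo-R-squared, `1 - logLik(model) / logLik(null)`.
#' A negative MPD coefficient means predictions degrade as the hosts
#' associated with a genome's genes grow phylogenetically broader. Under
#' complete separation the ML fit diverges; the function then substitutes a
#' Firth bias-reduced fit and labels the result.
#'
#' @param predictions a `host_predictions` data frame (scored rows used), or
#'   any data frame with logical `correct` and numeric `profile_mpd`.
#' @return list with `coefficients` (intercept, mpd slope),
#'   `mcfadden_r_squared`, `p_value` (Wald, slope), `method` (`"glm"` or
#'   `"firth"`), `separation` flag, and `n`.
#' @export
logistic_mpd <- function(predictions) {
  d <- predictions[!is.na(predictions$predicted_genus) &
                     !is.na(predictions$profile_mpd), , drop = FALSE]
  y <- as.integer(d$correct)
  x <- d$profile_mpd
  if (length(unique(y)) < 2L) {
    stop("need both correct and incorrect predictions to fit", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("MPD does not vary", call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  method <- "glm"
  if (separation || !fit$converged) {
    separation <- TRUE
    method <- "firth"
    fit_coef <- firth_logit(cbind(1, x), y)
    coefs <- fit_coef$beta
    se <- fit_coef$se
  } else {
    coefs <- stats::coef(fit)
    se <- summary(fit)$coefficients[, 2]
  }
  ll <- logit_loglik(coefs, cbind(1, x), y)
  null_coef <- stats::qlogis(mean(y))
  ll0 <- logit_loglik(c(null_coef, 0), cbind(1, x), y)
  z <- coefs[2] / se[2]
  list(coefficients = stats::setNames(unname(coefs),
                                      c("(Intercept)", "mpd")),
       se = stats::setNames(unname(se), c("(Intercept)", "mpd")),
       mcfadden_r_squared = 1 - ll / ll0,
       p_value = 2 * stats::pnorm(-abs(z)),
       method = method,
       separation = separation,
       n = length(y))
}

logit_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Firth bias-reduced logistic regression (Jeffreys-prior score adjustment),
# used only when ordinary ML separates.
firth_logit <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XW <- X * W
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    H <- rowSums((X %*% info_inv) * XW)  # hat diagonal
    U <- crossprod(X, y - p + H * (0.5 - p))
    step <- drop(info_inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(info_inv)))
}

#' Read a subsystem annotation table
#'
#' Reads a TSV with columns `subsystem`, `pre`, `post`: the number of
#' annotations in each functional subsystem among all genes (`pre`) and among
#' the genes retained by a mimax run (`post`). Any row labeled `Total`
#' (case-insensitive) is dropped; `post > pre` is an error.
#'
#' @param path file path.
#' @return data frame with columns `subsystem`, `pre`, `post`.
#' @export
read_annotation_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subsystem", "pre", "post") %in% names(d))) {
    stop("annotation table needs columns subsystem, pre, post", call. = FALSE)
  }
  d <- d[tolower(trimws(d$subsystem)) != "total", , drop = FALSE]
  if (anyDuplicated(d$subsystem)) {
    stop("duplicate subsystem labels", call. = FALSE)
  }
  if (any(d$post > d$pre)) {
    stop("post-mimax count exceeds pre-mimax count for: ",
         paste(d$subsystem[d$post > d$pre], collapse = ", "), call. = FALSE)
  }
  rownames(d) <- NULL
  d
}

#' Subsystem enrichment among mimax-retained genes
#'
#' Regresses post-mimax annotation counts on pre-mimax counts by OLS and
#' flags subsystems whose observed post-mimax count falls outside the
#' pointwise confidence band for the mean response at their pre-mimax count
#' (t distribution, `n - 2` df). Subsystems above the band are
#' over-retained relative to the global trend, those below under-retained.
#' The default band is the confidence interval for the mean response; a
#' prediction interval is available via `interval`.
#'
#' @param table data frame from [read_annotation_table()] (Total row already
#'   excluded; at least 3 rows).
#' @param ci_level confidence level for the band; default 0.999.
#' @param interval `"confidence"` (mean response, default) or
#'   `"prediction"`.
#' @return list with `table` (input plus `fitted`, `ci_lower`, `ci_upper`,
#'   `direction` in over/under/none), `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `proportion_retained` (total post / total
#'   pre).
#' @export
enrichment_outliers <- function(table, ci_level = 0.999,
                                interval = c("confidence", "prediction")) {
  interval <- match.arg(interval)
  stopifnot(nrow(table) >= 3L)
  if (stats::sd(table$pre) == 0) {
    stop("pre-mimax counts have zero variance", call. = FALSE)
  }
  fit <- stats::lm(post ~ pre, data = table)
  band <- stats::predict(fit, newdata = table, interval = interval,
                         level = ci_level)
  direction <- rep("none", nrow(table))
  direction[table$post > band[, "upr"]] <- "over"
  direction[table$post < band[, "lwr"]] <- "under"
  out_table <- cbind(table,
                     fitted = band[, "fit"],
                     ci_lower = band[, "lwr"],
                     ci_upper = band[, "upr"],
                     direction = direction)
  sm <- summary(fit)
  list(table = out_table,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       adj_r_squared = sm$adj.r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       proportion_retained = sum(table$post) / sum(table$pre))
}
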