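# Independent oracles and shared fixtures, built in code.

# Enumerate all global alignments of two tiny sequences under the package's
# scoring (match +1, mismatch -1, gap of length L costs 5 + L, end gaps
# penalized) and return the set of identities achieved by score-optimal
# alignments, with terminal-gap columns excluded from the denominator.
# Exponential; only for sequences of length <= 7.
enum_identities <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$ids <- numeric()
  rec <- function(i, j, score, last, top, bot) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$ids <- numeric()
      }
      if (abs(score - best$score) < 1e-9) {
        gap <- top == "-" | bot == "-"
        n <- length(top)
        lead <- 0L
        while (lead < n && gap[lead + 1L]) lead <- lead + 1L
        trail <- 0L
        while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
        keep <- seq.int(lead + 1L, n - trail)
        id <- sum(top[keep] == bot[keep] & top[keep] != "-") / length(keep)
        best$ids <- sort(unique(c(best$ids, id)))
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) 1 else -1
      rec(i + 1L, j + 1L, score + s, "m", c(top, a[i]), c(bot, b[j]))
    }
    if (i <= length(a)) {
      pen <- if (identical(last, "d")) 1 else 6
      rec(i + 1L, j, score - pen, "d", c(top, a[i]), c(bot, "-"))
    }
    if (j <= length(b)) {
      pen <- if (identical(last, "i")) 1 else 6
      rec(i, j + 1L, score - pen, "i", c(top, "-"), c(bot, b[j]))
    }
  }
  rec(1L, 1L, 0, "", character(), character())
  best$ids
}

# Brute-force abundance-weighted MPD: explicit double loop over ordered
# host pairs, i != j.
brute_mpd <- function(profile, d) {
  profile <- profile[profile > 0]
  f <- profile / sum(profile)
  gen <- names(profile)
  num <- 0
  den <- 0
  for (i in gen) {
    for (j in gen) {
      if (i != j) {
        num <- num + d[i, j] * f[[i]] * f[[j]]
        den <- den + f[[i]] * f[[j]]
      }
    }
  }
  if (den == 0) 0 else num / den
}

# Mutual information through the entropy identity I = H(X) + H(Y) - H(X,Y).
entropy_mi <- function(m) {
  p <- m / sum(m)
  H <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  H(rowSums(p)) + H(colSums(p)) - H(as.vector(p))
}

# Exhaustive search over all row subsets of a chi matrix that keep every
# genome covered; returns the maximal mutual information and one argmax.
exhaustive_mimax <- function(chi, P) {
  rows <- rownames(chi$counts)
  n <- length(rows)
  stopifnot(n <= 16)
  cover <- vapply(chi$provenance, function(gc) {
    rowSums(P[, intersect(gc, colnames(P)), drop = FALSE])
  }, numeric(nrow(P)))
  relevant <- rowSums(cover) > 0
  cover <- cover[relevant, , drop = FALSE]
  best <- -Inf
  best_rows <- NULL
  for (mask in seq_len(2^n - 1L)) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    if (nrow(cover) && any(rowSums(cover[, keep, drop = FALSE]) == 0)) next
    mi <- mutual_information(chi$counts[keep, , drop = FALSE])
    if (mi > best + 1e-12) {
      best <- mi
      best_rows <- rows[keep]
    }
  }
  list(mi = best, rows = best_rows)
}

rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  s / choose(n, 2)
}

# Two partitions (named/ordered the same way) describe the same clustering?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Protein families of graded divergence for identity-threshold sweeps:
# `fams` ancestors, `per` members each, mutated at per-family rates spanning
# 0.05..0.40 so different thresholds split different families.
make_family_set <- function(seed = 11, fams = 6, per = 4, len = 80,
                            max_rate = 0.40) {
  set.seed(seed)
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rates <- seq(0.05, max_rate, length.out = fams)
  rows <- vector("list", fams * per)
  k <- 0L
  for (f in seq_len(fams)) {
    anc <- sample(ab, len, replace = TRUE)
    for (m in seq_len(per)) {
      k <- k + 1L
      s <- anc
      mut <- stats::runif(len) < rates[f]
      s[mut] <- vapply(s[mut], function(o) sample(setdiff(ab, o), 1),
                       character(1))
      rows[[k]] <- data.frame(gene_id = sprintf("f%02d_m%02d", f, m),
                              family = f,
                              sequence = paste(s, collapse = ""),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# A 12-row mimax instance with a known reachable optimum: 4 host-specific
# chi rows (one per genus, counts 3) plus 8 mixed rows; every genome carries
# its genus-specific cluster and two mixed clusters, so all mixed rows are
# redundant for coverage and the optimum is the 4 clean rows.
mimax_instance <- function(seed = 42) {
  genera <- paste0("G", 1:4)
  rows <- paste0("r", 1:12)
  set.seed(seed)
  counts <- rbind(diag(4) * 3, matrix(stats::rpois(32, 2), 8, 4))
  dimnames(counts) <- list(rows, genera)
  genomes <- as.vector(outer(genera, 1:3, paste, sep = "_"))
  P <- matrix(0L, 12, 12, dimnames = list(genomes, rows))
  for (i in seq_along(genomes)) {
    gen <- match(sub("_.*", "", genomes[i]), genera)
    P[i, gen] <- 1L
    P[i, sample(5:12, 2)] <- 1L
  }
  chi <- structure(list(counts = counts,
                        provenance = stats::setNames(as.list(rows), rows)),
                   class = "chi_matrix")
  list(chi = chi, P = P)
}

# A small simulated dataset reused across unit tests.
small_sim <- function(seed = 3) {
  simulate_dataset(simulation_config(n_hosts = 4, n_genomes_per_host = 5,
                                     genes_per_genome = 12,
                                     pool_size_per_host = 24, seed = seed))
}

# The default-condition simulated study and its full pipeline run, computed
# once per test session (used by several acceptance checks).
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    sim <- simulate_dataset(simulation_config(seed = 1))
    .run_cache$sim <- sim
    .run_cache$run <- suppressMessages(
      run_pipeline(sim, inflation_grid = c(2, 4), seed = 1)
    )
  }
  .run_cache$run
}
default_sim <- function() {
  default_run()
  .run_cache$sim
}
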