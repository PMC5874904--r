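test_that("genus collapse places each genus at its strains' MRCA", {
  tw <- withr::local_tempfile(lines = "((A1:1,A2:1):1,B:2);")
  ht <- read_host_tree(tw)
  g <- collapse_to_genus(ht, c(A1 = "A", A2 = "A", B = "B"))
  expect_setequal(rownames(g$dist), c("A", "B"))
  expect_equal(g$dist["A", "B"], 3)
  # representative-tip tree is consistent with the matrix here
  expect_equal(ape::cophenetic.phylo(g$tree)["A", "B"], 3)

  # an already genus-level tree is unchanged
  tg <- withr::local_tempfile(lines = "((A:1,B:1):1,C:2);")
  htg <- read_host_tree(tg)
  gg <- collapse_to_genus(htg, c(A = "A", B = "B", C = "C"))
  expect_equal(gg$dist, htg$dist)

  # drop list removes a leaf before collapsing
  gd <- collapse_to_genus(htg, c(A = "A", B = "B", C = "C"), drop = "C")
  expect_setequal(rownames(gd$dist), c("A", "B"))
})

test_that("genus map can merge taxa across genera", {
  tw <- withr::local_tempfile(lines = "(((Ca:1,Cb:1):1,Cp:2):1,D:3);")
  ht <- read_host_tree(tw)
  # Cp is mapped into genus C (as with Chlamydophila under Chlamydia)
  g <- collapse_to_genus(ht, c(Ca = "C", Cb = "C", Cp = "C", D = "D"))
  expect_setequal(rownames(g$dist), c("C", "D"))
  expect_equal(g$dist["C", "D"], 4)  # MRCA of {Ca,Cb,Cp} at depth 1, D at 3
})

test_that("non-monophyletic genera collapse at the MRCA with a warning", {
  tw <- withr::local_tempfile(lines = "((A1:1,(B1:1,A2:1):1):1,C:3);")
  ht <- read_host_tree(tw)
  expect_warning(
    g <- collapse_to_genus(ht, c(A1 = "A", B1 = "B", A2 = "A", C = "C")),
    "B1"
  )
  expect_equal(g$dist["A", "C"], 4)  # A's MRCA sits at depth 1
})

test_that("host profiles count known-host genomes per cluster and sum per genome", {
  P <- matrix(c(1L, 1L, 1L, 0L,
                1L, 0L, 0L, 1L), 4, 2,
              dimnames = list(c("g1", "g2", "g3", "g4"), c("c1", "c2")))
  genomes <- data.frame(genome_id = paste0("g", 1:4),
                        host_genus = c("E", "E", "S", NA))
  prof <- host_profiles(P, genomes)
  expect_equal(prof$cluster["c1", ], c(E = 2, S = 1))
  expect_equal(prof$cluster["c2", ], c(E = 1, S = 0))
  # genome profile = sum over its clusters
  expect_equal(prof$genome["g1", ], c(E = 3, S = 1))
  # unknown-host genome contributes nothing but still gets a profile row
  expect_equal(unname(prof$genome["g4", ]), c(1, 0))
})

test_that("clusters found only in unknown-host genomes are flagged", {
  P <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  genomes <- data.frame(genome_id = c("g1", "g2"), host_genus = c("E", NA))
  expect_message(prof <- host_profiles(P, genomes), "unknown-host")
  expect_equal(prof$orphan_clusters, "c2")
})

test_that("MPD matches its defining examples", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(mpd(c(E = 7), matrix(0, 1, 1, dimnames = list("E", "E"))), 0)
  expect_equal(mpd(c(A = 1, B = 1), d), 4 * 0 + d["A", "B"] * 1,
               ignore_attr = TRUE)
  expect_equal(mpd(c(A = 3, B = 5), d), unname(d["A", "B"]))  # weights drop out
  expect_equal(mpd(c(A = 2, B = 1, C = 1), d), 3.2)
  expect_warning(na <- mpd(c(A = 0), d), "undefined")
  expect_true(is.na(na))
  expect_error(mpd(c(Z = 1), d), "Z")
})

test_that("MPD equals the brute-force double sum on random profile/tree pairs", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    tree <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
    ht <- host_tree(tree)
    profile <- stats::setNames(stats::rpois(n, 2), tree$tip.label)
    profile[sample(n, 1)] <- profile[sample(n, 1)] + 1  # ensure nonzero
    got <- mpd(profile, ht)
    expect_equal(got, brute_mpd(profile, ht$dist), tolerance = 1e-12)
    # invariant to uniform count scaling, bounded by tree diameter
    expect_equal(mpd(profile * 13, ht), got, tolerance = 1e-12)
    expect_lte(got, max(ht$dist))
  }
})

path3 <- function() {
  g <- igraph::make_graph(~ c1 - c2, c2 - c3)
  P <- matrix(0L, 2, 3, dimnames = list(c("G1", "G2"), c("c1", "c2", "c3")))
  genomes <- data.frame(genome_id = c("G1", "G2"), host_genus = c("E", "S"))
  d <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("E", "S"), c("E", "S")))
  list(g = g, P = P, genomes = genomes, d = d)
}

test_that("pair topology averages the rectangular gene submatrix", {
  x <- path3()
  x$P[cbind(c(1, 2), c(1, 3))] <- 1L  # G1={c1}, G2={c3}
  st <- pairwise_topology(x$g, x$P, x$genomes, x$d)
  expect_equal(st$mean_shortest_path, 2)
  expect_equal(st$mean_similarity, 1)  # N(c1)=N(c3)={c2}
  expect_equal(st$host_distance, 5)

  y <- path3()
  y$P[cbind(c(1, 1, 2, 2), c(1, 2, 2, 3))] <- 1L  # G1={c1,c2}, G2={c2,c3}
  st2 <- pairwise_topology(y$g, y$P, y$genomes, y$d)
  expect_equal(st2$mean_shortest_path, (1 + 2 + 0 + 1) / 4)
  # Jaccard: (c1,c2)=0, (c1,c3)=1, (c2,c2)=1, (c2,c3)=0
  expect_equal(st2$mean_similarity, 1 / 2)
})

test_that("unreachable gene pairs are excluded from the path mean and counted", {
  g <- igraph::make_graph(~ c1 - c2, c3 - c4)
  P <- matrix(0L, 2, 4, dimnames = list(c("G1", "G2"), paste0("c", 1:4)))
  P[1, c(1, 3)] <- 1L  # G1 = {c1, c3}
  P[2, c(2, 4)] <- 1L  # G2 = {c2, c4}
  genomes <- data.frame(genome_id = c("G1", "G2"), host_genus = c("E", "S"))
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("E", "S"), c("E", "S")))
  st <- pairwise_topology(g, P, genomes, d)
  expect_equal(st$n_unreachable, 2L)       # c1-c4 and c3-c2
  expect_equal(st$mean_shortest_path, 1)   # mean of the two finite cells
})

test_that("host-distance regression recovers exact and null relationships", {
  sp <- exp(seq(0.1, 2, length.out = 10))
  st <- data.frame(genome_a = "a", genome_b = "b",
                   mean_shortest_path = sp,
                   n_unreachable = 0L,
                   mean_similarity = exp(-seq(0.1, 2, length.out = 10)),
                   host_distance = 3 * log(sp) + 1)
  fits <- host_distance_regression(st)
  expect_equal(fits$shortest_path$r_squared, 1)
  expect_equal(fits$shortest_path$slope, 3)
  expect_equal(fits$similarity$slope, -3)

  set.seed(5)
  st$host_distance <- sample(st$host_distance)
  null_fit <- host_distance_regression(st)
  expect_lt(null_fit$shortest_path$r_squared, 0.5)

  st$mean_shortest_path <- rep(2, 10)
  expect_error(host_distance_regression(st), "zero variance")
})

test_that("zero-valued similarities are dropped from the log fit and counted", {
  st <- data.frame(genome_a = "a", genome_b = "b",
                   mean_shortest_path = c(1, 2, 3, 4),
                   n_unreachable = 0L,
                   mean_similarity = c(0, 0.5, 0.25, 0.125),
                   host_distance = c(9, 1, 2, 3))
  fits <- host_distance_regression(st)
  expect_equal(fits$similarity$n_dropped, 1L)
  expect_equal(fits$similarity$n_used, 3L)
})
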