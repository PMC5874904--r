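toy_prediction_setup <- function() {
  # 8 genomes over 2 genera; clusters c1 (shared, E-heavy), c2 (S-specific)
  genomes <- data.frame(
    genome_id = paste0("g", 1:8),
    host_genus = c("E", "E", "E", "E", "E", "S", "S", "S")
  )
  P <- matrix(0L, 8, 2, dimnames = list(genomes$genome_id, c("c1", "c2")))
  P[1:6, "c1"] <- 1L
  P[6:8, "c2"] <- 1L
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("E", "S"), c("E", "S")))
  prof <- host_profiles(P, genomes)$cluster
  list(genomes = genomes, P = P, d = d, prof = prof)
}

test_that("predicted host is the argmax of the leave-one-out profile", {
  x <- toy_prediction_setup()
  pred <- predict_hosts(x$P, x$prof, x$genomes, x$d)
  g1 <- pred[pred$genome_id == "g1", ]
  # c1 profile {E:5, S:1}; minus g1's own count -> {E:4, S:1}
  expect_equal(g1$predicted_genus, "E")
  expect_true(g1$correct)
  g6 <- pred[pred$genome_id == "g6", ]
  # g6 (S): LOO over c1 {E:5,S:0} + c2 {S:2} -> E wins: an honest error
  expect_equal(g6$predicted_genus, "E")
  expect_false(g6$correct)
})

test_that("the focal genome's own counts are never used", {
  x <- toy_prediction_setup()
  pred <- predict_hosts(x$P, x$prof, x$genomes, x$d)
  # recompute g7's profile with and without exclusion
  with_own <- x$prof["c2", ]
  loo <- with_own
  loo["S"] <- loo["S"] - 1
  expect_equal(unname(with_own["S"]), 3)
  expect_equal(unname(loo["S"]), 2)
  g7 <- pred[pred$genome_id == "g7", ]
  expect_equal(g7$predicted_genus, "S")
  expect_equal(g7$profile_mpd, 0)  # LOO profile is single-host
})

test_that("ties are flagged and broken toward the globally commoner genus", {
  genomes <- data.frame(genome_id = paste0("g", 1:7),
                        host_genus = c("E", "E", "E", "S", "S", "E", "S"))
  P <- matrix(0L, 7, 2, dimnames = list(genomes$genome_id, c("c1", "c2")))
  P[c(1, 2, 6), "c1"] <- 1L    # c1: E,E,E
  P[c(4, 5, 6), "c2"] <- 1L    # c2: S,S,E
  prof <- host_profiles(P, genomes)$cluster
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("E", "S"), c("E", "S")))
  pred <- predict_hosts(P, prof, genomes, d)
  g6 <- pred[pred$genome_id == "g6", ]
  # g6's LOO profile: c1 {E:2} + c2 {S:2} -> tie; E is globally commoner (4>3)
  expect_true(g6$tie)
  expect_equal(g6$predicted_genus, "E")
})

test_that("genomes sharing no retained genes get no prediction", {
  genomes <- data.frame(genome_id = c("g1", "g2", "g3"),
                        host_genus = c("E", "E", "S"))
  P <- matrix(c(1L, 1L, 0L, 0L, 0L, 1L), 3, 2,
              dimnames = list(genomes$genome_id, c("c1", "c2")))
  prof <- host_profiles(P, genomes)$cluster
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("E", "S"), c("E", "S")))
  pred <- predict_hosts(P, prof, genomes, d)
  g3 <- pred[pred$genome_id == "g3", ]
  expect_true(is.na(g3$predicted_genus))
  rep <- accuracy_report(pred)
  expect_equal(attr(rep, "n_scored"), 2L)
  expect_equal(attr(rep, "n_unpredicted"), 1L)
})

test_that("accuracy report tallies per-genus accuracy and modal errors", {
  pred <- data.frame(
    genome_id = paste0("g", 1:10),
    predicted_genus = c("E", "E", "E", "S", "E", "S", "S", "E", "Y", "S"),
    annotated_genus = c("E", "E", "E", "E", "E", "S", "S", "S", "S", "S"),
    correct = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    profile_mpd = 0, tie = FALSE
  )
  rep <- accuracy_report(pred)
  expect_equal(attr(rep, "overall_accuracy"), 0.7)
  e_row <- rep[rep$host_genus == "E", ]
  expect_equal(e_row$accuracy, 0.8)
  expect_equal(e_row$most_common_incorrect, "S")
  s_row <- rep[rep$host_genus == "S", ]
  expect_equal(s_row$most_common_incorrect, "E")
})

test_that("sister-genus confusion shows up as reciprocal modal errors", {
  set.seed(41)
  n <- 60
  truth <- rep(c("A", "B", "C"), each = n / 3)
  predicted <- truth
  # confusion concentrated between sisters A and B
  flip <- stats::runif(n) < 0.3 & truth != "C"
  predicted[flip] <- ifelse(truth[flip] == "A", "B", "A")
  pred <- data.frame(genome_id = paste0("g", 1:n),
                     predicted_genus = predicted, annotated_genus = truth,
                     correct = predicted == truth, profile_mpd = 0,
                     tie = FALSE)
  rep <- accuracy_report(pred)
  expect_equal(rep$most_common_incorrect[rep$host_genus == "A"], "B")
  expect_equal(rep$most_common_incorrect[rep$host_genus == "B"], "A")
})

test_that("logistic MPD fit matches glm and recovers a planted model", {
  set.seed(3)
  x <- stats::runif(500, 0, 3)
  y <- stats::rbinom(500, 1, stats::plogis(2 - 1.5 * x))
  d <- data.frame(predicted_genus = "E", correct = as.logical(y),
                  profile_mpd = x)
  fit <- logistic_mpd(d)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-8)
  expect_lt(fit$coefficients[["mpd"]], 0)
  expect_lt(abs(fit$coefficients[["mpd"]] - (-1.5)), 2 * fit$se[["mpd"]])
  # McFadden cross-check via deviances
  expect_equal(fit$mcfadden_r_squared,
               1 - as.numeric(stats::logLik(ref)) /
                 as.numeric(stats::logLik(stats::glm(y ~ 1,
                                                     family = stats::binomial()))),
               tolerance = 1e-8)
})

test_that("correctness independent of MPD gives a near-zero McFadden R2", {
  set.seed(8)
  d <- data.frame(predicted_genus = "E",
                  correct = stats::runif(400) < 0.6,
                  profile_mpd = stats::runif(400, 0, 3))
  fit <- logistic_mpd(d)
  expect_lt(fit$mcfadden_r_squared, 0.02)
})

test_that("degenerate logistic inputs are refused or flagged", {
  all_right <- data.frame(predicted_genus = "E", correct = TRUE,
                          profile_mpd = stats::runif(10))
  expect_error(logistic_mpd(all_right), "both correct and incorrect")

  # complete separation: correct iff MPD below a cut
  x <- seq(0.1, 2, length.out = 40)
  sep <- data.frame(predicted_genus = "E", correct = x < 1, profile_mpd = x)
  fit <- logistic_mpd(sep)
  expect_true(fit$separation)
  expect_equal(fit$method, "firth")
  expect_lt(fit$coefficients[["mpd"]], 0)
})

test_that("external genes map to their centroid's cluster or to none", {
  set.seed(2)
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cent_seq <- vapply(1:3, function(i)
    paste(sample(ab, 80, replace = TRUE), collapse = ""), character(1))
  centroids <- data.frame(gene_id = paste0("cent", 1:3),
                          cluster_id = paste0("C", 1:3),
                          sequence = cent_seq)
  queries <- data.frame(
    gene_id = c("hit", "miss"),
    sequence = c(cent_seq[2],
                 paste(rep("ACDY", 20), collapse = ""))
  )
  asg <- assign_external_genes(queries, centroids)
  expect_equal(asg$cluster_id[asg$gene_id == "hit"], "C2")
  expect_true(is.na(asg$cluster_id[asg$gene_id == "miss"]))
  expect_gt(asg$bitscore[1], 50)
  expect_lt(asg$evalue[1], 1e-5)

  # equidistant query: lower cluster id wins and the tie is logged
  dup <- centroids
  dup$sequence[3] <- dup$sequence[1]
  expect_message(
    tie <- assign_external_genes(data.frame(gene_id = "q",
                                            sequence = cent_seq[1]), dup),
    "tie"
  )
  expect_equal(tie$cluster_id, "C1")

  none <- assign_external_genes(queries, centroids[0, ])
  expect_true(all(is.na(none$cluster_id)))
})

test_that("enrichment fit flags outliers against the CI band", {
  # exactly collinear table: perfect fit, no outliers
  tab <- data.frame(subsystem = paste0("s", 1:5),
                    pre = c(10, 20, 30, 40, 50),
                    post = c(5, 10, 15, 20, 25))
  enr <- enrichment_outliers(tab)
  expect_equal(enr$r_squared, 1)
  expect_true(all(enr$table$direction == "none"))
  expect_lt(max(enr$table$ci_upper - enr$table$ci_lower), 1e-6)

  # r_squared is invariant to rescaling counts into frequencies
  tab2 <- data.frame(subsystem = paste0("s", 1:6),
                     pre = c(12, 25, 31, 47, 52, 8),
                     post = c(5, 11, 14, 20, 30, 2))
  a <- enrichment_outliers(tab2)
  tab3 <- transform(tab2, pre = pre / sum(pre), post = post / sum(post))
  b <- enrichment_outliers(tab3)
  expect_equal(a$r_squared, b$r_squared)

  # prediction band is wider than the mean-response band
  p <- enrichment_outliers(tab2, interval = "prediction")
  expect_true(all(p$table$ci_upper >= a$table$ci_upper))

  expect_error(enrichment_outliers(transform(tab2, pre = 10)), "variance")
})

test_that("annotation tables are validated and the Total row is dropped", {
  path <- withr::local_tempfile(lines = c(
    "subsystem\tpre\tpost", "alpha\t10\t5", "beta\t20\t10", "Total\t30\t15"
  ))
  tab <- read_annotation_table(path)
  expect_equal(nrow(tab), 2L)
  bad <- withr::local_tempfile(lines = c(
    "subsystem\tpre\tpost", "alpha\t10\t11"
  ))
  expect_error(read_annotation_table(bad), "alpha")
})
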