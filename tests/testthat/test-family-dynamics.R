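test_that("mirror-trajectory clusters are detected and split correctly", {
  x <- seq(-1, 1, length.out = 6)
  up <- 100 * (1.5 + x)
  m <- rbind(up, up * 1.3, up * 0.7, rev(up), rev(up) * 1.2, rev(up) * 0.9)
  dimnames(m) <- list(paste0("g", 1:6), paste0("s", 1:6))
  r <- compensation_test(m, family_id = "toy")
  within <- stats::cor(t(m), method = "spearman")
  expect_true(all(within[1:3, 1:3] == 1))
  expect_true(all(within[1:3, 4:6] == -1))
  expect_lt(r$p_raw, 0.05)
  expect_setequal(
    list(sort(r$expression_clusters$a), sort(r$expression_clusters$b)),
    list(c("g1", "g2", "g3"), c("g4", "g5", "g6")))
  expect_length(r$observed_correlations, 15)
  # 6 within-cluster and 9 cross-cluster pairs -> balanced score 2 * 6/15
  expect_equal(r$bimodality, 0.8)
})

test_that("the full-enumeration null is exactly centred at zero", {
  set.seed(61)
  m <- matrix(stats::rlnorm(4 * 6, 5, 1), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  r <- compensation_test(m)
  expect_length(r$null_correlations, 6 * factorial(6))  # 6 pairs x 720 orderings
  expect_equal(mean(r$null_correlations), 0, tolerance = 1e-12)
})

test_that("the test caps and samples orderings for many stages, reproducibly", {
  set.seed(62)
  m <- matrix(stats::rlnorm(3 * 8), 3, 8,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  r1 <- compensation_test(m, n_perm_cap = 100, seed = 5)
  r2 <- compensation_test(m, n_perm_cap = 100, seed = 5)
  expect_length(r1$null_correlations, 3 * 100)
  expect_identical(r1$null_correlations, r2$null_correlations)
})

test_that("degenerate families are skipped or trimmed with a warning", {
  m <- matrix(stats::rlnorm(12), 2, 6,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  expect_error(compensation_test(m), class = "family_skip")
  m2 <- rbind(m, g3 = rep(5, 6), g4 = stats::rlnorm(6))
  expect_warning(r <- compensation_test(m2), "constant")
  expect_equal(r$n_genes, 3)
  expect_error(compensation_test(m2[, 1:3]), "stages")
})

test_that("the screen corrects across reportable families only (Bonferroni formula)", {
  set.seed(63)
  fams <- c(replicate(4, make_compensated_family(8), simplify = FALSE),
            replicate(3, {
              m <- matrix(stats::rlnorm(8 * 6, 5, 0.6), 8, 6,
                          dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
              m
            }, simplify = FALSE),
            list(small = matrix(stats::rlnorm(4 * 6, 5, 0.6), 4, 6,
                                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))),
            list(tiny = matrix(stats::rlnorm(2 * 6), 2, 6,
                               dimnames = list(paste0("g", 1:2), paste0("s", 1:6)))))
  names(fams) <- c(paste0("comp", 1:4), paste0("null", 1:3), "small", "tiny")
  scr <- compensation_screen(fams, alpha = 0.05)
  # the 4-gene family is tested but not in the corrected report
  expect_true("small" %in% names(scr$results))
  expect_false("small" %in% scr$table$family_id)
  expect_true("tiny" %in% names(scr$skipped))
  m_eff <- nrow(scr$table)
  expect_identical(m_eff, 7L)
  expect_equal(scr$table$p_corrected,
               pmin(1, scr$table$p_raw * m_eff), tolerance = 1e-12)
  expect_true(all(scr$table$significant[grep("comp", scr$table$family_id)]))
  bh <- compensation_screen(fams, correction = "bh", alpha = 0.05)
  expect_true(all(bh$table$p_corrected <= scr$table$p_corrected + 1e-12))
})

test_that("gap chaining matches the worked examples", {
  # gaps 5 kb, 5 kb, 20 kb -> one cluster of three, one singleton
  starts <- c(0, 72 + 5000, (72 + 5000) * 2, (72 + 5000) * 2 + 72 + 20000)
  tg <- make_trna(starts, ids = paste0("g", 1:4))
  cs <- define_clusters(tg)
  expect_identical(cs$n_clusters, 1L)
  expect_setequal(cs$clusters[[1]], c("g1", "g2", "g3"))
  # all genes > 7.5 kb apart -> no clusters
  expect_identical(define_clusters(make_trna(c(0, 10000, 20000)))$n_clusters, 0L)
  # same coordinates, different chromosomes -> not clustered
  tg2 <- rbind(make_trna(0, chrom = "chr1", ids = "a"),
               make_trna(0, chrom = "chr2", ids = "b"))
  expect_identical(define_clusters(tg2)$n_clusters, 0L)
})

test_that("chaining agrees with the brute-force all-pairs oracle on random layouts", {
  set.seed(64)
  for (i in 1:100) {
    tg <- data.frame(
      gene_id = sprintf("g%02d", 1:50),
      chrom = sample(paste0("chr", 1:3), 50, TRUE),
      start = sample.int(3e5, 50), stringsAsFactors = FALSE)
    tg$end <- tg$start + 72L
    got <- cluster_signature(define_clusters(tg))
    expect_identical(unname(got), unname(brute_force_clusters(tg)))
  }
  # clusters partition their genes: no gene in two clusters
  ds <- default_dataset()
  cs <- define_clusters(ds$trna_genes)
  expect_identical(anyDuplicated(unlist(cs$clusters)), 0L)
})

test_that("family-pure clustered layouts give near-total colocalization and a tiny p", {
  ds <- simulate_dataset(sim_config(seed = 71, n_pc_genes = 50,
                                    n_trna_genes = 120, n_families = 20,
                                    clustered_fraction = 1))
  r <- cluster_randomization_test(ds$trna_genes, n_rand = 300, seed = 2)
  singleton <- sum(table(ds$trna_genes$family_id) == 1)
  expect_gt(r$statistic, 100 * (1 - (singleton + 1) / 20))
  expect_lt(r$p_binomial, 1e-6)
  expect_lt(r$p_empirical, 0.01)
  r2 <- cluster_randomization_test(ds$trna_genes, n_rand = 300, seed = 2)
  expect_identical(r$statistic, r2$statistic)
  expect_identical(r$p_binomial, r2$p_binomial)
})

test_that("the randomization statistic is invariant to chromosome naming and gene order", {
  ds <- small_dataset()
  tg <- ds$trna_genes
  r1 <- cluster_randomization_test(tg, n_rand = 100, seed = 3)
  tg2 <- tg[sample(nrow(tg)), , drop = FALSE]
  tg2$chrom <- paste0("scaffold_", tg2$chrom)
  r2 <- cluster_randomization_test(tg2, n_rand = 100, seed = 3)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(sort(names(r1$per_family)), sort(names(r2$per_family)))
})

test_that("no clusters means a zero statistic and a skipped test", {
  tg <- make_trna(c(0, 1e5, 2e5, 3e5), family = "Gly-GCC")
  expect_warning(r <- cluster_randomization_test(tg, n_rand = 10), "skipped")
  expect_identical(r$statistic, 0)
  expect_true(is.na(r$p_binomial))
})

test_that("clustering percentages compare as expected between family groups", {
  sig <- stats::setNames(rep(c(TRUE, FALSE), each = 6), paste0("f", 1:12))
  same <- stats::setNames(rep(c(10, 60, 90), 4), paste0("f", 1:12))
  r <- compensation_vs_clustering(sig, same)
  expect_gt(r$p, 0.9)
  disjoint <- stats::setNames(rep(c(0, 100), each = 6), paste0("f", 1:12))
  r2 <- compensation_vs_clustering(sig, disjoint)
  expect_lt(r2$p, 0.05)
  expect_error(compensation_vs_clustering(sig[1:3], same[1:3]), ">= 2")
})
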