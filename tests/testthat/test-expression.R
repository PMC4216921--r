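mk_cm <- function(counts, samples, stages) {
  dimnames(counts) <- list(sprintf("g%03d", seq_len(nrow(counts))), samples)
  count_matrix(counts, stages)
}

test_that("expression calling requires the threshold in every replicate of one condition", {
  samples <- c("liver.E15.5.rep1", "liver.E15.5.rep2",
               "liver.P4.rep1", "liver.P4.rep2")
  cnt <- rbind(c(12L, 11L, 0L, 0L),   # expressed: both reps >= 10 at E15.5
               c(12L, 9L, 12L, 9L),   # never both reps >= 10
               c(0L, 0L, 10L, 10L))   # expressed at P4
  cm <- mk_cm(cnt, samples, c("E15.5", "P4"))
  expect_setequal(call_expressed_trnas(cm), c("g001", "g003"))
  expect_setequal(call_expressed_trnas(cm, min_reads = 0),
                  rownames(cm$counts))
  cm1 <- mk_cm(cnt[, 1:3], samples[1:3], c("E15.5", "P4"))
  expect_error(call_expressed_trnas(cm1), "single replicate")
})

test_that("median-of-ratios size factors behave on symmetric and scaled samples", {
  cnt <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3,
                dimnames = list(c("a", "b", "c"),
                                c("x.S.rep1", "x.S.rep2")))
  sf <- normalize_counts(count_matrix(cnt, "S"))$size_factors
  expect_equal(unname(sf), c(1, 1))
  cnt2 <- cnt; cnt2[, 2] <- cnt[, 1] * 2L
  sf2 <- normalize_counts(count_matrix(cnt2, "S"))$size_factors
  expect_equal(unname(sf2[2] / sf2[1]), 2)
  # agrees with the DESeq reference implementation
  ds <- small_dataset()
  ours <- normalize_counts(ds$trna_counts)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(ds$trna_counts$counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("normalization falls back to total counts when no gene is all-positive", {
  cnt <- matrix(c(4L, 0L, 0L, 8L), 2,
                dimnames = list(c("a", "b"), c("x.S.rep1", "x.S.rep2")))
  expect_warning(em <- normalize_counts(count_matrix(cnt, "S")), "fallback|total-count")
  expect_equal(unname(em$size_factors), c(4, 8) / sqrt(32))
  zero <- matrix(0L, 2, 2, dimnames = dimnames(cnt))
  expect_error(normalize_counts(count_matrix(zero, "S")), "all-zero")
})

test_that("identical groups give null DE results and BH keeps p_adjusted >= p", {
  set.seed(31)
  half <- matrix(rnbinom(300, mu = 80, size = 20), 150)
  cnt <- cbind(half, half)
  dimnames(cnt) <- list(sprintf("g%03d", 1:150),
                        c("a.S1.rep1", "a.S1.rep2", "a.S2.rep1", "a.S2.rep2"))
  res <- de_test(count_matrix(cnt, c("S1", "S2")), "S1", "S2", "a")
  expect_lt(max(abs(res$log2_fold_change), na.rm = TRUE), 1e-3)
  expect_gt(min(res$p_value, na.rm = TRUE), 0.99)
  expect_false(any(res$significant))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12, na.rm = TRUE))
  # BH is monotone in the p-value ranks
  ok <- !is.na(res$p_adjusted)
  ord <- order(res$p_value[ok])
  expect_true(!is.unsorted(res$p_adjusted[ok][ord]))
})

test_that("a strong true effect is detected and all-zero genes are reported NA", {
  set.seed(32)
  mu <- rlnorm(200, log(100), 0.5)
  cnt <- cbind(matrix(rnbinom(400, mu = mu, size = 20), 200),
               matrix(rnbinom(400, mu = mu * rep(c(8, 1), c(20, 180)), size = 20), 200))
  cnt[1, ] <- 0L  # degenerate gene
  dimnames(cnt) <- list(sprintf("g%03d", 1:200),
                        c("a.S1.rep1", "a.S1.rep2", "a.S2.rep1", "a.S2.rep2"))
  res <- de_test(count_matrix(cnt, c("S1", "S2")), "S1", "S2", "a")
  expect_true(is.na(res$p_value[res$gene_id == "g001"]))
  expect_false(res$significant[res$gene_id == "g001"])
  hits <- res$gene_id[res$significant]
  expect_gt(mean(sprintf("g%03d", 2:20) %in% hits), 0.8)
})

test_that("an external DE table is validated and thresholded", {
  tab <- data.frame(gene_id = c("g1", "g2"),
                    log2_fold_change = c(2, 0),
                    p_value = c(4e-4, 0.6),
                    p_adjusted = c(4e-4, 0.6))
  res <- de_test(NULL, "S1", "S2", "liver", alpha = 0.001, de_table = tab)
  expect_identical(res$significant, c(TRUE, FALSE))
  expect_identical(res$tissue, c("liver", "liver"))
  expect_error(de_test(NULL, "S1", "S2", "liver", de_table = tab[, 1:2]),
               "columns")
})

test_that("spearman PCA separates duplicated sample groups and reports variance fractions", {
  set.seed(41)
  base_a <- rlnorm(300, 4, 1); base_b <- rlnorm(300, 4, 1)
  jitter <- function(v) v * exp(rnorm(300, 0, 0.05))
  vals <- cbind(jitter(base_a), jitter(base_a), jitter(base_a),
                jitter(base_b), jitter(base_b), jitter(base_b))
  cnt <- matrix(as.integer(round(vals)), 300,
                dimnames = list(sprintf("g%03d", 1:300),
                                c("a.S1.rep1", "a.S1.rep2", "a.S2.rep1",
                                  "b.S1.rep1", "b.S1.rep2", "b.S2.rep1")))
  em <- normalize_counts(count_matrix(cnt, c("S1", "S2")))
  p <- spearman_pca(em)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  pc1 <- p$scores[, 1]
  expect_true(all(pc1[1:3] > 0) != all(pc1[4:6] > 0))  # one group each side
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) || max(pc1[4:6]) < min(pc1[1:3]))
  # invariant to per-sample monotone transforms
  em2 <- em; em2$values <- em$values^1.7
  p2 <- spearman_pca(em2)
  expect_equal(p$scores, p2$scores, tolerance = 1e-12)
  # the of-remaining convention: first entries match, PC2 is rescaled
  expect_equal(p$variance_fraction_of_remaining[1], p$variance_fraction[1])
  expect_equal(p$variance_fraction_of_remaining[2],
               p$variance_fraction[2] / (1 - p$variance_fraction[1]))
})

test_that("spearman PCA names offending constant samples", {
  cnt <- matrix(c(1L, 1L, 1L, 5L, 2L, 9L, 4L, 8L, 2L), 3,
                dimnames = list(c("a", "b", "c"),
                                c("x.S.rep1", "x.S.rep2", "x.S.rep3")))
  em <- suppressWarnings(normalize_counts(count_matrix(cnt, "S")))
  expect_error(spearman_pca(em), "x.S.rep1")
})
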