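code <- load_genetic_code()

test_that("count_codons enumerates in-frame triplets", {
  expect_identical(count_codons("ATGGCTTAA"),
                   c(ATG = 1L, GCT = 1L, TAA = 1L))
  expect_identical(count_codons("AAAAAA"), c(AAA = 2L))
  expect_error(count_codons(""), "multiple of 3")
  expect_error(count_codons("ATGG"), "multiple of 3")
})

test_that("codon count tables agree with per-gene counting and row sums", {
  ds <- small_dataset()
  cc <- codon_count_table(ds$transcripts, code)
  expect_identical(unname(rowSums(cc)),
                   as.numeric(ds$transcripts$length_nt / 3))
  g <- ds$transcripts[7, ]
  by_hand <- count_codons(g$cds)
  expect_equal(unname(as.numeric(cc[g$gene_id, names(by_hand)])),
               unname(as.numeric(by_hand)))
  expect_true(all(cc[g$gene_id, setdiff(code$codons, names(by_hand))] == 0))
})

test_that("weighted usage matches the hand-enumeration oracle", {
  # g1: "AAAAAA", weight (expr per kb) 10 -> U(AAA) = 2 * 10 = 20
  # g2: "AAGAAGAAG", weight 5            -> U(AAG) = 3 * 5  = 15
  tx <- data.frame(gene_id = c("g1", "g2"),
                   cds = c("AAAAAA", "AAGAAGAAG"),
                   stringsAsFactors = FALSE)
  cc <- codon_count_table(tx, code)
  lens <- c(g1 = 6, g2 = 9)
  expr <- c(g1 = 10 * (6 / 1000), g2 = 5 * (9 / 1000))
  U <- weighted_usage(cc, expr, lens, "codon", code)
  expect_equal(unname(U$values[["AAA"]]), 20)
  expect_equal(unname(U$values[["AAG"]]), 15)
  expect_equal(sum(U$values), 35)
  # amino-acid level aggregates through the code: K = AAA + AAG
  Ua <- weighted_usage(cc, expr, lens, "amino_acid", code)
  expect_equal(unname(Ua$values[["K"]]), 35)
  expect_error(weighted_usage(cc, expr["g1"], lens), "missing")
})

test_that("stop codons never enter usage profiles", {
  tx <- data.frame(gene_id = "g1", cds = "ATGTAA", stringsAsFactors = FALSE)
  U <- weighted_usage(codon_count_table(tx, code), c(g1 = 1), c(g1 = 6))
  expect_length(U$values, 61)
  expect_false(any(code$stop_codons %in% names(U$values)))
  expect_equal(sum(U$values > 0), 1)
})

test_that("relative usage normalizes and rejects zero totals", {
  up <- usage_profile(c(AAA = 2, AAG = 2), "codon")
  r <- relative_usage(up)
  expect_equal(unname(r$values), c(0.5, 0.5))
  expect_true(r$normalized)
  expect_equal(unname(relative_usage(usage_profile(c(ATG = 7), "codon"))$values), 1)
  expect_error(relative_usage(usage_profile(c(AAA = 0), "codon")), "zero")
})

test_that("relative profiles are scale invariant and sum to one", {
  ds <- small_dataset()
  cc <- codon_count_table(ds$transcripts, code)
  lens <- stats::setNames(ds$transcripts$length_nt, ds$transcripts$gene_id)
  expr <- stats::setNames(stats::runif(nrow(cc), 1, 100), rownames(cc))
  r1 <- relative_usage(weighted_usage(cc, expr, lens, "codon", code))
  r2 <- relative_usage(weighted_usage(cc, expr * 2, lens, "codon", code))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
  expect_equal(sum(r1$values), 1, tolerance = 1e-9)
  expect_true(all(r1$values >= 0))
  # amino-acid profile equals the code-aggregated codon profile
  ra <- relative_usage(weighted_usage(cc, expr, lens, "amino_acid", code))
  agg <- vapply(split(r1$values, unname(code$table[names(r1$values)])),
                sum, numeric(1))
  expect_equal(ra$values[names(agg)], agg, tolerance = 1e-12)
})

test_that("equal expression recovers the genomic codon frequency exactly", {
  ds <- small_dataset()
  cc <- codon_count_table(ds$transcripts, code)
  lens <- stats::setNames(ds$transcripts$length_nt, ds$transcripts$gene_id)
  # weights cancel the length normalization -> plain genomic frequency
  expr <- lens / 1000
  r <- relative_usage(weighted_usage(cc, expr, lens, "codon", code))
  genomic <- colSums(cc[, code$sense_codons])
  expect_equal(r$values, genomic / sum(genomic), tolerance = 1e-12)
})

test_that("anticodon abundance sums member genes and isotypes sum families", {
  tg <- rbind(make_trna(c(0, 10000), family = "Gly-GCC", ids = c("a", "b")),
              make_trna(20000, family = "Lys-TTT", ids = "c"))
  ab <- anticodon_abundance(c(a = 3, b = 7, c = 10), tg, "anticodon")
  expect_equal(unname(ab$values[c("Gly-GCC", "Lys-TTT")]), c(0.5, 0.5))
  tg2 <- rbind(make_trna(0, family = "Leu-CAG", ids = "x"),
               make_trna(10000, family = "Leu-AAG", ids = "y"),
               make_trna(20000, family = "Ser-AGA", ids = "z"))
  iso <- anticodon_abundance(c(x = 2, y = 3, z = 5), tg2, "isotype")
  expect_equal(unname(iso$values[["Leu"]]), 0.5)
  expect_error(anticodon_abundance(c(q = 1), tg), "annotation")
  # selenocysteine genes are excluded from abundance
  tg$excluded[tg$gene_id == "a"] <- TRUE
  ab2 <- anticodon_abundance(c(a = 3, b = 7, c = 10), tg, "anticodon")
  expect_equal(unname(ab2$values[["Gly-GCC"]]), 7 / 17)
})

test_that("interface correlation is rank invariant and filters unencoded families", {
  pairing <- codon_family_pairing(code)
  codons <- code$sense_codons[1:12]
  u <- stats::setNames(seq(0.01, 0.12, 0.01), codons)
  cu <- usage_profile(u / sum(u), "codon", normalized = TRUE)
  fams <- pairing[codons]
  av <- stats::setNames(as.numeric(u^2), fams)   # monotone transform
  au <- usage_profile(av / sum(av), "anticodon", normalized = TRUE)
  r <- interface_correlation(cu, au, pairing)
  expect_equal(r$rho, 1)
  expect_identical(r$n_pairs, 12L)
  # dropping families shrinks the pair set when exclusion is on
  au2 <- usage_profile(au$values[1:8] / sum(au$values[1:8]), "anticodon",
                       normalized = TRUE)
  expect_identical(interface_correlation(cu, au2, pairing)$n_pairs, 8L)
  expect_identical(
    interface_correlation(cu, au2, pairing, exclude_unencoded = FALSE)$n_pairs,
    12L)
  expect_error(interface_correlation(
    usage_profile(u[1:3] / sum(u[1:3]), "codon", normalized = TRUE), au, pairing),
    ">= 4")
})

test_that("expression partition splits deterministically at the quantiles", {
  expr <- stats::setNames(1:10, sprintf("g%02d", 1:10))
  p <- partition_by_expression(expr, 0.1, 0.9)
  expect_identical(p$low, "g01")
  expect_identical(p$high, "g10")
  # boundary ties break by gene id
  expr2 <- stats::setNames(rep(1, 10), sprintf("g%02d", 10:1))
  p2 <- partition_by_expression(expr2, 0.1, 0.9)
  expect_identical(p2$low, "g01")
  expect_identical(p2$high, "g10")
  expect_error(partition_by_expression(expr, 0.5, 0.5), "q_low")
  expect_error(partition_by_expression(expr, 0.001, 0.9), "empty")
})
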