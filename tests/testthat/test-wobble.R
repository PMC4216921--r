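code <- load_genetic_code()
all_families <- unname(codon_family_pairing(code))

test_that("wobble rules always include the Watson-Crick partner", {
  rules <- wobble_rules()
  expect_true("C" %in% rules$G)
  expect_true("A" %in% rules$T)
  expect_true("T" %in% rules$A)   # inosine reads U, C, A
  expect_identical(rules$C, "G")
  expect_error(wobble_rules(list(G = "T")), "Watson-Crick")
  custom <- wobble_rules(list(A = c("T", "C")))  # drop the A:I pairing
  expect_identical(custom$A, c("T", "C"))
})

test_that("orphan codons are those whose Watson-Crick anticodon is unencoded", {
  expect_length(find_orphan_codons(code, all_families), 0)
  # removing Gly-GCC (anticodon GCC reads codon GGC) orphans exactly GGC
  expect_identical(find_orphan_codons(code, setdiff(all_families, "Gly-GCC")),
                   "GGC")
})

test_that("orphans are assigned within-isotype with the G > A > U > C preference", {
  # orphan GGC (Gly, third base C): G34 candidate absent, A34 family present
  enc <- c("Gly-ACC", "Gly-CCC", "Gly-TCC")
  dm <- assign_wobble_decoders("GGC", enc, code = code)
  expect_identical(unname(dm$codon_to_family[["GGC"]]), "Gly-ACC")
  # with the G34 family present it wins
  dm2 <- assign_wobble_decoders("GGC", c(enc, "Gly-GCC"), code = code)
  expect_identical(unname(dm2$codon_to_family[["GGC"]]), "Gly-GCC")
  # orphan ending G with only the U34 partner -> that family
  # (Lys AAG: WC anticodon CTT; U34 partner is Lys-TTT)
  dm3 <- assign_wobble_decoders("AAG", "Lys-TTT", code = code)
  expect_identical(unname(dm3$codon_to_family[["AAG"]]), "Lys-TTT")
  # orphan whose isotype has no encoded family is unmatchable
  dm4 <- assign_wobble_decoders("TGG", "Lys-TTT", code = code)
  expect_identical(dm4$unmatchable, "TGG")
  expect_false("TGG" %in% names(dm4$codon_to_family))
})

test_that("assignments never cross isotype boundaries and each codon has one decoder", {
  enc <- sample(all_families, 40)
  orphans <- find_orphan_codons(code, enc)
  dm <- assign_wobble_decoders(orphans, enc, code = code)
  for (cdn in names(dm$codon_to_family)) {
    fam <- dm$codon_to_family[[cdn]]
    expect_identical(sub("-.*", "", fam),
                     unname(codonbalance:::AA_THREE[unname(code$table[cdn])]))
  }
  served <- unlist(dm$family_to_codons, use.names = FALSE)
  expect_identical(anyDuplicated(served), 0L)
})

test_that("abundance redistribution is demand-proportional and conserved", {
  dmap <- structure(list(
    codon_to_family = c(GGA = "Gly-TCC", GGG = "Gly-TCC"),
    family_to_codons = list("Gly-TCC" = c("GGA", "GGG")),
    unmatchable = character(0)), class = "decoding_map")
  ab <- usage_profile(c("Gly-TCC" = 10), "anticodon")
  demand <- usage_profile(c(GGA = 0.75, GGG = 0.25), "codon", normalized = TRUE)
  av <- redistribute_abundance(ab, dmap, demand)
  expect_equal(unname(av[c("GGA", "GGG")]), c(7.5, 2.5))
  # zero demand everywhere -> equal split
  zero <- usage_profile(c(GGA = 0, GGG = 0, AAA = 1), "codon", normalized = TRUE)
  expect_equal(unname(redistribute_abundance(ab, dmap, zero)[c("GGA", "GGG")]),
               c(5, 5))
  # single-codon family passes its abundance through unchanged
  dmap1 <- structure(list(codon_to_family = c(AAA = "Lys-TTT"),
                          family_to_codons = list("Lys-TTT" = "AAA"),
                          unmatchable = character(0)), class = "decoding_map")
  expect_equal(unname(redistribute_abundance(
    usage_profile(c("Lys-TTT" = 4), "anticodon"), dmap1, demand)), 4)
})

test_that("redistribution conserves total abundance on random family sets", {
  set.seed(91)
  for (i in 1:50) {
    enc <- sample(all_families, sample(20:47, 1))
    ab <- stats::setNames(stats::runif(length(enc)), enc)
    ab <- usage_profile(ab / sum(ab), "anticodon", normalized = TRUE)
    d <- stats::runif(61)
    demand <- usage_profile(stats::setNames(d / sum(d), code$sense_codons),
                            "codon", normalized = TRUE)
    dm <- assign_wobble_decoders(find_orphan_codons(code, enc), enc, code = code)
    av <- redistribute_abundance(ab, dm, demand)
    mapped <- intersect(names(dm$family_to_codons), names(ab$values))
    expect_lt(abs(sum(av) - sum(ab$values[mapped])), 1e-9)
  }
})

test_that("with no orphan codons the corrected correlation equals the uncorrected one", {
  set.seed(92)
  ab <- stats::setNames(stats::runif(61), all_families)
  ab <- usage_profile(ab / sum(ab), "anticodon", normalized = TRUE)
  d <- stats::runif(61)
  cu <- usage_profile(stats::setNames(d / sum(d), code$sense_codons),
                      "codon", normalized = TRUE)
  plain <- interface_correlation(cu, ab)
  corrected <- wobble_corrected_correlation(cu, ab, code = code)
  expect_length(corrected$orphans, 0)
  expect_equal(corrected$rho, plain$rho, tolerance = 1e-12)
  expect_identical(corrected$n_pairs, plain$n_pairs)
})

test_that("mouse-like family sets give a positive, broadly comparable corrected correlation", {
  ds <- default_dataset()
  enc <- unique(ds$trna_genes$family_id)
  expect_equal(length(find_orphan_codons(code, enc)), 61 - length(enc))
  pair_rho <- function(seed) {
    d <- simulate_dataset(sim_config(seed = seed))
    ex <- call_expressed_trnas(d$trna_counts)
    me <- normalize_counts(d$mrna_counts)
    te <- normalize_counts(d$trna_counts)
    cc <- codon_count_table(d$transcripts, code)
    lens <- stats::setNames(d$transcripts$length_nt, d$transcripts$gene_id)
    sel <- me$samples$tissue == "liver" & me$samples$stage == "E15.5"
    cu <- relative_usage(weighted_usage(
      cc, rowMeans(me$values[, sel, drop = FALSE]), lens, "codon", code))
    ta <- anticodon_abundance(rowMeans(te$values[, sel, drop = FALSE])[ex],
                              d$trna_genes, "anticodon")
    c(plain = interface_correlation(cu, ta)$rho,
      corrected = wobble_corrected_correlation(cu, ta, code = code)$rho)
  }
  rhos <- vapply(1:10, pair_rho, numeric(2))
  expect_true(all(rhos["corrected", ] > 0))
  drop <- stats::median(rhos["corrected", ] - rhos["plain", ])
  expect_gte(drop, -0.2)
  expect_lte(drop, 0.05)
})
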