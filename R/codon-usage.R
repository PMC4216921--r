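# Expression-weighted codon and amino-acid usage from coding sequences;
# anticodon isoacceptor / isotype abundance from tRNA quantifications; the
# Spearman correlation across the codon-anticodon interface.

#' Count in-frame codons in one coding sequence
#'
#' Non-overlapping triplets in reading frame; the raw table keeps stop
#' codons (downstream usage computations restrict to sense codons).
#'
#' @param cds upper-case DNA string, length divisible by 3.
#' @return Named integer vector of observed codon counts.
#' @export
count_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0 || n %% 3L != 0L) {
    stopf("CDS length must be a positive multiple of 3 (got %d)", n)
  }
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- table(codons)
  stats::setNames(as.integer(tab), names(tab))
}

#' Codon count table for a set of transcripts
#'
#' @param transcripts data.frame with `gene_id` and `cds`.
#' @param code a [load_genetic_code()] object.
#' @return Integer matrix genes x 64 codons; each row sums to CDS length / 3.
#' @export
codon_count_table <- function(transcripts, code = load_genetic_code()) {
  if (any(nchar(transcripts$cds) %% 3L != 0L)) {
    stopf("all CDS lengths must be divisible by 3")
  }
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(transcripts$cds), width = 3, step = 3
  )
  rownames(m) <- transcripts$gene_id
  m[, code$codons, drop = FALSE]
}

#' Expression-weighted codon or amino-acid usage
#'
#' For each key k, `U_k = sum_g count_{g,k} * expr_g / (length_g / 1000)`:
#' per-gene codon counts weighted by the gene's library-size-normalized
#' expression per kilobase of counted CDS, summed over genes. Stop codons
#' are excluded; at the amino-acid level codon values are aggregated through
#' the genetic code.
#'
#' @param codon_counts genes x codons matrix ([codon_count_table()]).
#' @param expr named per-gene expression (already library-size normalized).
#' @param lengths named per-gene CDS length in nt; defaults to 3x row sums
#'   of `codon_counts`.
#' @param level `"codon"` or `"amino_acid"`.
#' @param code a [load_genetic_code()] object.
#' @return Unnormalized [usage_profile()] over the 61 sense codons or 20
#'   amino acids.
#' @export
weighted_usage <- function(codon_counts, expr, lengths = NULL,
                           level = c("codon", "amino_acid"),
                           code = load_genetic_code()) {
  level <- match.arg(level)
  genes <- rownames(codon_counts)
  missing <- setdiff(genes, names(expr))
  if (length(missing) > 0) {
    stopf("genes missing from expression vector: %s%s",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  }
  if (is.null(lengths)) {
    lengths <- stats::setNames(3 * rowSums(codon_counts), genes)
  }
  w <- unname(expr[genes]) / (unname(lengths[genes]) / 1000)
  U <- colSums(codon_counts[, code$sense_codons, drop = FALSE] * w)
  if (level == "amino_acid") {
    aa <- unname(code$table[code$sense_codons])
    U <- vapply(split(U, aa), sum, numeric(1))
    U <- U[code$amino_acids]
  }
  usage_profile(U, kind = if (level == "codon") "codon" else "amino_acid",
                normalized = FALSE)
}

#' Normalize a usage profile to relative usage
#'
#' `u_i = U_i / sum_j U_j`.
#'
#' @param up a [usage_profile()].
#' @return The normalized profile (sums to 1 within 1e-9).
#' @export
relative_usage <- function(up) {
  stopifnot(inherits(up, "usage_profile"))
  total <- sum(up$values)
  if (total <= 0) stopf("cannot normalize a zero usage profile")
  usage_profile(up$values / total, kind = up$kind, normalized = TRUE)
}

#' Anticodon isoacceptor or isotype abundance from tRNA expression
#'
#' Family abundance is the sum of expression of the family's member genes,
#' normalized to relative abundance; the isotype level further sums families
#' by amino acid. Selenocysteine genes are excluded.
#'
#' @param trna_expr named per-gene expression over the expressed tRNA set.
#' @param trna_genes tRNA annotation data.frame (needs `gene_id`,
#'   `family_id`, `isotype`, `excluded`).
#' @param level `"anticodon"` or `"isotype"`.
#' @return Normalized [usage_profile()].
#' @export
anticodon_abundance <- function(trna_expr, trna_genes,
                                level = c("anticodon", "isotype")) {
  level <- match.arg(level)
  idx <- match(names(trna_expr), trna_genes$gene_id)
  if (anyNA(idx)) {
    stopf("tRNA genes without annotation/family: %s",
          paste(names(trna_expr)[is.na(idx)], collapse = ", "))
  }
  keep <- !trna_genes$excluded[idx]
  expr <- trna_expr[keep]; idx <- idx[keep]
  key <- if (level == "anticodon") trna_genes$family_id[idx] else trna_genes$isotype[idx]
  A <- vapply(split(unname(expr), key), sum, numeric(1))
  total <- sum(A)
  if (total <= 0) stopf("total tRNA expression is zero")
  usage_profile(A / total, kind = level, normalized = TRUE)
}

#' Spearman correlation across the codon-anticodon interface
#'
#' Correlates relative codon usage with the relative abundance of each
#' codon's Watson-Crick anticodon family. Codons whose anticodon family is
#' not genomically encoded (absent from the abundance profile) are excluded
#' when `exclude_unencoded = TRUE`, otherwise counted as zero abundance.
#'
#' @param codon_u codon-level [usage_profile()].
#' @param anticodon_u anticodon-level [usage_profile()].
#' @param pairing named map codon -> family id ([codon_family_pairing()]).
#' @param exclude_unencoded drop codons with no encoded anticodon family.
#' @return list with `rho`, `p`, `n_pairs`.
#' @export
interface_correlation <- function(codon_u, anticodon_u,
                                  pairing = codon_family_pairing(),
                                  exclude_unencoded = TRUE) {
  codons <- intersect(names(codon_u$values), names(pairing))
  fam <- pairing[codons]
  ab <- anticodon_u$values[fam]
  if (exclude_unencoded) {
    keep <- !is.na(ab)
    codons <- codons[keep]; ab <- ab[keep]
  } else {
    ab[is.na(ab)] <- 0
  }
  if (length(codons) < 4) stopf("need >= 4 codon/anticodon pairs, got %d", length(codons))
  ct <- suppressWarnings(
    stats::cor.test(unname(codon_u$values[codons]), unname(ab),
                    method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = length(codons))
}

#' Split genes into high- and low-expression sets by quantile
#'
#' Deterministic split: genes are ordered by expression with ties broken by
#' gene id, the bottom `floor(n * q_low)` form the low set and the top
#' `n - floor(n * q_high)` the high set.
#'
#' @param expr named per-gene expression.
#' @param q_low,q_high quantile cutoffs, `0 <= q_low < q_high <= 1`.
#' @return list with `high` and `low` gene-id vectors.
#' @export
partition_by_expression <- function(expr, q_low = 0.1, q_high = 0.9) {
  if (!(q_low >= 0 && q_high <= 1 && q_low < q_high)) {
    stopf("need 0 <= q_low < q_high <= 1")
  }
  n <- length(expr)
  ord <- names(expr)[order(unname(expr), names(expr))]
  n_low <- floor(n * q_low)
  n_high <- n - floor(n * q_high)
  if (n_low < 1 || n_high < 1) stopf("quantile split leaves an empty partition")
  list(high = sort(ord[(n - n_high + 1):n]), low = sort(ord[seq_len(n_low)]))
}
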