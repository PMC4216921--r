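# Shuffled-transcriptome null models: background distributions of codon /
# amino-acid usage and anticodon / isotype abundance obtained by randomly
# rearranging expression values across genes, and the comparison of an
# observed codon-anticodon correlation against that background.

#' Shuffle expression values across genes
#'
#' Randomly rearranges the expression values across genes, producing a
#' permutation: the multiset of assigned values equals the input multiset.
#' In `"all_annotated"` mode the values are first padded with zeros up to
#' the size of the annotated universe, so non-expressed genes can receive an
#' (often zero) expression value and expressed totals are preserved.
#'
#' @param expr named per-gene expression vector.
#' @param universe `"expressed"` (permute within `names(expr)`) or
#'   `"all_annotated"` (permute the zero-padded multiset over `genes_all`).
#' @param genes_all gene ids of the annotated universe (required and must be
#'   a superset of `names(expr)` in `"all_annotated"` mode).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return Named per-gene expression vector over the chosen universe.
#' @export
shuffle_expression <- function(expr, universe = c("expressed", "all_annotated"),
                               genes_all = NULL, seed = NULL) {
  universe <- match.arg(universe)
  if (universe == "expressed") {
    vals <- unname(expr)
    ids <- names(expr)
  } else {
    if (is.null(genes_all)) stopf("all_annotated mode needs genes_all")
    if (length(genes_all) < length(expr) || !all(names(expr) %in% genes_all)) {
      stopf("genes_all must be a superset of the expressed genes")
    }
    vals <- c(unname(expr), rep(0, length(genes_all) - length(expr)))
    ids <- genes_all
  }
  with_seed(seed, stats::setNames(vals[sample.int(length(vals))], ids))
}

#' Shuffled-transcriptome background distributions
#'
#' For each of `n_reps` replicates, shuffles the mRNA and tRNA expression
#' vectors, recomputes relative codon and amino-acid usage and anticodon and
#' isotype abundance, and records the Spearman interface correlation between
#' the shuffled mRNA and shuffled tRNA replicate. Reports the per-key mean
#' profiles over replicates and the set of background correlations
#' (`n_reps` paired values, or `n_reps^2` with `crossed = TRUE`).
#'
#' @param codon_counts genes x codons matrix covering the shuffling universe.
#' @param lengths named CDS lengths (nt) for the same genes.
#' @param mrna_expr,trna_expr named library-size-normalized expression.
#' @param trna_genes tRNA annotation covering the tRNA universe.
#' @param mode `"expressed"` or `"all_annotated"`.
#' @param genes_all,trna_genes_all annotated universes for
#'   `"all_annotated"` mode (character vectors of gene ids; tRNA universe
#'   defaults to all genes in `trna_genes`).
#' @param n_reps number of shuffled transcriptomes (default 100).
#' @param crossed if `TRUE`, correlate every shuffled mRNA replicate with
#'   every shuffled tRNA replicate instead of pairing them.
#' @param seed integer seed.
#' @param code a [load_genetic_code()] object.
#' @return An object of class `background_summary`: mean profiles
#'   (`mean_codon`, `mean_amino_acid`, `mean_anticodon`, `mean_isotype`),
#'   `rhos`, `n_reps`, `mode`.
#' @export
background_distributions <- function(codon_counts, lengths, mrna_expr,
                                     trna_expr, trna_genes,
                                     mode = c("expressed", "all_annotated"),
                                     genes_all = NULL, trna_genes_all = NULL,
                                     n_reps = 100, crossed = FALSE, seed = 1,
                                     code = load_genetic_code()) {
  mode <- match.arg(mode)
  if (n_reps < 2) stopf("n_reps must be >= 2")
  if (mode == "all_annotated" && is.null(trna_genes_all)) {
    trna_genes_all <- trna_genes$gene_id
  }
  pairing <- codon_family_pairing(code)

  codon_mat <- matrix(NA_real_, n_reps, length(code$sense_codons))
  aa_mat <- matrix(NA_real_, n_reps, length(code$amino_acids))
  fams <- sort(unique(trna_genes$family_id[!trna_genes$excluded]))
  isos <- sort(unique(trna_genes$isotype[!trna_genes$excluded]))
  anti_mat <- matrix(0, n_reps, length(fams), dimnames = list(NULL, fams))
  iso_mat <- matrix(0, n_reps, length(isos), dimnames = list(NULL, isos))
  codon_profiles <- vector("list", n_reps)
  anti_profiles <- vector("list", n_reps)

  for (i in seq_len(n_reps)) {
    me <- shuffle_expression(mrna_expr, universe = mode, genes_all = genes_all,
                             seed = seed + 2L * i)
    te <- shuffle_expression(trna_expr, universe = mode,
                             genes_all = trna_genes_all, seed = seed + 2L * i + 1L)
    cu <- relative_usage(weighted_usage(
      codon_counts[names(me), , drop = FALSE], me, lengths, "codon", code))
    au <- relative_usage(weighted_usage(
      codon_counts[names(me), , drop = FALSE], me, lengths, "amino_acid", code))
    ta <- anticodon_abundance(te, trna_genes, "anticodon")
    ti <- anticodon_abundance(te, trna_genes, "isotype")
    codon_mat[i, ] <- cu$values
    aa_mat[i, ] <- au$values
    anti_mat[i, names(ta$values)] <- ta$values
    iso_mat[i, names(ti$values)] <- ti$values
    codon_profiles[[i]] <- cu
    anti_profiles[[i]] <- ta
  }

  pair_rho <- function(i, j) {
    interface_correlation(codon_profiles[[i]], anti_profiles[[j]], pairing)$rho
  }
  rhos <- if (crossed) {
    as.vector(outer(seq_len(n_reps), seq_len(n_reps),
                    Vectorize(pair_rho)))
  } else {
    vapply(seq_len(n_reps), function(i) pair_rho(i, i), numeric(1))
  }

  mk <- function(m, keys, kind) {
    usage_profile(stats::setNames(colMeans(m) / sum(colMeans(m)), keys),
                  kind = kind, normalized = TRUE)
  }
  structure(list(
    mean_codon = mk(codon_mat, code$sense_codons, "codon"),
    mean_amino_acid = mk(aa_mat, code$amino_acids, "amino_acid"),
    mean_anticodon = mk(anti_mat, fams, "anticodon"),
    mean_isotype = mk(iso_mat, isos, "isotype"),
    rhos = rhos, n_reps = n_reps, mode = mode
  ), class = "background_summary")
}

#' @export
print.background_summary <- function(x, ...) {
  cat("background_summary (", x$mode, "): ", x$n_reps, " shuffles; rho in [",
      round(min(x$rhos), 3), ", ", round(max(x$rhos), 3), "]\n", sep = "")
  invisible(x)
}

#' Compare an observed interface correlation to its shuffled background
#'
#' Reports the background maximum, mean and sd, and the empirical
#' exceedance probability `(# background >= observed + 1) / (n + 1)`.
#'
#' @param observed_rho observed Spearman correlation.
#' @param background_rhos background correlations (e.g. from
#'   [background_distributions()]).
#' @return list with `observed`, `n`, `background_max`, `background_mean`,
#'   `background_sd`, `exceedance`.
#' @export
compare_observed_to_background <- function(observed_rho, background_rhos) {
  if (length(background_rhos) == 0) stopf("empty background")
  n <- length(background_rhos)
  list(
    observed = observed_rho, n = n,
    background_max = max(background_rhos),
    background_mean = mean(background_rhos),
    background_sd = stats::sd(background_rhos),
    exceedance = (sum(background_rhos >= observed_rho) + 1) / (n + 1)
  )
}
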