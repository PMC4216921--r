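# Expression calling for tRNA genes, library-size normalization, differential
# expression between developmental stages, and PCA on sample-correlation
# matrices.

#' Call expressed tRNA genes
#'
#' A tRNA gene is called expressed if, in at least one tissue-stage
#' condition, every biological replicate of that condition has at least
#' `min_reads` counts. Counts are assumed to be pre-windowed to the gene
#' locus plus/minus 100 bp of flanking sequence (an upstream counting
#' concern; this function consumes the windowed counts).
#'
#' @param counts tRNA [count_matrix()]; every condition must have >= 2
#'   replicates (the rule is defined on both replicates).
#' @param min_reads read threshold (default 10).
#' @return Character vector of expressed gene ids.
#' @export
call_expressed_trnas <- function(counts, min_reads = 10) {
  stopifnot(inherits(counts, "count_matrix"))
  cond <- interaction(counts$samples$tissue, counts$samples$stage, drop = TRUE)
  nrep <- table(cond)
  if (any(nrep < 2)) {
    stopf("condition(s) with a single replicate: %s",
          paste(names(nrep)[nrep < 2], collapse = ", "))
  }
  ok <- vapply(levels(cond), function(cv) {
    sub <- counts$counts[, cond == cv, drop = FALSE]
    apply(sub >= min_reads, 1, all)
  }, logical(nrow(counts$counts)))
  sort(rownames(counts$counts)[rowSums(ok) > 0])
}

# Median-of-ratios size factors (the DESeq convention): the reference is the
# per-gene geometric mean over samples, computed on genes with all-positive
# counts; each sample's factor is the median of its count/reference ratios.
median_of_ratios <- function(mat) {
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) return(NULL)
  loggeo <- rowMeans(log(mat[pos, , drop = FALSE]))
  apply(mat[pos, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - loggeo))
  })
}

#' Library-size normalize a count matrix
#'
#' Median-of-ratios size factors over genes with all-positive counts;
#' normalized value = count / size factor. If no gene is positive in every
#' sample, falls back to total-count scaling (factors proportional to column
#' sums, geometric mean 1) with a warning.
#'
#' @param counts a [count_matrix()].
#' @return An `expression_matrix`: list with `values`, `samples`, `stages`
#'   and the `size_factors` used.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  mat <- counts$counts
  if (all(mat == 0)) stopf("all-zero count matrix")
  sf <- median_of_ratios(mat)
  if (is.null(sf)) {
    warnf("no gene with all-positive counts; falling back to total-count size factors")
    cs <- colSums(mat)
    sf <- cs / exp(mean(log(cs)))
  }
  expression_matrix(sweep(mat, 2, sf, "/"), counts$samples, counts$stages,
                    stats::setNames(sf, colnames(mat)))
}

#' Differential expression between two developmental stages
#'
#' Negative-binomial Wald test per gene (DESeq2) between two stages of one
#' tissue, with Benjamini-Hochberg correction and a significance call at
#' `alpha` (default 0.001 on the adjusted p-value). Genes with zero counts
#' in every sample of both groups are reported with NA statistics and do not
#' enter the BH correction. An externally produced DE table can be supplied
#' instead via `de_table`, in which case it is validated, thresholded and
#' passed through.
#'
#' @param counts a [count_matrix()].
#' @param stage_a,stage_b stage labels to contrast (fold change is B vs A).
#' @param tissue tissue to test within.
#' @param alpha adjusted-p significance threshold.
#' @param de_table optional data.frame with columns `gene_id`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`.
#' @return data.frame with columns `gene_id`, `tissue`, `stage_a`,
#'   `stage_b`, `log2_fold_change`, `p_value`, `p_adjusted`, `significant`.
#' @export
de_test <- function(counts, stage_a, stage_b, tissue, alpha = 0.001,
                    de_table = NULL) {
  if (!is.null(de_table)) {
    need <- c("gene_id", "log2_fold_change", "p_value", "p_adjusted")
    if (!all(need %in% names(de_table))) {
      stopf("de_table must have columns: %s", paste(need, collapse = ", "))
    }
    de_table$tissue <- tissue
    de_table$stage_a <- stage_a; de_table$stage_b <- stage_b
    de_table$significant <- !is.na(de_table$p_adjusted) & de_table$p_adjusted < alpha
    return(de_table[, c("gene_id", "tissue", "stage_a", "stage_b",
                        "log2_fold_change", "p_value", "p_adjusted",
                        "significant")])
  }
  stopifnot(inherits(counts, "count_matrix"))
  sel <- counts$samples$tissue == tissue &
    counts$samples$stage %in% c(stage_a, stage_b)
  sub <- counts$counts[, sel, drop = FALSE]
  grp <- factor(counts$samples$stage[sel], levels = c(stage_a, stage_b))
  if (any(table(grp) < 2)) stopf("need >= 2 replicates per condition")

  nonzero <- rowSums(sub) > 0
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = sub[nonzero, , drop = FALSE],
    colData = S4Vectors::DataFrame(condition = grp),
    design = ~condition
  )
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("condition", stage_b, stage_a))

  out <- data.frame(
    gene_id = rownames(sub), tissue = tissue,
    stage_a = stage_a, stage_b = stage_b,
    log2_fold_change = NA_real_, p_value = NA_real_, p_adjusted = NA_real_,
    stringsAsFactors = FALSE
  )
  idx <- match(rownames(res), out$gene_id)
  out$log2_fold_change[idx] <- res$log2FoldChange
  out$p_value[idx] <- res$pvalue
  out$p_adjusted[idx] <- res$padj
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' PCA on the matrix of pairwise Spearman correlations between samples
#'
#' Computes the samples x samples Spearman correlation matrix of the
#' expression values (optionally on a gene subset), then performs PCA on
#' that matrix. Because ranks are invariant to monotone per-sample
#' transforms, so is the result. Variance fractions are reported both raw
#' and as each component's share of the variance remaining after removing
#' the preceding components (the convention used when quoting "X% of the
#' remaining variance ordered the samples by stage").
#'
#' @param expr an `expression_matrix` ([normalize_counts()]).
#' @param gene_subset optional gene ids to restrict to.
#' @return An object of class `pca_result`: list with `scores` (samples x
#'   components), `variance_fraction`, `variance_fraction_of_remaining`,
#'   `samples`.
#' @export
spearman_pca <- function(expr, gene_subset = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  mat <- expr$values
  if (!is.null(gene_subset)) mat <- mat[gene_subset, , drop = FALSE]
  if (ncol(mat) < 3) stopf("need >= 3 samples for PCA")
  const <- apply(mat, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stopf("constant expression in sample(s): %s",
          paste(colnames(mat)[const], collapse = ", "))
  }
  C <- stats::cor(mat, method = "spearman")
  pr <- stats::prcomp(C, center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  vf <- v / sum(v)
  vrem <- v / rev(cumsum(rev(v)))
  structure(list(
    scores = pr$x,
    variance_fraction = vf,
    variance_fraction_of_remaining = vrem,
    samples = expr$samples
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples; PC1",
      sprintf("%.1f%%", 100 * x$variance_fraction[1]), "of variance, PC2",
      sprintf("%.1f%%", 100 * x$variance_fraction_of_remaining[2]),
      "of remaining\n")
  invisible(x)
}
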