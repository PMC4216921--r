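# Within-family expression compensation: pairwise Spearman correlations of
# tRNA gene trajectories across developmental stages, compared by chi-square
# against a null built from stage-order permutations. Plus genomic clustering
# of tRNA genes and the family-label randomization test.

# All n! permutations of 1:n as a matrix (rows = permutations).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Stage-order permutations used for the null: full enumeration when n! fits
# under the cap, otherwise `cap` seeded random orderings. Only the relative
# ordering of the two genes in a pair matters for rank correlation, so one
# gene is held fixed and the other permuted.
stage_permutations <- function(S, cap, seed = NULL) {
  if (factorial(S) <= cap) return(all_permutations(S))
  with_seed(seed, t(replicate(cap, sample.int(S))))
}

# Average replicates within (stage) for one tissue and return per-family
# genes x stages matrices, stage-ordered.
#' Per-family gene-by-stage expression matrices
#'
#' Averages replicates within each stage of one tissue and splits the
#' resulting genes x stages matrix by isoacceptor family.
#'
#' @param expr an `expression_matrix` ([normalize_counts()]).
#' @param trna_genes tRNA annotation data.frame.
#' @param tissue tissue to extract.
#' @param genes optional gene subset (e.g. the expressed set).
#' @return Named list family_id -> genes x stages matrix.
#' @export
family_stage_matrices <- function(expr, trna_genes, tissue, genes = NULL) {
  sel <- expr$samples$tissue == tissue
  if (!any(sel)) stopf("no samples for tissue %s", tissue)
  mat <- expr$values[, sel, drop = FALSE]
  stage <- factor(expr$samples$stage[sel], levels = expr$stages)
  bystage <- sapply(levels(stage), function(s) {
    rowMeans(mat[, stage == s, drop = FALSE])
  })
  if (!is.null(genes)) bystage <- bystage[intersect(rownames(bystage), genes), , drop = FALSE]
  keep <- trna_genes$gene_id[!trna_genes$excluded]
  bystage <- bystage[intersect(rownames(bystage), keep), , drop = FALSE]
  fam <- trna_genes$family_id[match(rownames(bystage), trna_genes$gene_id)]
  lapply(split(rownames(bystage), fam), function(g) {
    bystage[g, , drop = FALSE]
  })
}

#' Within-family compensation test
#'
#' Computes all pairwise Spearman correlations between the member genes'
#' expression trajectories across developmental stages, builds a null
#' distribution from the correlations obtainable by permuting the stage
#' order for each pair (full enumeration of the S! relative orderings when
#' it fits under `n_perm_cap`, sampled otherwise), and compares observed to
#' null by a chi-square goodness-of-fit test on shared equal-width bins over
#' `[-1, 1]` (bins with null-expected count < 5 merged with their
#' neighbour). When the test is significant the member genes are split into
#' two expression clusters by the sign of the leading eigenvector of their
#' correlation matrix. A descriptive bimodality score (the balanced
#' fraction of strongly positive/negative observed correlations) is also
#' reported but is not the decision rule.
#'
#' @param family_expr genes x stages matrix (replicate means, stage order).
#' @param n_perm_cap cap on stage orderings per pair (720 = 6!).
#' @param bins number of equal-width bins over `[-1, 1]`.
#' @param seed seed (used only when orderings are sampled).
#' @param family_id optional label carried into the result.
#' @return An object of class `compensation_result`.
#' @export
compensation_test <- function(family_expr, n_perm_cap = 720, bins = 20,
                              seed = NULL, family_id = NULL) {
  mat <- as.matrix(family_expr)
  S <- ncol(mat)
  if (S < 4) stopf("need >= 4 stages, got %d", S)
  const <- apply(mat, 1, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warnf("excluding %d gene(s) with constant trajectories in family %s",
          sum(const), family_id %||% "?")
    mat <- mat[!const, , drop = FALSE]
  }
  n <- nrow(mat)
  if (n < 3) {
    stop(structure(class = c("family_skip", "error", "condition"),
                   list(message = sprintf(
                     "family %s skipped: %d usable genes (< 3)",
                     family_id %||% "?", n), call = NULL)))
  }

  R <- t(apply(mat, 1, rank))
  obs_cor <- stats::cor(t(R))          # Pearson on ranks = Spearman
  observed <- obs_cor[upper.tri(obs_cor)]

  P <- stage_permutations(S, n_perm_cap, seed)
  nulls <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    rxc <- R[i, ] - mean(R[i, ])
    sdx <- stats::sd(R[i, ])
    for (j in (i + 1):n) {
      ry <- R[j, ]
      M <- matrix(ry[P], nrow(P))
      k <- k + 1L
      nulls[[k]] <- as.vector(M %*% rxc) / ((S - 1) * sdx * stats::sd(ry))
    }
  }
  null_all <- unlist(nulls)

  breaks <- seq(-1, 1, length.out = bins + 1)
  cut_counts <- function(x) {
    tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                  bins), bins)
  }
  obs_counts <- cut_counts(observed)
  null_counts <- cut_counts(null_all)
  null_prop <- null_counts / sum(null_counts)
  expected <- null_prop * length(observed)

  # merge bins with expected < 5 outward: groups are built from the two
  # tails of [-1, 1] inward, each accumulating bins until it reaches an
  # expected count of 5, alternating sides; whatever remains in the centre
  # forms the final group (folded into its neighbours if itself deficient).
  # This keeps the tails -- where bimodality shows -- in their own cells.
  # The centre remainder keeps its own cell down to an expected count of 1
  # (Cochran's condition tolerates a minority of cells between 1 and 5);
  # folding it away would erase the centre deficit that distinguishes a
  # bimodal family from the unimodal null.
  grp <- integer(bins); i <- 1L; j <- bins; gid <- 0L
  repeat {
    if (i > j) break
    remaining <- sum(expected[i:j])
    if (i == j || remaining < 10) {
      if (remaining >= 1 || gid == 0L) {
        gid <- gid + 1L
        grp[i:j] <- gid
      } else {
        # near-empty centre: split it between the flanking groups
        mid <- (i + j) %/% 2
        grp[i:mid] <- grp[i - 1L]
        if (mid < j) grp[(mid + 1L):j] <- grp[j + 1L]
      }
      break
    }
    gid <- gid + 1L; acc <- 0
    while (acc < 5 && i < j) { grp[i] <- gid; acc <- acc + expected[i]; i <- i + 1L }
    gid <- gid + 1L; acc <- 0
    while (acc < 5 && j > i) { grp[j] <- gid; acc <- acc + expected[j]; j <- j - 1L }
  }
  gsum <- function(x) vapply(split(x, grp), sum, numeric(1))
  obs_m <- gsum(obs_counts)
  exp_m <- gsum(expected)
  keep <- exp_m > 0
  obs_m <- obs_m[keep]; exp_m <- exp_m[keep]

  if (length(obs_m) >= 2) {
    chi2 <- sum((obs_m - exp_m)^2 / exp_m)
    df <- length(obs_m) - 1L
    p_raw <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    chi2 <- 0; df <- 0L; p_raw <- 1
  }

  ev <- eigen(obs_cor, symmetric = TRUE)$vectors[, 1]
  clusters <- list(a = rownames(mat)[ev >= 0], b = rownames(mat)[ev < 0])
  bimod <- 2 * min(mean(observed >= 0.5), mean(observed <= -0.5))

  structure(list(
    family_id = family_id, n_genes = n,
    observed_correlations = observed, null_correlations = null_all,
    chi2_stat = chi2, df = df, p_raw = p_raw,
    p_corrected = NA_real_, significant = NA,
    expression_clusters = clusters, bimodality = bimod,
    n_excluded_constant = sum(const)
  ), class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat("compensation_result", x$family_id %||% "", ":", x$n_genes, "genes,",
      length(x$observed_correlations), "pairs; chi2 =", round(x$chi2_stat, 2),
      "p =", format.pval(x$p_raw), "\n")
  invisible(x)
}

#' Compensation screen over isoacceptor families
#'
#' Runs [compensation_test()] for every family with more than two usable
#' genes, then applies a multiplicity correction across -- and reports
#' significance for -- families with at least `min_genes_report` genes
#' (families below that size are tested but carry too few gene pairs for a
#' meaningful call).
#'
#' @param family_exprs named list family_id -> genes x stages matrix
#'   ([family_stage_matrices()]).
#' @param min_genes_report family size required to enter the corrected
#'   report (default 6).
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param alpha significance threshold on the corrected p-value.
#' @param ... passed to [compensation_test()].
#' @return list with `results` (all `compensation_result`s), `table`
#'   (data.frame for reported families) and `skipped` (family: reason).
#' @export
compensation_screen <- function(family_exprs, min_genes_report = 6,
                                correction = c("bonferroni", "bh"),
                                alpha = 0.05, ...) {
  correction <- match.arg(correction)
  results <- list(); skipped <- character(0)
  for (f in names(family_exprs)) {
    if (nrow(family_exprs[[f]]) <= 2) {
      skipped[f] <- sprintf("%d genes (<= 2)", nrow(family_exprs[[f]]))
      next
    }
    r <- tryCatch(compensation_test(family_exprs[[f]], family_id = f, ...),
                  family_skip = function(e) conditionMessage(e))
    if (is.character(r)) skipped[f] <- r else results[[f]] <- r
  }
  if (length(results) == 0) {
    warnf("no testable families")
    return(list(results = list(), table = NULL, skipped = skipped))
  }
  n_genes <- vapply(results, `[[`, numeric(1), "n_genes")
  p_raw <- vapply(results, `[[`, numeric(1), "p_raw")
  eligible <- n_genes >= min_genes_report
  if (!any(eligible)) {
    warnf("no families with >= %d genes to report", min_genes_report)
    return(list(results = results, table = NULL, skipped = skipped))
  }
  p_corr <- stats::p.adjust(p_raw[eligible],
                            method = if (correction == "bh") "BH" else "bonferroni")
  tab <- data.frame(
    family_id = names(results)[eligible],
    n_genes = n_genes[eligible],
    chi2 = vapply(results[eligible], `[[`, numeric(1), "chi2_stat"),
    p_raw = p_raw[eligible],
    p_corrected = p_corr,
    significant = p_corr < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in seq_len(nrow(tab))) {
    results[[tab$family_id[i]]]$p_corrected <- tab$p_corrected[i]
    results[[tab$family_id[i]]]$significant <- tab$significant[i]
  }
  list(results = results, table = tab, skipped = skipped)
}

#' Chain tRNA genes into genomic clusters
#'
#' Per chromosome, genes sorted by start are chained whenever the gap
#' between one gene's end and the next gene's start is at most
#' `gap_kb` kilobases; maximal chains of two or more genes become clusters.
#' Strand is ignored.
#'
#' @param trna_genes tRNA annotation data.frame.
#' @param gap_kb maximum intergenic gap within a cluster (default 7.5).
#' @return An object of class `cluster_set`: list with `clusters` (list of
#'   gene-id vectors), `gap_kb`, `n_clusters`.
#' @export
define_clusters <- function(trna_genes, gap_kb = 7.5) {
  gap_bp <- gap_kb * 1000
  clusters <- list()
  for (chrom in unique(trna_genes$chrom)) {
    sub <- trna_genes[trna_genes$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start, sub$gene_id), , drop = FALSE]
    if (nrow(sub) == 0) next
    gap <- sub$start[-1] - utils::head(sub$end, -1)
    brk <- c(0, cumsum(gap > gap_bp))
    for (run in split(sub$gene_id, brk)) {
      if (length(run) >= 2) clusters[[length(clusters) + 1L]] <- run
    }
  }
  structure(list(clusters = clusters, gap_kb = gap_kb,
                 n_clusters = length(clusters)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", x$n_clusters, "clusters (gap <=", x$gap_kb, "kb) holding",
      sum(lengths(x$clusters)), "genes\n")
  invisible(x)
}

# Per-gene indicator: does the gene sit in a cluster together with at least
# one other gene of the given family labels?
colocalizes_with_family <- function(gene_ids, families, clusters) {
  fam <- stats::setNames(families, gene_ids)
  coloc <- stats::setNames(rep(FALSE, length(gene_ids)), gene_ids)
  for (cl in clusters$clusters) {
    fl <- fam[cl]
    dup <- fl %in% fl[duplicated(fl)]
    coloc[cl[dup]] <- TRUE
  }
  coloc
}

#' Family-label randomization test for genomic clustering
#'
#' Statistic: the mean over isoacceptor families of the percentage of
#' family members colocalizing in a genomic cluster with at least one
#' same-family gene. The null preserves family sizes and the cluster
#' layout, randomly reassigning genes to families `n_rand` times. Reported
#' p-values: a binomial test of the observed number of colocalizing genes
#' against the null-expected colocalization probability (success = a gene
#' colocalizes with a same-family gene, n = total genes), and the empirical
#' exceedance fraction over the randomizations.
#'
#' @param trna_genes tRNA annotation data.frame.
#' @param clusters optional [define_clusters()] result (recomputed if NULL).
#' @param n_rand number of family-label randomizations (default 1000).
#' @param seed integer seed.
#' @return list with `statistic` (mean % per family), `per_family` (named
#'   percentages), `null_mean`, `p_binomial`, `p_empirical`,
#'   `n_colocalizing`, `n_genes`.
#' @export
cluster_randomization_test <- function(trna_genes, clusters = NULL,
                                       n_rand = 1000, seed = 1) {
  if (is.null(clusters)) clusters <- define_clusters(trna_genes)
  genes <- trna_genes$gene_id
  fams <- trna_genes$family_id
  if (anyNA(fams)) stopf("every gene needs a family")
  if (clusters$n_clusters == 0) {
    warnf("no genomic clusters; test skipped")
    return(list(statistic = 0, per_family = NULL, null_mean = NA_real_,
                p_binomial = NA_real_, p_empirical = NA_real_,
                n_colocalizing = 0L, n_genes = length(genes)))
  }
  stat_of <- function(labels) {
    coloc <- colocalizes_with_family(genes, labels, clusters)
    per_fam <- tapply(coloc, labels, mean) * 100
    list(stat = mean(per_fam), per_fam = per_fam, n_coloc = sum(coloc))
  }
  obs <- stat_of(fams)
  null <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      s <- stat_of(sample(fams))
      c(s$stat, s$n_coloc)
    }, numeric(2))
  })
  p0 <- mean(null[2, ]) / length(genes)
  p_binom <- stats::binom.test(obs$n_coloc, length(genes), p0)$p.value
  p_emp <- (sum(null[1, ] >= obs$stat) + 1) / (n_rand + 1)
  list(statistic = obs$stat, per_family = obs$per_fam,
       null_mean = mean(null[1, ]), p_binomial = p_binom,
       p_empirical = p_emp, n_colocalizing = obs$n_coloc,
       n_genes = length(genes))
}

#' Compare genomic clustering between compensated and other families
#'
#' Chi-square comparison of the per-family clustering percentages between
#' families with and without evidence of compensation, binned into quarters
#' of the 0-100% range.
#'
#' @param significant named logical: family -> compensation call.
#' @param fractions named numeric: family -> clustering percentage.
#' @param breaks bin edges on the percentage scale.
#' @return list with `chi2`, `p`, `table`.
#' @export
compensation_vs_clustering <- function(significant, fractions,
                                       breaks = c(0, 25, 50, 75, 100)) {
  common <- intersect(names(significant), names(fractions))
  significant <- significant[common]; fractions <- fractions[common]
  if (sum(significant) < 2 || sum(!significant) < 2) {
    stopf("need >= 2 families in each group (got %d compensated, %d not)",
          sum(significant), sum(!significant))
  }
  bin <- cut(fractions, breaks = breaks, include.lowest = TRUE)
  tab <- table(group = ifelse(significant, "compensated", "other"), bin = bin)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) return(list(chi2 = 0, p = 1, table = tab))
  ct <- suppressWarnings(stats::chisq.test(tab))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}
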