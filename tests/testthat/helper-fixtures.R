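# Shared fixtures and oracles. Everything is generated in code; datasets
# reused across tests are memoized per session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_dataset <- function() {
  cached("default", simulate_dataset(sim_config(seed = 101)))
}

small_dataset <- function() {
  cached("small", simulate_dataset(
    sim_config(seed = 202, n_pc_genes = 300, n_trna_genes = 120,
               n_families = 30)))
}

# Condition-mean normalized expression and the observed codon-anticodon
# Spearman correlation for one tissue/stage of a simulated dataset.
interface_rho_of <- function(ds, tissue = "liver", stage = "E15.5") {
  code <- load_genetic_code()
  ex <- call_expressed_trnas(ds$trna_counts)
  me <- normalize_counts(ds$mrna_counts)
  te <- normalize_counts(ds$trna_counts)
  cc <- codon_count_table(ds$transcripts, code)
  lens <- stats::setNames(ds$transcripts$length_nt, ds$transcripts$gene_id)
  msel <- me$samples$tissue == tissue & me$samples$stage == stage
  tsel <- te$samples$tissue == tissue & te$samples$stage == stage
  mex <- rowMeans(me$values[, msel, drop = FALSE])
  tex <- rowMeans(te$values[, tsel, drop = FALSE])[ex]
  cu <- relative_usage(weighted_usage(cc, mex, lens, "codon", code))
  ta <- anticodon_abundance(tex, ds$trna_genes, "anticodon")
  interface_correlation(cu, ta)$rho
}

# Minimal tRNA annotation data.frame from start coordinates.
make_trna <- function(starts, chrom = "chr1", family = "Gly-GCC",
                      width = 72L, ids = NULL) {
  n <- length(starts)
  data.frame(
    gene_id = ids %||% sprintf("t%02d", seq_len(n)),
    chrom = rep_len(chrom, n),
    start = as.integer(starts), end = as.integer(starts + width),
    strand = "+",
    anticodon = sub(".*-", "", rep_len(family, n)),
    isotype = sub("-.*", "", rep_len(family, n)),
    family_id = rep_len(family, n),
    excluded = FALSE, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force single-linkage clustering oracle: union-find over all gene
# pairs closer than the gap on the same chromosome.
brute_force_clusters <- function(tg, gap_kb = 7.5) {
  n <- nrow(tg)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (tg$chrom[i] == tg$chrom[j]) {
      gap <- max(tg$start[i], tg$start[j]) - min(tg$end[i], tg$end[j])
      if (gap <= gap_kb * 1000) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  cl <- split(tg$gene_id, comp)
  sort(vapply(Filter(function(x) length(x) >= 2, cl),
              function(x) paste(sort(x), collapse = ","), character(1)),
       method = "radix")
}

cluster_signature <- function(cs) {
  sort(vapply(cs$clusters, function(x) paste(sort(x), collapse = ","),
              character(1)), method = "radix")
}

# One pass over 50 seeded default datasets: observed interface correlation
# (liver E15.5) plus the PCA structure flags (PC1 separates tissues; PC2
# stage-monotone in both tissues). Shared by several tests.
seed_scan <- function(n_seeds = 50) {
  cached("scan", {
    lapply(seq_len(n_seeds), function(s) {
      ds <- simulate_dataset(sim_config(seed = s))
      me <- normalize_counts(ds$mrna_counts)
      p <- spearman_pca(me)
      sm <- p$samples
      by_tissue <- split(p$scores[, 1], sm$tissue)
      sep <- max(by_tissue[[1]]) < min(by_tissue[[2]]) ||
        max(by_tissue[[2]]) < min(by_tissue[[1]])
      mono <- all(vapply(unique(sm$tissue), function(tt) {
        sel <- sm$tissue == tt
        sc <- tapply(p$scores[sel, 2],
                     factor(sm$stage[sel], levels = me$stages), mean)
        abs(stats::cor(sc, seq_along(sc), method = "spearman")) == 1
      }, logical(1)))
      list(rho = interface_rho_of(ds), pc1_separates = sep,
           pc2_monotone = mono)
    })
  })
}

# NB count matrix for DE calibration tests: 2 vs 2 replicates, optional
# fraction of genes with a true log2 fold change of +/- lfc.
make_de_counts <- function(n_genes = 2000, frac_de = 0, lfc = 3,
                           dispersion = 0.05, base_mean = 200) {
  mu <- stats::rlnorm(n_genes, log(base_mean), 1)
  de <- sample.int(n_genes, round(frac_de * n_genes))
  f <- rep(1, n_genes)
  if (length(de) > 0) f[de] <- 2^(sample(c(-lfc, lfc), length(de), TRUE))
  size <- 1 / dispersion
  cnt <- cbind(matrix(stats::rnbinom(2 * n_genes, mu = mu, size = size), n_genes),
               matrix(stats::rnbinom(2 * n_genes, mu = mu * f, size = size), n_genes))
  rownames(cnt) <- sprintf("g%05d", seq_len(n_genes))
  colnames(cnt) <- c("a.S1.rep1", "a.S1.rep2", "a.S2.rep1", "a.S2.rep2")
  list(cm = count_matrix(cnt, stages = c("S1", "S2")),
       true_de = rownames(cnt)[de])
}

# Generator-style compensated family: two gene clusters with mirrored stage
# share trajectories, NB-sampled in two replicates and replicate-averaged.
make_compensated_family <- function(n_genes = 8, n_stages = 6, total = 3000,
                                    amplitude = 0.35, dispersion = 0.05) {
  x <- seq(-1, 1, length.out = n_stages)
  a <- 0.5 + amplitude * x
  ha <- ceiling(n_genes / 2)
  wa <- stats::rgamma(ha, 2); wa <- wa / sum(wa)
  wb <- stats::rgamma(n_genes - ha, 2); wb <- wb / sum(wb)
  mu <- rbind(outer(wa, a * total), outer(wb, (1 - a) * total))
  size <- 1 / dispersion
  r1 <- matrix(stats::rnbinom(length(mu), mu = mu, size = size), n_genes)
  r2 <- matrix(stats::rnbinom(length(mu), mu = mu, size = size), n_genes)
  m <- (r1 + r2) / 2
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%d", seq_len(n_stages)))
  m
}
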