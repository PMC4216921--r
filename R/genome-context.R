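# Genomic context of differentially expressed tRNA genes: colocalization
# with differentially expressed protein-coding neighbours (neighbour-ratio
# distributions compared by Kolmogorov-Smirnov) and association with
# chromatin-mark intervals (Fisher's exact test at fixed distances).

coords_to_granges <- function(coords) {
  GenomicRanges::GRanges(
    seqnames = coords$chrom,
    ranges = IRanges::IRanges(start = coords$start + 1L, end = coords$end),
    gene_id = coords$gene_id
  )
}

expand_granges <- function(gr, bp) {
  GenomicRanges::trim(GenomicRanges::resize(
    gr, width = GenomicRanges::width(gr) + 2 * bp, fix = "center"))
}

# Neighbour ratio r_t = (# up-regulated protein-coding genes) / (# all
# protein-coding genes) within `window_bp` of each tRNA gene; genes with no
# protein-coding neighbour are excluded.
neighbour_ratios <- function(trna_gr, pc_gr, pc_up, window_bp) {
  win <- expand_granges(trna_gr, window_bp)
  a <- GenomicRanges::countOverlaps(win, pc_gr)
  u <- GenomicRanges::countOverlaps(win, pc_gr[pc_gr$gene_id %in% pc_up])
  keep <- a > 0
  list(ratios = u[keep] / a[keep], n_excluded = sum(!keep))
}

#' Colocalization of differentially expressed tRNA and protein-coding genes
#'
#' For each up-regulated tRNA gene and window size, computes the ratio of
#' up-regulated to total protein-coding genes within the window (the tRNA
#' interval expanded by the window on both sides; any intersection counts),
#' and likewise for non-differentially-expressed tRNA genes; the two ratio
#' distributions are compared by a two-sample Kolmogorov-Smirnov test.
#'
#' Because neighbour counts are small, the ratios are heavily tied and the
#' continuous-case KS p-value is grossly conservative; by default the D
#' statistic is therefore referred to its group-label permutation
#' distribution (`p_method = "permutation"`), which is valid under ties.
#' `p_method = "asymptotic"` gives the classical p-value instead.
#'
#' @param trna_genes tRNA annotation data.frame.
#' @param pc_coords protein-coding coordinates (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param trna_up,trna_nonde gene-id sets of up-regulated and non-DE tRNAs.
#' @param pc_up gene ids of up-regulated protein-coding genes.
#' @param windows_kb window sizes (default 10, 50, 100 kb).
#' @param p_method `"permutation"` (default) or `"asymptotic"`.
#' @param n_perm label permutations for the permutation p-value.
#' @param seed seed for the permutations.
#' @return data.frame per window: group sizes, excluded counts, KS `D`, `p`
#'   (NA when either group is empty after exclusions).
#' @export
colocalization_test <- function(trna_genes, pc_coords, trna_up, trna_nonde,
                                pc_up, windows_kb = c(10, 50, 100),
                                p_method = c("permutation", "asymptotic"),
                                n_perm = 999, seed = 1) {
  p_method <- match.arg(p_method)
  trna_coords <- trna_genes[, c("gene_id", "chrom", "start", "end")]
  trna_gr <- coords_to_granges(trna_coords)
  pc_gr <- coords_to_granges(pc_coords)
  up_gr <- trna_gr[trna_gr$gene_id %in% trna_up]
  non_gr <- trna_gr[trna_gr$gene_id %in% trna_nonde]
  ks_d <- function(x, y) {
    suppressWarnings(unname(stats::ks.test(x, y)$statistic))
  }
  out <- lapply(windows_kb, function(w) {
    ru <- neighbour_ratios(up_gr, pc_gr, pc_up, w * 1000)
    rn <- neighbour_ratios(non_gr, pc_gr, pc_up, w * 1000)
    n1 <- length(ru$ratios); n2 <- length(rn$ratios)
    if (n1 == 0 || n2 == 0) {
      d <- NA_real_; p <- NA_real_
    } else if (p_method == "asymptotic") {
      ks <- suppressWarnings(stats::ks.test(ru$ratios, rn$ratios))
      d <- unname(ks$statistic); p <- ks$p.value
    } else {
      d <- ks_d(ru$ratios, rn$ratios)
      pool <- c(ru$ratios, rn$ratios)
      dnull <- with_seed(seed + w, vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n1 + n2, n1)
        ks_d(pool[idx], pool[-idx])
      }, numeric(1)))
      p <- (sum(dnull >= d - 1e-12) + 1) / (n_perm + 1)
    }
    data.frame(window_kb = w,
               n_up = n1, n_nonde = n2,
               n_excluded = ru$n_excluded + rn$n_excluded,
               ks_d = d, p = p)
  })
  do.call(rbind, out)
}

#' Colocalization screen across DE significance thresholds
#'
#' Derives the up-regulated and non-DE tRNA sets and the up-regulated
#' protein-coding set from [de_test()] tables at each significance
#' threshold, then runs [colocalization_test()] per threshold and window.
#'
#' @param trna_genes,pc_coords coordinates as in [colocalization_test()].
#' @param trna_de,pc_de DE tables ([de_test()] output).
#' @param windows_kb window sizes.
#' @param alphas adjusted-p thresholds defining the DE sets
#'   (default 0.1, 0.05, 0.01).
#' @return data.frame with one row per threshold x window.
#' @export
colocalization_screen <- function(trna_genes, pc_coords, trna_de, pc_de,
                                  windows_kb = c(10, 50, 100),
                                  alphas = c(0.1, 0.05, 0.01)) {
  out <- lapply(alphas, function(a) {
    t_sig <- !is.na(trna_de$p_adjusted) & trna_de$p_adjusted < a
    p_sig <- !is.na(pc_de$p_adjusted) & pc_de$p_adjusted < a
    res <- colocalization_test(
      trna_genes, pc_coords,
      trna_up = trna_de$gene_id[t_sig & trna_de$log2_fold_change > 0],
      trna_nonde = trna_de$gene_id[!t_sig],
      pc_up = pc_de$gene_id[p_sig & pc_de$log2_fold_change > 0],
      windows_kb = windows_kb
    )
    cbind(alpha = a, res)
  })
  do.call(rbind, out)
}

#' Chromatin-mark association of two tRNA gene sets
#'
#' A tRNA gene "has" a mark at distance d if any mark interval intersects
#' the gene interval expanded by d on both sides. For each distance a 2x2
#' table (set membership x mark presence) is tested by a two-sided Fisher's
#' exact test.
#'
#' @param marks mark intervals: a `GRanges`, or a named list of `GRanges`
#'   (one entry per mark).
#' @param trna_genes tRNA annotation data.frame.
#' @param set_a,set_b disjoint gene-id sets (e.g. DE vs non-DE).
#' @param distances_kb distances (default 0.1, 0.5, 1 kb).
#' @return data.frame per mark x distance: counts, `odds_ratio`, `p`.
#' @export
chromatin_association <- function(marks, trna_genes, set_a, set_b,
                                  distances_kb = c(0.1, 0.5, 1.0)) {
  if (length(set_a) == 0 || length(set_b) == 0) stopf("empty tRNA gene set")
  if (length(intersect(set_a, set_b)) > 0) stopf("gene sets must be disjoint")
  if (!is.list(marks)) marks <- list(mark = marks)
  trna_gr <- coords_to_granges(trna_genes[, c("gene_id", "chrom", "start", "end")])
  out <- list()
  for (mk in names(marks)) {
    for (d in distances_kb) {
      win <- expand_granges(trna_gr, round(d * 1000))
      has <- GenomicRanges::countOverlaps(win, marks[[mk]]) > 0
      names(has) <- trna_gr$gene_id
      tab <- matrix(c(sum(has[set_a]), sum(!has[set_a]),
                      sum(has[set_b]), sum(!has[set_b])),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(set = c("a", "b"),
                                    mark = c("present", "absent")))
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      out[[length(out) + 1L]] <- data.frame(
        mark = mk, distance_kb = d,
        a_present = tab[1, 1], a_absent = tab[1, 2],
        b_present = tab[2, 1], b_absent = tab[2, 2],
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
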