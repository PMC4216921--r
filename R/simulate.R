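# Synthetic-data generator. Emulates the statistical structure of a
# two-tissue, six-stage, two-replicate developmental study: negative-binomial
# counts with a dominant tissue effect and a monotone stage trend for
# protein-coding genes; tRNA genes grouped into anticodon isoacceptor
# families, placed on synthetic chromosomes with genomic clustering; a
# configurable rank coupling between expression-weighted codon demand and
# anticodon family abundance; and designated "compensated" families whose two
# gene clusters move in opposite directions while the family total stays flat.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study design the package models: liver and brain at
#' six developmental stages (E15.5 ... P29) in two replicates; 433 tRNA genes
#' in 47 anticodon families of which ~72% are transcriptionally active; ~93%
#' of tRNA genes lying in genomic clusters (gap < 7.5 kb); and a target
#' codon-anticodon Spearman coupling of 0.7 (the middle of the 0.64-0.76
#' range the method is designed to detect).
#'
#' @param n_pc_genes number of protein-coding genes.
#' @param n_trna_genes number of tRNA genes.
#' @param n_families number of anticodon isoacceptor families (<= 47).
#' @param tissues,stages,replicates design; `stages` is the stage order.
#' @param nb_dispersion shared NB dispersion (variance = mu + disp * mu^2).
#' @param tissue_effect_sd,stage_effect_sd,noise_sd log2-scale effect sizes;
#'   tissue effects dominate by default so sample-correlation PCA separates
#'   tissues on PC1 and stages on PC2.
#' @param stage_shared_frac fraction of the stage-trend variance shared
#'   between tissues (developmental programs common to both organs), so a
#'   single principal component orders the samples of both tissues by stage.
#' @param depth_log2_sd log2 sd of per-sample sequencing-depth factors.
#' @param coupling_rho target Spearman correlation between codon demand and
#'   anticodon family abundance, in `[0, 1]`.
#' @param compensated_families family ids to endow with two anti-correlated
#'   expression clusters; `NULL` selects ~59% of families with >= 6 active
#'   genes (seeded).
#' @param compensation_amplitude half-range of the compensated cluster share
#'   trajectory (cluster A share runs `0.5 +/- amplitude` across stages).
#' @param cluster_gap_kb gap below which adjacent tRNA genes chain into a
#'   genomic cluster.
#' @param clustered_fraction fraction of tRNA genes placed inside a cluster
#'   with a same-family neighbour.
#' @param family_size_skew Zipf exponent for family sizes (0 = even).
#' @param trna_silent_frac fraction of tRNA genes that are never expressed.
#' @param pc_base_mean,trna_base_mean mean counts for an average gene.
#' @param cds_len_codons median CDS length in codons (log-normal, sdlog 0.35).
#' @param codon_weights `"biased"` (default; fixed 8-fold spread across sense
#'   codons, comparable to real codon-usage bias), `"uniform"`, or a named
#'   numeric vector of sense-codon weights.
#' @param n_chromosomes,chrom_length_mb synthetic genome shape.
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pc_genes = 2000,
                       n_trna_genes = 433,
                       n_families = 47,
                       tissues = c("liver", "brain"),
                       stages = c("E15.5", "E18.5", "P0.5", "P4", "P22", "P29"),
                       replicates = 2,
                       nb_dispersion = 0.05,
                       tissue_effect_sd = 2,
                       stage_effect_sd = 0.5,
                       stage_shared_frac = 0.7,
                       noise_sd = 0.15,
                       depth_log2_sd = 0.2,
                       coupling_rho = 0.7,
                       compensated_families = NULL,
                       compensation_amplitude = 0.35,
                       cluster_gap_kb = 7.5,
                       clustered_fraction = 0.93,
                       family_size_skew = 0.5,
                       trna_silent_frac = 0.28,
                       pc_base_mean = 150,
                       trna_base_mean = 300,
                       cds_len_codons = 300,
                       codon_weights = "biased",
                       n_chromosomes = 8,
                       chrom_length_mb = 25,
                       seed = 1) {
  cfg <- as.list(environment())
  if (n_families > 47) stopf("n_families must be <= 47 (one per non-SeC anticodon family)")
  if (n_families < 1 || n_trna_genes < n_families) {
    stopf("need n_trna_genes >= n_families >= 1")
  }
  if (replicates < 2) stopf("replicates must be >= 2")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (coupling_rho < 0 || coupling_rho > 1) stopf("coupling_rho must be in [0, 1]")
  if (length(stages) < 2) stopf("need >= 2 stages")
  if (compensation_amplitude <= 0 || compensation_amplitude >= 0.5) {
    stopf("compensation_amplitude must be in (0, 0.5)")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Fixed candidate family universe: the 61 Watson-Crick anticodons of sense
# codons, ordered round-robin across isotypes so any n_families >= 20 covers
# all 20 amino acids.
candidate_families <- function(code = load_genetic_code()) {
  pairing <- codon_family_pairing(code)
  fam <- data.frame(
    family_id = unname(pairing),
    codon = names(pairing),
    anticodon = codon_to_anticodon(names(pairing)),
    isotype = AA_THREE[unname(code$table[names(pairing)])],
    stringsAsFactors = FALSE
  )
  fam <- fam[order(fam$isotype, fam$anticodon), ]
  fam$within <- stats::ave(seq_len(nrow(fam)), fam$isotype, FUN = seq_along)
  fam[order(fam$within, fam$isotype), , drop = FALSE]
}

# Sense-codon sampling weights for synthetic CDS.
resolve_codon_weights <- function(codon_weights, code) {
  sense <- code$sense_codons
  if (is.character(codon_weights) && length(codon_weights) == 1) {
    w <- switch(codon_weights,
      biased  = 2^seq(-1.5, 1.5, length.out = length(sense)),
      uniform = rep(1, length(sense)),
      stopf("unknown codon_weights preset: %s", codon_weights)
    )
    return(stats::setNames(w, sense))
  }
  if (!all(sense %in% names(codon_weights))) {
    stopf("codon_weights must name every sense codon")
  }
  codon_weights[sense]
}

#' Generate a synthetic genome: coding sequences and tRNA gene annotation
#'
#' CDS are drawn codon-by-codon from the configured codon-frequency model
#' (ATG start, one stop at the end). tRNA genes are assigned to anticodon
#' families (every family gets at least one gene; the remainder follow a
#' Zipf size distribution) and placed on synthetic chromosomes so that
#' `clustered_fraction` of them sit in chains of same-family genes with
#' inter-gene gaps below `cluster_gap_kb`, while chains and isolated genes
#' are separated by much larger gaps.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (gene_id/cds/length_nt), `pc_coords`
#'   (gene_id/chrom/start/end), `trna_genes` (annotation data.frame as from
#'   [read_trna_annotation()]), `families` (family table) and
#'   `codon_weights`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  code <- load_genetic_code()
  with_seed(config$seed, {
    w <- resolve_codon_weights(config$codon_weights, code)

    # --- protein-coding genes -------------------------------------------
    n <- config$n_pc_genes
    len_codons <- pmax(50L, round(stats::rlnorm(n, log(config$cds_len_codons), 0.35)))
    total <- sum(len_codons)
    body <- sample(code$sense_codons, total, replace = TRUE, prob = w)
    stops <- sample(code$stop_codons, n, replace = TRUE)
    idx_end <- cumsum(len_codons)
    idx_start <- c(1L, head(idx_end, -1L) + 1L)
    cds <- vapply(seq_len(n), function(i) {
      paste0("ATG", paste(body[idx_start[i]:idx_end[i]], collapse = ""), stops[i])
    }, character(1))
    transcripts <- data.frame(
      gene_id = sprintf("pc%05d", seq_len(n)),
      cds = cds, length_nt = nchar(cds), stringsAsFactors = FALSE
    )
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    chrom_len <- round(config$chrom_length_mb * 1e6)
    pc_chrom <- sample(chroms, n, replace = TRUE)
    pc_start <- sample.int(chrom_len - 100000L, n, replace = TRUE)
    pc_coords <- data.frame(
      gene_id = transcripts$gene_id, chrom = pc_chrom,
      start = pc_start, end = pc_start + pmin(transcripts$length_nt * 10L, 50000L),
      stringsAsFactors = FALSE
    )

    # --- tRNA genes ------------------------------------------------------
    cand <- candidate_families(code)
    fams <- cand[seq_len(config$n_families), , drop = FALSE]
    # one gene per family, then Zipf-skewed assignment of the remainder
    extra <- config$n_trna_genes - config$n_families
    zipf <- sample(seq_len(config$n_families))^(-config$family_size_skew)
    fam_of_gene <- c(seq_len(config$n_families),
                     sample(seq_len(config$n_families), extra,
                            replace = TRUE, prob = zipf / sum(zipf)))
    fam_of_gene <- sort(fam_of_gene)
    trna <- data.frame(
      gene_id = sprintf("trna%04d", seq_along(fam_of_gene)),
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = sample(c("+", "-"), length(fam_of_gene), replace = TRUE),
      anticodon = fams$anticodon[fam_of_gene],
      isotype = fams$isotype[fam_of_gene],
      stringsAsFactors = FALSE
    )
    trna$family_id <- paste0(trna$isotype, "-", trna$anticodon)
    trna$excluded <- FALSE

    # placement units: same-family chains (2-3 genes) and isolated singles
    gap_bp <- round(config$cluster_gap_kb * 1000)
    units <- list()
    for (f in unique(trna$family_id)) {
      members <- trna$gene_id[trna$family_id == f]
      clustered <- members[stats::runif(length(members)) < config$clustered_fraction]
      isolated <- setdiff(members, clustered)
      if (length(clustered) == 1L) { # a gene cannot cluster alone
        isolated <- c(isolated, clustered); clustered <- character(0)
      }
      while (length(clustered) >= 2L) {
        take <- min(length(clustered), sample(2:3, 1))
        if (length(clustered) - take == 1L) take <- length(clustered)
        units[[length(units) + 1L]] <- clustered[seq_len(take)]
        clustered <- clustered[-seq_len(take)]
      }
      for (g in isolated) units[[length(units) + 1L]] <- g
    }
    units <- units[sample(length(units))]
    gene_len <- 72L
    pos <- stats::setNames(rep(10000L, length(chroms)), chroms)
    ci <- 0L
    for (u in units) {
      ci <- ci %% length(chroms) + 1L
      chrom <- chroms[ci]
      at <- pos[[chrom]] + round(gap_bp * stats::runif(1, 5, 20))
      for (g in u) {
        i <- match(g, trna$gene_id)
        trna$chrom[i] <- chrom
        trna$start[i] <- as.integer(at)
        trna$end[i] <- as.integer(at + gene_len)
        at <- at + gene_len + round(gap_bp * stats::runif(1, 0.2, 0.8))
      }
      pos[[chrom]] <- at
    }
    trna$start <- as.integer(trna$start); trna$end <- as.integer(trna$end)

    list(transcripts = transcripts, pc_coords = pc_coords,
         trna_genes = trna, families = fams, codon_weights = w)
  })
}

#' Generate mRNA and tRNA count matrices with known truth
#'
#' Protein-coding log2 means are baseline + per-tissue effect + linear stage
#' trend + per-sample noise; counts are negative binomial with a shared
#' dispersion. tRNA anticodon-family abundances are coupled to the
#' expression-weighted codon demand at the configured Spearman
#' `coupling_rho` via a Gaussian copula on ranks (the family-abundance
#' multiset equals the demand multiset, reordered by a noisy latent rank),
#' and distributed over member genes. Compensated families are split into
#' two clusters whose per-stage shares run in opposite directions while the
#' family total stays constant across stages.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return list with `mrna_counts` and `trna_counts` ([count_matrix()]s) and
#'   `truth` (true means, cluster memberships, silent genes, coupling).
#' @export
simulate_counts <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  code <- load_genetic_code()
  with_seed(config$seed + 1L, {
    tissues <- config$tissues; stages <- config$stages
    S <- length(stages); R <- config$replicates
    x <- seq(-1, 1, length.out = S)

    smp <- expand.grid(replicate = seq_len(R), stage = stages, tissue = tissues,
                       stringsAsFactors = FALSE)
    smp <- smp[, c("tissue", "stage", "replicate")]
    ids <- sample_id(smp$tissue, smp$stage, smp$replicate)

    # --- protein-coding means and counts ---------------------------------
    n <- nrow(genome$transcripts)
    genes <- genome$transcripts$gene_id
    b <- stats::rnorm(n, log2(config$pc_base_mean), 1.2)
    Tef <- matrix(stats::rnorm(n * length(tissues), 0, config$tissue_effect_sd),
                  n, dimnames = list(genes, tissues))
    shared <- stats::rnorm(n, 0, config$stage_effect_sd)
    slope <- sqrt(config$stage_shared_frac) * matrix(shared, n, length(tissues)) +
      sqrt(1 - config$stage_shared_frac) *
        matrix(stats::rnorm(n * length(tissues), 0, config$stage_effect_sd), n)
    dimnames(slope) <- list(genes, tissues)
    depth <- stats::setNames(stats::rnorm(length(ids), 0, config$depth_log2_sd), ids)

    mu_cond <- function(tissue, stage) { # true mean, no depth/noise
      2^(b + Tef[, tissue] + slope[, tissue] * x[match(stage, stages)])
    }
    mrna <- matrix(0L, n, length(ids), dimnames = list(genes, ids))
    for (j in seq_along(ids)) {
      mu <- mu_cond(smp$tissue[j], smp$stage[j]) *
        2^(depth[j] + stats::rnorm(n, 0, config$noise_sd))
      mrna[, j] <- stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }

    # --- codon demand per tissue (stage-averaged true means) -------------
    cc <- codon_count_table(genome$transcripts, code)
    kb <- genome$transcripts$length_nt / 1000
    demand <- sapply(tissues, function(tt) {
      e <- rowMeans(sapply(stages, function(ss) mu_cond(tt, ss))) / kb
      u <- colSums(cc[, code$sense_codons, drop = FALSE] * e)
      u / sum(u)
    })
    rownames(demand) <- code$sense_codons

    # --- tRNA family abundances coupled to demand ------------------------
    trna <- genome$trna_genes
    fams <- genome$families
    F <- nrow(fams)
    r_pearson <- 2 * sin(pi * config$coupling_rho / 6) # Gaussian-copula inverse

    fam_sizes <- table(trna$family_id)[fams$family_id]
    # silent genes: sampled per family, keeping >= 2 active where possible
    silent <- character(0)
    for (f in fams$family_id) {
      members <- trna$gene_id[trna$family_id == f]
      n_sil <- min(stats::rbinom(1, length(members), config$trna_silent_frac),
                   max(0L, length(members) - 2L))
      if (n_sil > 0) silent <- c(silent, sample(members, n_sil))
    }
    active <- setdiff(trna$gene_id, silent)

    # compensated families: need >= 6 active genes
    n_active_fam <- table(trna$family_id[trna$gene_id %in% active])
    eligible <- names(n_active_fam)[n_active_fam >= 6]
    comp_fams <- config$compensated_families
    if (is.null(comp_fams)) {
      comp_fams <- sort(sample(eligible, round(0.59 * length(eligible))))
    } else {
      missing <- setdiff(comp_fams, eligible)
      if (length(missing) > 0) {
        stopf("compensated families without >= 6 active genes: %s",
              paste(missing, collapse = ", "))
      }
    }

    total_trna <- config$n_trna_genes * config$trna_base_mean
    trna_mu <- array(0, dim = c(nrow(trna), length(tissues), S),
                     dimnames = list(trna$gene_id, tissues, stages))
    clusters <- list()
    fam_share <- matrix(NA_real_, F, length(tissues),
                        dimnames = list(fams$family_id, tissues))
    for (ti in seq_along(tissues)) {
      d <- demand[fams$codon, ti]
      zr <- stats::qnorm((rank(d, ties.method = "first") - 0.375) / (F + 0.25))
      zl <- r_pearson * zr + sqrt(1 - r_pearson^2) * stats::rnorm(F)
      wf <- sort(d)[rank(zl, ties.method = "first")] # demand multiset, rank-coupled
      share <- wf / sum(wf)
      fam_share[, ti] <- share
      for (fi in seq_len(F)) {
        f <- fams$family_id[fi]
        members <- intersect(trna$gene_id[trna$family_id == f], active)
        if (length(members) == 0) next
        fam_total_s <- if (f %in% comp_fams) {
          rep(share[fi] * total_trna, S) # held constant across stages
        } else {
          share[fi] * total_trna * 2^stats::rnorm(S, 0, 0.05)
        }
        if (f %in% comp_fams) {
          half <- ceiling(length(members) / 2)
          a_genes <- members[seq_len(half)]
          b_genes <- setdiff(members, a_genes)
          if (ti == 1L) clusters[[f]] <- list(a = a_genes, b = b_genes)
          a_share <- 0.5 + config$compensation_amplitude * x # rises with stage
          wa <- stats::rgamma(length(a_genes), 2); wa <- wa / sum(wa)
          wb <- stats::rgamma(length(b_genes), 2); wb <- wb / sum(wb)
          for (s in seq_len(S)) {
            trna_mu[a_genes, ti, s] <- fam_total_s[s] * a_share[s] * wa
            trna_mu[b_genes, ti, s] <- fam_total_s[s] * (1 - a_share[s]) * wb
          }
        } else {
          wg <- stats::rgamma(length(members), 2); wg <- wg / sum(wg)
          for (s in seq_len(S)) trna_mu[members, ti, s] <- fam_total_s[s] * wg
        }
      }
    }
    trna_mu[silent, , ] <- 0.1 # background-level, below any expression call

    tdepth <- stats::setNames(stats::rnorm(length(ids), 0, config$depth_log2_sd), ids)
    tcounts <- matrix(0L, nrow(trna), length(ids),
                      dimnames = list(trna$gene_id, ids))
    for (j in seq_along(ids)) {
      mu <- trna_mu[, match(smp$tissue[j], tissues), match(smp$stage[j], stages)] *
        2^(tdepth[j] + stats::rnorm(nrow(trna), 0, 0.1))
      tcounts[, j] <- stats::rnbinom(nrow(trna), mu = mu,
                                     size = 1 / config$nb_dispersion)
    }

    truth <- list(
      config = config,
      baseline_log2 = b, tissue_effect = Tef, stage_slope = slope,
      stage_x = x, depth_log2 = depth, trna_depth_log2 = tdepth,
      codon_demand = demand, family_share = fam_share,
      trna_mu = trna_mu, silent_genes = sort(silent),
      compensated_families = comp_fams, compensation_clusters = clusters,
      coupling_rho = config$coupling_rho
    )
    list(
      mrna_counts = count_matrix(mrna, stages = stages),
      trna_counts = count_matrix(tcounts, stages = stages),
      truth = truth
    )
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_genome()] then [simulate_counts()].
#'
#' @param config a [sim_config()].
#' @return list with `transcripts`, `pc_coords`, `trna_genes`, `families`,
#'   `mrna_counts`, `trna_counts`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  cnt <- simulate_counts(config, genome)
  c(genome[c("transcripts", "pc_coords", "trna_genes", "families")],
    cnt, list(config = config))
}

#' True differentially expressed protein-coding genes between two stages
#'
#' @param truth `truth` element of [simulate_counts()].
#' @param stage_a,stage_b,tissue condition pair.
#' @param lfc_threshold absolute true log2 fold change defining "true DE".
#' @return Character vector of gene ids.
#' @export
true_de_genes <- function(truth, stage_a, stage_b, tissue, lfc_threshold = 1) {
  stages <- truth$config$stages
  dx <- truth$stage_x[match(stage_b, stages)] - truth$stage_x[match(stage_a, stages)]
  lfc <- truth$stage_slope[, tissue] * dx
  names(lfc)[abs(lfc) >= lfc_threshold]
}

#' Simulate chromatin-mark intervals around tRNA genes
#'
#' Places a short mark interval near each gene of `positive_set` with
#' probability `p_positive` and near the remaining genes with probability
#' `p_background`, plus uniform random background intervals, emulating a
#' histone-mark peak set that preferentially decorates a designated gene set.
#'
#' @param trna_genes tRNA annotation data.frame.
#' @param positive_set gene ids preferentially marked.
#' @param p_positive,p_background marking probabilities.
#' @param offset_bp maximum distance of the mark from the gene boundary.
#' @param n_random number of unrelated background intervals.
#' @param chrom_length_bp chromosome length for background placement.
#' @param seed integer seed.
#' @return A `GRanges` of mark intervals.
#' @export
simulate_chromatin_marks <- function(trna_genes, positive_set,
                                     p_positive = 0.8, p_background = 0.1,
                                     offset_bp = 300, n_random = 100,
                                     chrom_length_bp = 25e6, seed = 1) {
  with_seed(seed, {
    p <- ifelse(trna_genes$gene_id %in% positive_set, p_positive, p_background)
    hit <- stats::runif(nrow(trna_genes)) < p
    marked <- trna_genes[hit, , drop = FALSE]
    off <- round(stats::runif(nrow(marked), 0, offset_bp))
    side <- sample(c(-1, 1), nrow(marked), replace = TRUE)
    start <- ifelse(side < 0, marked$start - off - 200, marked$end + off)
    chrom <- c(marked$chrom,
               sample(unique(trna_genes$chrom), n_random, replace = TRUE))
    rs <- sample.int(chrom_length_bp - 200L, n_random)
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = pmax(1, c(start, rs)) + 1L,
                                width = 200L)
    )
    sort(gr)
  })
}
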