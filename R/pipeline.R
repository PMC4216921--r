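# End-to-end orchestration: expression calling -> normalization -> DE -> PCA
# -> usage/abundance profiles -> interface correlations (plain and
# wobble-corrected) -> shuffled backgrounds -> compensation screen ->
# genomic clusters -> optional colocalization / chromatin association.
# Driven by a configuration list (or YAML file); every stochastic step takes
# an explicit seed recorded in the manifest, so identical configurations
# give identical outputs.

write_tsv_meta <- function(df, path, meta) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

# Replicate-mean normalized expression for one tissue/stage condition.
condition_expression <- function(expr, tissue, stage) {
  sel <- expr$samples$tissue == tissue & expr$samples$stage == stage
  if (!any(sel)) stopf("no samples for %s %s", tissue, stage)
  rowMeans(expr$values[, sel, drop = FALSE])
}

default_pipeline_config <- function() {
  list(
    simulate = list(),          # sim_config() arguments; NULL -> read inputs
    inputs = NULL,              # list(cds_fasta=, trna_bed=, mrna_counts=, trna_counts=, stages=)
    stages_run = c("expression", "de", "pca", "usage", "background",
                   "compensation", "clusters", "colocalization"),
    min_reads = 10,
    de_alpha = 0.001,
    comp_alpha = 0.05,
    comp_correction = "bonferroni",
    background_reps = 100,
    n_rand = 1000,
    coloc_windows_kb = c(10, 50, 100),
    coloc_alphas = c(0.1, 0.05, 0.01),
    seed = 1
  )
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    data <- simulate_dataset(do.call(sim_config, sim_args))
    return(data)
  }
  inp <- cfg$inputs
  need <- c("cds_fasta", "trna_bed", "mrna_counts", "trna_counts")
  missing <- need[!vapply(need, function(k) !is.null(inp[[k]]) && file.exists(inp[[k]]),
                          logical(1))]
  if (length(missing) > 0) {
    stopf("missing required input(s): %s", paste(missing, collapse = ", "))
  }
  list(
    transcripts = read_cds_fasta(inp$cds_fasta),
    trna_genes = read_trna_annotation(inp$trna_bed),
    mrna_counts = read_counts(inp$mrna_counts, stages = inp$stages),
    trna_counts = read_counts(inp$trna_counts, stages = inp$stages),
    pc_coords = if (!is.null(inp$pc_bed)) {
      gr <- read_bed(inp$pc_bed)
      data.frame(gene_id = gr$name,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
    } else NULL
  )
}

#' Run the full codon-anticodon analysis pipeline
#'
#' Executes the analysis stages selected in the configuration on either a
#' simulated dataset (`config$simulate`, a list of [sim_config()]
#' arguments) or on files named in `config$inputs`. Writes TSV outputs and
#' a manifest (configuration echo, seeds, package version) to `out_dir` and
#' returns the results invisibly. Identical configurations produce
#' identical outputs.
#'
#' @param config configuration list (see `codonbalance:::default_pipeline_config`
#'   for the recognised fields and defaults) or the path of a YAML file
#'   holding one.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the computed objects.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("codonbalance_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config,
                           keep.null = FALSE)
  if (!is.null(config$simulate) || is.null(config$inputs)) {
    cfg$simulate <- config$simulate %||% list()
    cfg$inputs <- NULL
  } else {
    cfg$simulate <- NULL
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- cfg$stages_run
  code <- load_genetic_code()
  res <- list(config = cfg)

  data <- load_pipeline_inputs(cfg)
  res$data <- data
  stages <- data$mrna_counts$stages
  tissues <- unique(data$mrna_counts$samples$tissue)

  # --- expression calling and normalization ------------------------------
  expressed <- call_expressed_trnas(data$trna_counts, cfg$min_reads)
  writeLines(expressed, file.path(out_dir, "expressed_trnas.txt"))
  mrna_expr <- normalize_counts(data$mrna_counts)
  trna_expr <- normalize_counts(data$trna_counts)
  res$expressed_trnas <- expressed
  res$mrna_expr <- mrna_expr; res$trna_expr <- trna_expr
  write_tsv_meta(
    data.frame(sample_id = names(mrna_expr$size_factors),
               mrna = unname(mrna_expr$size_factors),
               trna = unname(trna_expr$size_factors)),
    file.path(out_dir, "size_factors.tsv"), "median-of-ratios size factors")

  # --- differential expression ------------------------------------------
  if ("de" %in% run) {
    first <- stages[1]; last <- stages[length(stages)]
    de <- list()
    for (tt in tissues) {
      de[[paste0("mrna.", tt)]] <- de_test(data$mrna_counts, first, last, tt,
                                           alpha = cfg$de_alpha)
      de[[paste0("trna.", tt)]] <- de_test(data$trna_counts, first, last, tt,
                                           alpha = cfg$de_alpha)
    }
    res$de <- de
    for (nm in names(de)) {
      write_tsv_meta(de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")),
                     sprintf("NB Wald DE, BH-corrected, alpha=%g", cfg$de_alpha))
    }
  }

  # --- PCA ---------------------------------------------------------------
  if ("pca" %in% run) {
    res$pca_mrna <- spearman_pca(mrna_expr)
    res$pca_trna <- spearman_pca(trna_expr, gene_subset = expressed)
    for (nm in c("pca_mrna", "pca_trna")) {
      p <- res[[nm]]
      df <- data.frame(p$samples, p$scores[, 1:min(4, ncol(p$scores))])
      write_tsv_meta(df, file.path(out_dir, paste0(nm, ".tsv")),
                     paste0("PCA on pairwise Spearman correlations; varfrac=",
                            paste(signif(p$variance_fraction[1:4], 4), collapse = ",")))
    }
  }

  # --- usage profiles and interface correlations -------------------------
  if ("usage" %in% run) {
    cc <- codon_count_table(data$transcripts, code)
    lens <- stats::setNames(data$transcripts$length_nt, data$transcripts$gene_id)
    pairing <- codon_family_pairing(code)
    rows <- list(); urow <- list()
    for (tt in tissues) for (ss in stages) {
      me <- condition_expression(mrna_expr, tt, ss)
      te <- condition_expression(trna_expr, tt, ss)[expressed]
      cu <- relative_usage(weighted_usage(cc, me, lens, "codon", code))
      au <- relative_usage(weighted_usage(cc, me, lens, "amino_acid", code))
      ta <- anticodon_abundance(te, data$trna_genes, "anticodon")
      ti <- anticodon_abundance(te, data$trna_genes, "isotype")
      ic <- interface_correlation(cu, ta, pairing)
      iso_pair <- stats::setNames(AA_THREE[unname(code$table[code$sense_codons])],
                                  code$sense_codons)
      ii <- {
        ct <- suppressWarnings(stats::cor.test(
          unname(au$values[AA_ONE[names(ti$values)]]),
          unname(ti$values), method = "spearman", exact = FALSE))
        list(rho = unname(ct$estimate), p = ct$p.value,
             n_pairs = length(ti$values))
      }
      wc <- wobble_corrected_correlation(cu, ta, code = code)
      rows[[paste(tt, ss)]] <- data.frame(
        tissue = tt, stage = ss,
        level = c("codon", "isotype", "codon_wobble"),
        rho = c(ic$rho, ii$rho, wc$rho),
        p = c(ic$p, ii$p, wc$p),
        n_pairs = c(ic$n_pairs, ii$n_pairs, wc$n_pairs))
      for (pr in list(cu, au, ta, ti)) {
        urow[[length(urow) + 1L]] <- data.frame(
          tissue = tt, stage = ss, kind = pr$kind,
          key = names(pr$values), value = unname(pr$values))
      }
    }
    res$interface <- do.call(rbind, rows)
    write_tsv_meta(res$interface, file.path(out_dir, "interface_correlations.tsv"),
                   "Spearman codon demand vs anticodon supply")
    write_tsv_meta(do.call(rbind, urow), file.path(out_dir, "usage_profiles.tsv"),
                   "relative usage/abundance per condition")
    res$codon_counts <- cc
  }

  # --- shuffled backgrounds (first tissue, all stages) -------------------
  if ("background" %in% run && "usage" %in% run) {
    cc <- res$codon_counts
    lens <- stats::setNames(data$transcripts$length_nt, data$transcripts$gene_id)
    bg_rows <- list()
    for (ss in stages) {
      tt <- tissues[1]
      me <- condition_expression(mrna_expr, tt, ss)
      te <- condition_expression(trna_expr, tt, ss)[expressed]
      bg <- background_distributions(cc, lens, me, te, data$trna_genes,
                                     mode = "expressed",
                                     n_reps = cfg$background_reps,
                                     seed = cfg$seed + match(ss, stages))
      obs <- res$interface$rho[res$interface$tissue == tt &
                                 res$interface$stage == ss &
                                 res$interface$level == "codon"]
      cmpr <- compare_observed_to_background(obs, bg$rhos)
      bg_rows[[ss]] <- data.frame(
        tissue = tt, stage = ss, observed = cmpr$observed,
        bg_mean = cmpr$background_mean, bg_max = cmpr$background_max,
        exceedance = cmpr$exceedance)
    }
    res$background <- do.call(rbind, bg_rows)
    write_tsv_meta(res$background, file.path(out_dir, "background.tsv"),
                   sprintf("%d expression shuffles per stage", cfg$background_reps))
  }

  # --- compensation screen ----------------------------------------------
  if ("compensation" %in% run) {
    res$compensation <- list()
    for (tt in tissues) {
      fe <- family_stage_matrices(trna_expr, data$trna_genes, tt,
                                  genes = expressed)
      scr <- compensation_screen(fe, correction = cfg$comp_correction,
                                 alpha = cfg$comp_alpha, seed = cfg$seed)
      res$compensation[[tt]] <- scr
      if (!is.null(scr$table)) {
        write_tsv_meta(scr$table,
                       file.path(out_dir, paste0("compensation_", tt, ".tsv")),
                       sprintf("stage-permutation chi2 test, %s-corrected",
                               cfg$comp_correction))
      }
    }
  }

  # --- genomic clusters --------------------------------------------------
  if ("clusters" %in% run) {
    cl <- define_clusters(data$trna_genes)
    rnd <- cluster_randomization_test(data$trna_genes, cl,
                                      n_rand = cfg$n_rand, seed = cfg$seed)
    res$clusters <- cl; res$cluster_test <- rnd
    write_tsv_meta(
      data.frame(cluster = rep(seq_along(cl$clusters), lengths(cl$clusters)),
                 gene_id = unlist(cl$clusters)),
      file.path(out_dir, "clusters.tsv"),
      sprintf("%d clusters (gap <= %g kb); mean family colocalization %.1f%%, binomial p=%.3g",
              cl$n_clusters, cl$gap_kb, rnd$statistic, rnd$p_binomial))
    if ("compensation" %in% run && !is.null(res$compensation[[tissues[1]]]$table)) {
      tab <- res$compensation[[tissues[1]]]$table
      sig <- stats::setNames(tab$significant, tab$family_id)
      per_fam <- rnd$per_family[names(sig)]
      res$comp_vs_clustering <- tryCatch(
        compensation_vs_clustering(sig, per_fam),
        error = function(e) NULL)
    }
  }

  # --- colocalization (needs coordinates and DE tables) ------------------
  if ("colocalization" %in% run && "de" %in% run && !is.null(data$pc_coords)) {
    tt <- tissues[1]
    res$colocalization <- colocalization_screen(
      data$trna_genes, data$pc_coords,
      trna_de = res$de[[paste0("trna.", tt)]],
      pc_de = res$de[[paste0("mrna.", tt)]],
      windows_kb = cfg$coloc_windows_kb, alphas = cfg$coloc_alphas)
    write_tsv_meta(res$colocalization, file.path(out_dir, "colocalization.tsv"),
                   "KS test of up-regulated vs non-DE tRNA neighbour ratios")
  }

  # --- manifest ----------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), c("inputs"))], cfg_file)
  manifest <- list(
    package = "codonbalance",
    version = as.character(utils::packageVersion("codonbalance")),
    seed = as.integer(cfg$seed),
    config_hash = unname(tools::md5sum(cfg_file)),
    stages_run = run,
    n_expressed_trnas = length(expressed)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$out_dir <- out_dir
  invisible(res)
}
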