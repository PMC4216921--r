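# codonbalance

Tools for analysing the molecular interface between transcription and
translation: does the supply of tRNA anticodons track the demand for mRNA
codons as a transcriptome changes — across tissues, developmental stages, or
conditions?

During translation each coding sequence is read as a succession of triplet
codons (61 sense codons encoding 20 amino acids), and each codon is decoded
by a tRNA whose anticodon is its reverse complement — or, for "orphan"
codons with no genomically encoded Watson–Crick anticodon, by a wobbling
isoacceptor of the same isotype. `codonbalance` quantifies both sides of
this interface and the statistics that connect them:

- **Codon demand.** For gene *g* with per-codon counts *c<sub>g,k</sub>*
  (counted on the longest annotated CDS) and length-normalized expression
  *e<sub>g</sub>*, the usage of codon *k* is
  *U<sub>k</sub> = Σ<sub>g</sub> c<sub>g,k</sub> · e<sub>g</sub>*, and the
  relative usage is *u<sub>k</sub> = U<sub>k</sub> / Σ<sub>j</sub>
  U<sub>j</sub>*. Amino-acid usage aggregates codons through the genetic
  code.
- **Anticodon supply.** Per-gene tRNA quantifications (e.g. Pol III ChIP-seq
  occupancy at the gene locus ±100 bp) are summed within anticodon
  isoacceptor families and isotypes, after calling a gene expressed when at
  least one condition has ≥ 10 reads in every replicate.
- **The interface.** Spearman's ρ between relative codon usage and the
  relative abundance of each codon's Watson–Crick anticodon family
  (unencoded families excluded), with a wobble-corrected variant that
  redistributes each wobbling family's abundance over the codons it serves
  in proportion to their demand.
- **Null models.** 100 shuffled transcriptomes (expression values permuted
  over expressed or over all annotated genes) give background usage profiles
  and background interface correlations.
- **Within-family compensation.** For each isoacceptor family, all pairwise
  Spearman correlations of member-gene trajectories across stages are
  compared by χ² against the correlations obtainable by permuting the stage
  order — a bimodal observed distribution (two anti-correlated expression
  clusters with a stable family total) rejects the null.
- **Genomic context.** Chaining of tRNA genes into genomic clusters
  (gap ≤ 7.5 kb), a family-label randomization test for whether families
  colocalize, neighbour-ratio colocalization of differentially expressed
  tRNA and protein-coding genes (Kolmogorov–Smirnov), and chromatin-mark
  association (Fisher's exact test at 0.1/0.5/1 kb).

Differential expression between stages is delegated to DESeq2
(negative-binomial Wald test, Benjamini–Hochberg correction, significance
at adjusted *P* < 0.001), and PCA is performed on the matrix of pairwise
Spearman correlations between samples.

A first-class synthetic-data generator (`sim_config()`,
`simulate_dataset()`) emulates the study design all of this assumes — two
tissues × six stages × two replicates, negative-binomial counts dominated
by tissue identity, 433 tRNA genes in 47 families with genomic clustering,
a tunable codon–anticodon coupling, and designated compensated families —
so the entire pipeline runs and is tested without any external data.

## Worked example

```r
library(codonbalance)
cfg <- sim_config(seed = 1)        # the emulated study design
ds  <- simulate_dataset(cfg)

expressed <- call_expressed_trnas(ds$trna_counts, min_reads = 10)
cat(length(expressed), "of", nrow(ds$trna_genes), "tRNA genes called expressed\n")

code <- load_genetic_code()
cc   <- codon_count_table(ds$transcripts, code)
lens <- setNames(ds$transcripts$length_nt, ds$transcripts$gene_id)
expr <- normalize_counts(ds$mrna_counts)
trna <- normalize_counts(ds$trna_counts)
sel  <- expr$samples$tissue == "liver" & expr$samples$stage == "E15.5"

cu <- relative_usage(weighted_usage(cc, rowMeans(expr$values[, sel]), lens, "codon", code))
ta <- anticodon_abundance(rowMeans(trna$values[, sel])[expressed], ds$trna_genes, "anticodon")
ic <- interface_correlation(cu, ta)
wc <- wobble_corrected_correlation(cu, ta, code = code)

bg  <- background_distributions(cc, lens, rowMeans(expr$values[, sel]),
                                rowMeans(trna$values[, sel])[expressed],
                                ds$trna_genes, n_reps = 100, seed = 2)
cmp <- compare_observed_to_background(ic$rho, bg$rhos)

fe  <- family_stage_matrices(trna, ds$trna_genes, "liver", genes = expressed)
scr <- compensation_screen(fe, correction = "bonferroni", alpha = 0.05)
```

which prints:

```
318 of 433 tRNA genes called expressed
codon-anticodon interface: rho = 0.73 (p = 4.5e-09, 47 pairs)
wobble-corrected:          rho = 0.53 (14 orphan codons)
shuffled background:       max rho = 0.21, exceedance P = 0.010
compensated families:      17 of 27 with >= 6 genes
```

Reading: roughly three quarters of the annotated tRNA genes are
transcriptionally active; codon demand and anticodon supply are strongly
rank-correlated (ρ = 0.73 over the 47 encoded families) and remain clearly
correlated after accounting for wobble decoding of the 14 orphan codons;
no shuffled transcriptome comes close to the observed correlation; and a
majority of the isoacceptor families large enough to test show the
two-cluster compensation signature. `run_pipeline()` executes the same
stages (plus DE, PCA, clustering and colocalization) from a single
configuration and writes TSV outputs with a manifest.

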