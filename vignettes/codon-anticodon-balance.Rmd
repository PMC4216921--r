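---
title: "Balancing codon demand and anticodon supply: models and methods"
author: "codonbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing codon demand and anticodon supply: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbalance)
```

# The question and the quantities

A transcriptome places a demand on the translational machinery: each
expressed mRNA contributes its codons in proportion to its abundance. The
machinery's capacity to meet that demand is set by the pool of tRNAs,
measured per gene (e.g. as Pol III occupancy at tRNA loci) and pooled into
anticodon isoacceptor families. `codonbalance` asks, for each tissue and
developmental stage, whether supply tracks demand, and by which regulatory
arithmetic — including the striking within-family *compensation* pattern in
which individual tRNA genes of a family move in opposite directions while
the family total stays put.

Two usage vectors are at the core. For gene $g$ with in-frame codon counts
$c_{g,k}$ (counted on the longest annotated CDS; genes with ambiguous bases
or lengths not divisible by three are dropped rather than imputed, because
the counts must be exact) and library-size-normalized expression $x_g$, we
weight each count by expression per kilobase of the counted sequence,

$$U_k \;=\; \sum_g c_{g,k}\,\frac{x_g}{L_g/1000},
\qquad u_k \;=\; \frac{U_k}{\sum_j U_j},$$

and aggregate $u$ to amino acids through the genetic code. The choice of
CDS length (rather than full transcript length) for $L_g$ follows from the
codons being counted on the CDS; a caller who prefers full transcript
lengths can pass them explicitly. Stop codons carry no tRNA and are
excluded from usage; selenocysteine is excluded throughout. On the supply
side, family abundance is the sum of member-gene expression, normalized the
same way.

The interface statistic is Spearman's $\rho$ between $u$ and the abundance
of each codon's Watson–Crick anticodon family (the anticodon, written
5'→3', is the codon's reverse complement). Codons whose family is not
genomically encoded are excluded from the correlation; rank correlation is
used because the two vectors live on different measurement scales.

# The synthetic study

Everything in the package is exercised against a generator
(`sim_config()`, `simulate_genome()`, `simulate_counts()`) that emulates a
developmental atlas: two tissues (liver, brain) at six ordered stages
(E15.5 … P29) in two replicates; 2,000 protein-coding genes; 433 tRNA genes
in 47 anticodon families covering all 20 isotypes. Those sizes are the
package's defaults and the problem sizes used by the test suite; they keep
a full pipeline run under a minute on one CPU while preserving every
structural feature the statistics depend on.

Design choices worth knowing:

* **Counts are negative binomial** with a single shared dispersion
  (default 0.05), means built from a per-gene baseline, a per-tissue offset
  (log2 SD 2 by default), a linear stage trend (log2 SD 0.5), and
  per-sample noise and depth factors. Tissue effects dominate stage effects
  by an order of magnitude of variance, which is what makes the first
  principal component of the sample-correlation matrix a tissue axis.
* **Stage trends are correlated between tissues** (`stage_shared_frac`,
  default 0.7): a substantial part of a developmental program —
  proliferation shutdown, metabolic maturation — is shared between organs.
  With fully independent per-tissue trends there is no single "stage" axis
  and the second principal component is an arbitrary rotation of the two
  tissues' gradients; the shared component gives the sample-correlation PCA
  the structure real developmental series show (PC1 tissue, PC2 stage, in
  both tissues at once).
* **Codon frequencies are biased.** Synthetic CDS are drawn codon by codon
  with weights spanning an ~8-fold range across the 61 sense codons
  (`codon_weights = "biased"`), the order of magnitude of real codon-usage
  bias. A uniform model is available but degenerate for rank statistics:
  with all frequencies tied at 1/61, codon "ranks" are pure sampling noise
  and neither the interface correlation nor the shuffle-convergence
  property is well defined.
* **Coupling is imposed at the family level**, not per gene, mirroring the
  finding that families, not individual genes, are stable. The family
  abundance multiset equals the codon-demand multiset, reordered by a
  latent Gaussian rank: with target Spearman $\rho_s$, the latent Pearson
  correlation is set to $r = 2\sin(\pi\rho_s/6)$ (the exact bivariate
  normal inversion), so the target is achieved in expectation without any
  calibration loop. At `coupling_rho = 1` supply equals demand exactly on
  ranks; at 0 they are independent.
* **Compensated families** (by default ~59% of families with ≥ 6 active
  genes) are split into two gene clusters whose per-stage shares run
  linearly from $0.5-a$ to $0.5+a$ (amplitude $a = 0.35$) in opposite
  directions; the family total is held constant across stages. In the
  generated truth, within-cluster trajectories are perfectly rank
  correlated and cross-cluster trajectories perfectly anti-correlated;
  count noise then degrades both, which is what the compensation test has
  to see through.
* **Placement.** ~93% of tRNA genes are laid down in same-family chains
  with intra-chain gaps below 7.5 kb, chains and singletons separated by
  much larger gaps; ~28% of genes are silent (never expressed), so the
  expressed set lands near three quarters of the annotation, as in real
  Pol III data.

What the generator does *not* emulate: multi-mapping and alignment
artefacts, sequence-level realism (tRNA gene bodies are uniform 72-bp
intervals), per-gene dispersion variation, batch effects, and any
mechanistic coupling between chromatin marks and expression (marks are
simulated directly at designated genes). Tests passing on this synthetic
data therefore validate the statistical machinery — calibration, power
against constructed truth, conservation laws, determinism — not the
biological conclusions one would draw from real data.

# Statistical procedures and their numerical choices

## Expression calling and normalization

A tRNA gene is *expressed* if some tissue–stage condition has at least 10
reads in every replicate (the rule is defined on both replicates, so a
condition with a single replicate is an error, not a silent pass). Counts
are assumed pre-windowed to the locus ± 100 bp — an upstream counting
concern documented as part of the input contract.

Size factors are median-of-ratios over genes with all-positive counts
(verified in the tests against DESeq2's implementation); when no such gene
exists the package falls back to total-count scaling with a warning rather
than failing, since degenerate fixtures and very sparse tRNA matrices are
legitimate inputs.

## Differential expression

`de_test()` wraps DESeq2 — a negative-binomial Wald test with
median-of-ratios normalization and dispersion moderation — and applies the
Benjamini–Hochberg correction with a default significance threshold of
adjusted $P < 0.001$. An externally produced DE table can be supplied
instead and is validated and thresholded identically, so results from any
other DE tool can be slotted into the downstream colocalization and
chromatin analyses. Calibration is checked in the test suite against
synthetic truth: null rejection rate at the nominal level within binomial
tolerance, and realized false-discovery proportion at most twice the
nominal rate under a 20% spike-in of 8-fold changes with two replicates
per group.

## PCA on the Spearman matrix

PCA is applied to the samples × samples matrix of pairwise Spearman rank
correlations (centred, then eigendecomposed via `prcomp`). Because ranks
are invariant under monotone per-sample transforms, so is the whole
result — a useful property when the two assays being compared (RNA-seq and
ChIP-seq) have very different dynamic ranges. Variance fractions are
reported both raw and as the share of variance *remaining* after earlier
components, the convention used when one says "the second component
explains X% of the remaining variance and orders the samples by stage."
A constant sample vector would produce undefined correlations; the error
names the offending sample.

## Shuffled-transcriptome backgrounds

`shuffle_expression()` permutes the observed expression values across
genes — a measure-preserving rearrangement, so every background
transcriptome spends exactly the observed expression budget. In
*all-annotated* mode the multiset is padded with zeros up to the size of
the annotated universe before permuting; padding (rather than resampling,
which is available behind a flag) preserves the observed totals exactly.
One hundred shuffles per condition reproduce the background usage
distributions; shuffled mRNA replicate $i$ is paired with shuffled tRNA
replicate $i$ for the background correlations (a crossed 100 × 100 mode
exists for sensitivity analysis). The observed correlation is summarized
against the background by the empirical exceedance
$(\#\{\rho_{bg} \ge \rho_{obs}\}+1)/(n+1)$.

## Wobble correction

Orphan codons are sense codons whose Watson–Crick anticodon is absent from
the encoded families (14 of 61 under the generator's 47-family universe).
Each orphan is assigned to an encoded family of the same isotype whose
anticodon differs only at position 34 and whose wobble base can read the
orphan's third base under the rule table G34 → {C, U}, U34 → {A, G},
A34 (inosine) → {U, C, A}, C34 → {G}; ties are broken by the fixed
preference G34 > A34 > U34 > C34, and the table is caller-editable because
published wobble matrices differ at the margins. A family serving several
codons splits its abundance across them in proportion to codon demand
(equal split if all demands are zero); total availability equals total
mapped abundance to numerical precision, an invariant the tests enforce at
1e-9 over a thousand random family universes. Orphans with no eligible
decoder are excluded from the corrected correlation and reported, matching
the treatment of unencoded families in the uncorrected statistic. With no
orphans the corrected correlation reduces exactly to the plain one.

## The compensation test

For each family with more than two usable genes (constant trajectories are
excluded with a warning), the observed statistic set is all pairwise
Spearman correlations across the stage-ordered replicate means. The null
holds one gene of a pair fixed and permutes the other's stage order — only
the relative ordering matters for rank correlation — enumerating all
$S! = 720$ orderings at six stages and sampling (seeded) beyond a cap of
720. The null is exactly centred: orderings come in reversal pairs with
opposite correlations, so the enumerated mean is zero to machine
precision.

Observed and null are binned on 20 shared equal-width bins over $[-1, 1]$
and compared by a χ² goodness-of-fit test. Binning is where small families
live or die, and the merge rule matters: cells are accumulated from the
two tails inward until each reaches an expected count of five, and the
centre remainder keeps its own cell down to an expected count of one
(Cochran's condition tolerates a minority of cells between 1 and 5).
Folding the centre into the tails — the naive merge — erases precisely the
centre deficit that distinguishes a bimodal correlation distribution from
the unimodal null, and costs most of the power at 6-gene families (15
pairs support at most three cells of expected ≥ 5). With the retained
centre cell the test is measured at type-I error 0.04–0.06 at
$\alpha = 0.05$ and power ~1 on generator-constructed two-cluster families
of six or more genes.

The screen tests every family with ≥ 3 usable genes but corrects across —
and reports — only families with ≥ 6 genes (smaller families carry too few
pairs for a meaningful call). Bonferroni is the default correction, with
Benjamini–Hochberg available; both appear in the field's practice for this
test and the package does not adjudicate. When a family is significant its
genes are split into two expression clusters by the sign of the leading
eigenvector of the gene–gene correlation matrix, and a descriptive
bimodality score (the balanced fraction of strong positive/negative pairs)
is emitted alongside — it is not the decision rule.

## Genomic clusters and colocalization

Clusters are maximal same-chromosome chains of ≥ 2 tRNA genes with
end-to-start gaps ≤ 7.5 kb (intergenic distance; a midpoint mode exists
behind a flag), verified against a brute-force all-pairs union-find oracle.
The family-label randomization test preserves family sizes and the cluster
layout while relabelling genes 1,000 times; the statistic is the mean over
families of the percentage of members colocalizing with a same-family
gene. Two p-values are reported: the binomial test of the observed
colocalizing-gene count against the null-expected rate (the classical
headline) and the empirical exceedance over the randomizations. The
binomial version is anti-conservative — colocalization events within one
cluster are positively dependent, and the measured null false-positive
rate is ~18% at $\alpha = 0.05$ — so the empirical p-value is the one to
trust for calibration; both are kept because the binomial number is what
this literature quotes.

Colocalization of differentially expressed tRNA and protein-coding genes
uses, for each up-regulated tRNA gene, the ratio of up-regulated to total
protein-coding genes within a symmetric window (10/50/100 kb; genes with
no neighbour are excluded and counted), comparing up-regulated against
non-DE tRNA genes by the two-sample Kolmogorov–Smirnov statistic. At
realistic gene densities the ratios are heavily tied small fractions, and
the continuous-case KS p-value is grossly conservative (median null p
≈ 0.99 in simulation); the default p-value therefore refers the D
statistic to its group-label permutation distribution (999 permutations,
seeded), which is valid under ties and measured uniform under the
generator's null. The asymptotic formula remains available.

Chromatin association expands each tRNA gene by 0.1/0.5/1 kb and tests the
2 × 2 table of set membership × mark presence with a two-sided Fisher's
exact test; the implementation is checked against direct hypergeometric
enumeration to 1e-12.

## Tolerances, ties, degenerate inputs

All "sums to one" checks use 1e-9; conservation and cross-implementation
identities use 1e-12; determinism contracts (same configuration, same
seed) are exact. Quantile splits order genes by expression with ties
broken by gene id, so high/low partitions are reproducible. Spearman
p-values use the asymptotic approximation (`exact = FALSE`) uniformly,
since tied profiles are routine. Every stochastic step takes an explicit
seed; seeded helpers restore the caller's RNG state, so library calls
never perturb user scripts.

# Limitations

The compensation χ² treats the $n(n-1)/2$ pairwise correlations as a
sample although pairs sharing a gene are not independent; the measured
type-I error stays below nominal ×1.6 at the sizes reported here, but the
p-values are approximate, and 6-gene families rarely survive Bonferroni
correction — detection concentrates at ≥ 8 genes. The DE wrapper does not
shrink fold changes. The wobble table is a default, not a measurement;
isotypes with several candidate decoders may be assigned differently than
by a modification-aware model. The generator's silent-gene and
family-size distributions are stylized; none of the acceptance-style
checks depend on their exact shape.
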