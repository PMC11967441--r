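---
title: "Methods: comparative ear-transcriptome phasing and QTL/QTN candidate integration"
author: "earphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative ear-transcriptome phasing and QTL/QTN candidate integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earphase)
```

## The analysis in one paragraph

Kernel row number (KRN) in maize is set during early ear (inflorescence)
development. `earphase` implements a comparative candidate-gene workflow for
this trait: two inbred lines with contrasting KRN are profiled by bulk
RNA-seq at five vegetative stages (V6–V10, leaf-collar staging) with three
biological replicates, giving 30 libraries. Per stage, genes differentially
expressed between the lines ("line-specific" DEGs) are called with a
negative-binomial Wald test at fold change ≥ 2 and BH-adjusted p < 0.05.
The stage trajectories of these DEGs are soft-clustered (fuzzy c-means), and
the five stages are partitioned into two contiguous phases at the split that
maximizes between-phase versus within-phase distance of the stage profiles —
on data shaped like real ear development this yields Phase I = V6–V8 and
Phase II = V9–V10. Phase-I line-specific DEGs are then intersected with two
layers of genetic evidence compiled from the mapping literature: QTL
hotspots (intervals where QTLs from at least two studies overlap) and 200 kb
windows around trait-associated QTNs (100 kb each side). Genes carrying both
layers of evidence — inside a hotspot and inside the window of a QTN that
itself lies in that hotspot — form the high-probability candidate set.

## Differential expression model

Counts \(K_{gj}\) follow a negative binomial with mean \(\mu_{gj} = s_j
q_{gc(j)}\) and variance \(\mu + \alpha_g \mu^2\). Size factors \(s_j\) are
median-of-ratios: the median across reference genes (positive counts in all
samples) of the count divided by the gene's geometric mean. Group means are
maximized by per-gene Newton iterations on the log scale; the Wald statistic
is \(\hat\beta/\mathrm{SE}\) with \(\hat\beta = \log(\hat\mu_B +
\tfrac12) - \log(\hat\mu_A + \tfrac12)\) (the half-count pseudo-mean guards
all-zero groups) and the standard error from the observed information,
referred to the normal distribution. Genes with total normalized count
below 10 are not tested and do not enter the BH correction. The fold-change
gate is inclusive (exactly 2-fold qualifies); the adjusted-p gate is strict
(exactly 0.05 does not).

**Dispersion estimation and small-sample calibration.** Gene-wise
dispersions are method-of-moments on normalized counts with group means
absorbed, shrunk (weight 0.2) on the log scale toward the 20%-trimmed mean.
With three replicates per group the raw moment estimate is extremely noisy
and falls below the truth for roughly half the genes, which makes a plug-in
Wald test sharply anticonservative (empirical type-I error near 0.12 at a
nominal 0.05 in our simulations). Rather than change the reference
distribution — a t reference with residual df repairs the null but caps the
attainable p-value so strongly that a true 4-fold change can no longer pass
BH correction — we floor the shrunken estimates at 1.3 times the central
(trimmed-mean) dispersion whenever the smallest group has five or fewer
replicates. Genes whose data support a higher dispersion keep it; genes
whose estimate dips below the center are treated as at least typically
dispersed. The 1.3 factor covers the typical spread of true dispersions
around their center. Under this rule the test suite measures type-I error
of about 0.04–0.055 under a heterogeneous-dispersion null and full power
for 4-fold effects at \(\mu = 200\), \(n = 3\). `center_floor = 0` restores
the bare estimator (appropriate for designs with many replicates, where the
floor is disabled by default anyway).

A consequence worth knowing: the *union* of DEG sets over five stages has a
higher empirical false-discovery proportion than any single contrast
(roughly the union of five 5%-FDR lists), which the acceptance report shows
honestly as `deg_empirical_fdr`.

## Expression summaries and QC

FPKM is \(10^9 K_{gj} / (L_g N_j)\) with \(L_g\) the annotated exonic
length and \(N_j\) the library's total assigned fragments (column sums of
the count matrix, since mapping-level totals are not part of a count
matrix; the choice is recorded here rather than silently assumed).
Abundance bins are left-closed at 1/10/100 FPKM — below 1 is "not
expressed". Stage expression is the arithmetic mean of surviving
replicates. Correlation and PCA operate on \(\log_2(x+1)\)-transformed
values, a standard variance stabilization; Pearson is the default for
sample-similarity matrices and Spearman for the replicate QC rule, where a
replicate is flagged when its mean rank correlation with same-group
siblings drops below 0.95. This turns a visual PCA judgment into a
reproducible, configurable threshold; single-replicate groups are never
flagged (they carry no internal evidence), only warned about. The qPCR
utility implements \(2^{-\Delta\Delta Ct}\) with the calibrator mapping to
exactly 1.

## Trajectory clustering and the phase split

Per line, stage-mean profiles of the line-specific DEG union are z-scored
per gene (population-variance convention; constant rows are masked, not
NaN-propagated) and clustered with fuzzy c-means: fuzzifier \(m = 2\)
(the canonical default; the underlying theory only requires \(m > 1\)) and
\(c = 4\) clusters by default, matching the four archetypal trajectory
shapes of early ear development. Memberships start from a symmetric
Dirichlet draw; ten restarts are run and the lowest-objective solution
kept, so results are reproducible bit-for-bit given the seed. Iterations
stop when the largest membership change falls below 1e-6. A point
coinciding with a centroid receives membership 1 there (the update is
otherwise undefined).

The two-phase partition is made explicit rather than visual: for every
contiguous split of the ordered stages, the score is the mean pairwise
distance between phase members divided by the pooled mean within-phase
distance (splits with no within-phase pair fall back to the raw
between-phase mean; ties break toward the earlier split). The stage vectors
scored in the pipeline are the per-stage \(\log_2\)-mean profiles over the
DEG union, both lines stacked. No automatic selection of \(c\) is
attempted — the cluster count is configuration, not inference.

## Genetic-architecture integration

Coordinates are 1-based inclusive throughout (GFF3 convention); the BED
writer converts to 0-based half-open at the boundary. Overlap means sharing
at least one bp; pure abutment (end + 1 = start) does not merge. Hotspot
merging is single-linkage per chromosome, implemented on
GenomicRanges/IRanges; a merged cluster becomes a hotspot only with ≥ 2
member QTLs from ≥ 2 distinct studies (a toggle counts within-study repeats
instead, since repeated detection within one study is arguably weaker
evidence). QTN windows are clamped at chromosome ends, never wrapped, and
never merged with each other, so per-QTN evidence survives to the report.
The common-region predicate binds a QTN to the hotspot containing it: a
candidate is "common" when it overlaps a hotspot H and the window of a QTN
positioned inside H. This same-hotspot binding is the strictest consistent
reading of "within QTLs where QTNs also exist"; an any-hotspot mode is
available. Unstranded throughout.

## The synthetic-data generator

The generator exists so every downstream stage is testable without
downloads, with ground truth attached. It emulates the study design: 2
lines × 5 stages × 3 replicates (30 libraries), 20,000 genes by default on
ten chromosomes with B73 RefGen_v4 lengths, NB counts with lognormal
dispersions (meanlog log 0.1, sdlog 0.5 — field-typical, as the underlying
study reports no dispersion information), library sizes 15–25 million
fragments (NovaSeq scale), a DE fraction of 0.15 with |log2FC| drawn from
a normal(2, 0.5) truncated at 1, and four temporal archetypes whose regime
changes between stages 3 and 4 so the phase split is recoverable. Baseline
abundances are wide lognormal (sdlog 2.3), which reproduces replicate
Spearman correlations near 0.97 — the reproducibility level the QC rule
assumes; per-library transcript shares are capped at ~2% so library totals
concentrate, and target totals are drawn 4 predicted-SD inside the
configured range so realized totals respect it. Gene spans are placed
without overlap (lognormal lengths around 3 kb). Genetic maps plant
hotspots as `support` QTLs from distinct studies all covering the planted
region; background QTLs are rejection-placed to overlap nothing, so the
planted hotspots are exactly the recoverable ones and round-trip tests can
demand exact recovery. QTNs fall inside planted hotspots with configurable
probability, otherwise at least one flank-width away from them.

What the generator does **not** emulate: GC/length biases, batch effects,
isoform-level structure, linkage disequilibrium among QTNs, correlated
gene-gene expression, and outlier replicates unless planted. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every artifact of real libraries.

## Problem sizes used by the validation suite

The test suite and the acceptance script run entirely from simulation:
interval-engine equivalence against a brute-force per-bp oracle on 500
random instances (chromosomes ≤ 100 kb); hotspot/tier round trips over 20
seeds; a 2,000-gene null and 200-seed power study at n = 3 for the Wald
test; 20-seed property checks for clustering and the phase split; and a
5,000-gene end-to-end pipeline run for the headline report. These sizes
were chosen as the smallest at which the binomial/simulation error of each
check is comfortably below its assertion band.

## Known limitations

- The DE module is a two-group NB Wald test; multi-factor designs, Cook's
  outlier handling, shrunken LFCs and independent filtering are out of
  scope, so exact numeric agreement with DESeq2 is not expected (direction
  and large-effect calls agree in the cross-check test).
- The fuzzifier is fixed, not estimated; cluster count is configuration.
- FPKM totals are column sums, not mapped-read totals.
- Marker-to-genome anchoring of QTL/QTN coordinates must happen upstream;
  the integration assumes one shared genome build and errors on
  chromosome-name mismatches rather than guessing.
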