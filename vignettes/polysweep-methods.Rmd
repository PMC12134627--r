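---
title: "Methods: sweep scanning and time-course expression analysis in polysweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning and time-course expression analysis in polysweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

polysweep implements an integrated analysis of chicken polydactyly: a
population-genomic arm that scans resequencing genotypes for selective
sweeps distinguishing five-toed (PPP) and four-toed (PPNT) breeds from the
wild red junglefowl (RJF) background, and a transcriptomic arm that follows
embryonic foot tissue across days 6–9 in both phenotypes. This vignette
documents the models, the parameters that matter, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Variant filtering

Filtering is two-tier. Record-level INFO hard filters follow GATK
conventions: a site passes only if every *present* key satisfies
QD > 10, MQ > 40, FS < 60, MQRankSum > −12.5 and ReadPosRankSum > −8;
absent keys never fail a site. All pass conditions are strict
inequalities oriented exactly as stated, so QD = 10.0 fails.

Cohort-level filters then run in a fixed order: restriction to biallelic
SNPs (or biallelic InDels for the InDel track); removal of samples with
more than 10% missing calls, with missingness computed over sites that
survived the record-level filters so that hard-filter casualties do not
inflate it; site call rate ≥ 95%; minor allele frequency > 1%; and an
exact Hardy–Weinberg test at p ≥ 10⁻⁵. The HWE p-value is the two-sided
exact tail of the Levene–Haldane distribution of heterozygote counts
conditional on allele counts, computed with the standard recurrence in
log space; by default the test pools all retained samples, with a
per-population option (minimum p across populations) because pooling
across differentiated populations deliberately also catches Wahlund-type
departures. Finally, SNPs with inter-site distance ≤ 5 bp are thinned by
a greedy left-to-right scan that keeps the first site of each close pair
(distance measured to the last *kept* site) — deterministic, and the
common convention where only "excluded" is specified. Each removed site
is attributed to the first criterion that removed it, so the report's
removals always sum to input minus output.

A degenerate interaction is worth knowing: with very few sites, any
single missing call exceeds a 10% per-sample missingness budget, so tiny
worked examples must either tolerate sample removal or relax
`sample_call_rate_min`. The shipped 8-record demonstration uses
`filter_config(sample_call_rate_min = 0.5)` for exactly this reason.

## Windowed diversity and differentiation

Statistics are computed in 40-kb windows sliding in 10-kb steps; only
full-width windows are emitted. Per-site nucleotide diversity is the
mean pairwise difference `2c(n−c)/(n(n−1))` for `c` alternate alleles
among `n` called alleles; window θπ divides the per-site sum by the
fixed 40-kb width rather than by callable sites, matching common
windowed-π tools (a per-callable-site denominator would require
modelling the monomorphic mask, which genotype-only input cannot
supply).

Differentiation uses Hudson's estimator with ratio-of-sums aggregation:
per site `N = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)` and
`D = p₁(1−p₂) + p₂(1−p₁)`, with the window estimate `ΣN/ΣD`. The choice
is deliberate: it is fully specifiable from allele counts, nearly
unbiased for unequal sample sizes, and ratio-of-sums avoids the
instability of averaging per-site ratios at rare variants. Negative
values are retained. Windows with fewer than 10 informative sites are
flagged and excluded from quantile computations because their π ratios
are unstable; windows with ΣD = 0 are undefined.

The log₂ π ratio is oriented as `log2(π_reference / π_focal)`, so
positive values mean diversity *loss* in the focal population; both
orientations of a comparison are obtained by swapping the roles, under
which Fst is invariant and the ratio negates.

## Outlier calling, regions, and ranking

A window is a sweep candidate for the focal population iff its Fst and
its log₂ π ratio *both* reach the empirical 95% quantile (nearest-rank,
inclusive) of defined windows — the joint, directional rule. Ties at a
threshold are all included; in the degenerate constant-distribution case
every window trivially passes, which is documented behaviour rather than
an error. Quantile calling requires at least 100 defined windows.

Outlier windows that overlap or are book-ended within one step merge
into regions carrying the peak window statistics. Regions are then
*described*, not gated, by Mann–Whitney tests of their per-site Fst
values against the genome-wide per-site background and of their
per-window log₂ ratios against all windows. The test runs at per-site
granularity for Fst because a handful of windows per region cannot reach
extreme significance under any rank test; the region flag (default
10⁻¹⁶) is reporting only. The Mann–Whitney implementation is exact —
including under ties, via a subset-sum dynamic programme over doubled
midranks — whenever `n₁·n₂ ≤ 400`, and otherwise uses the
tie-corrected normal approximation with continuity correction.

Genes overlapping any region by ≥ 1 bp are ranked by the maximum peak
Fst over their regions; unnamed genes are reported as "NA".

## Variant-effect classification

The classifier places biallelic variants into the standard genic
taxonomy with precedence exonic/splicing > splicing > exonic > intronic
> upstream/downstream (of different genes) > upstream > downstream >
intergenic. Flank width is 1,000 bp and the splice window is the 2
intronic bases adjacent to each exon boundary — the usual annotation
defaults, both configurable, since the category names alone do not pin
distances. Exonic SNPs in a complete CDS are translated codon-wise,
strand- and phase-aware, into synonymous, nonsynonymous, stopgain or
stoploss under the standard genetic code; exons outside any CDS or with
incomplete CDS yield `exonic_unknown`. Coding InDels are split by length
change mod 3 into frameshift/nonframeshift insertion, deletion or block
substitution; for nonframeshift events the mutated CDS is re-translated
and a gained internal stop or a lost terminal stop overrides the call.
Frameshift events keep their frameshift label even when the shifted
frame encounters an early stop — the length-based label is the more
informative one and keeps the category partition unambiguous. Multiple
transcripts collapse to the most severe category.

## TPM, expressed genes, and differential expression

TPM divides each count by gene length and normalises each sample to
10⁶. A gene counts as expressed when ≥ 2 replicates *within a single*
(condition, timepoint) group reach 0.5 TPM; support split across groups
does not qualify, which keeps the filter aligned with the replicate
structure it is meant to exploit.

The DE stage is a deliberately transparent simplification of
shrinkage-based NB machinery: median-of-ratios size factors; a pooled
method-of-moments dispersion `α = max((s² − μ)/μ², 10⁻⁸)` from
within-group variances; `log2FC = log2((μ_B + 0.5)/(μ_A + 0.5))` with a
0.5 pseudocount guarding empty groups; a delta-method Wald standard
error `SE² = (1/ln2)²[(1/(n_A μ′_A) + α/n_A) + (1/(n_B μ′_B) + α/n_B)]`;
normal two-sided p-values and Benjamini–Hochberg adjustment over the
tested genes. A gene is a DEG iff padj < 0.01 and |log2FC| > 2. There
is no dispersion shrinkage, no Cox–Reid adjustment and no outlier
replacement; the simulation-based checks in the test suite (type-I
control on null data, ≥ 90% power on planted 8-fold genes at μ = 200,
α = 0.1, 6 vs 6) are what licence it at this design size. The BH
universe is the expressed gene set. Sample-level summaries use PCA of
gene-centred log₂(TPM+1) via SVD and Spearman correlation with
midranks; the log transform is a documented choice where only "based on
TPM values" is specifiable.

## Temporal clustering

Per condition, profiles are replicate means per timepoint; genes with
more than 25% missing timepoints are dropped, remaining gaps are filled
with the gene's row mean, constant genes are removed, and rows are
z-scored — so clustering sees shapes, not levels. The fuzzifier comes
from the published empirical rule
`m = 1 + (1418/N + 22.05)D⁻² + (12.33/N + 0.243)D^(−0.0406 ln N − 0.1134)`.
Fuzzy c-means minimises `J = Σᵢ Σₖ u_ik^m ‖xᵢ − v_k‖²` with the standard
alternating updates, Euclidean distance on the z-scored rows, c = 6
clusters, and membership initialisation drawn from an RNG seeded with a
single integer (default 150). Results are deterministic given (seed,
data, parameters) but are not expected to be bit-identical to other
implementations' runs, whose RNG streams differ. A point coinciding
with a centroid receives membership 1 there; the objective sequence is
non-increasing by construction and asserted in tests. Hardened
assignments require membership ≥ 0.5, leaving ambiguous genes
unassigned — the same convention used when interpreting cluster plots.
Clustering operates on z-scored TPM means (the clustering package
convention); a log option can be had by transforming upstream.

## Enrichment

Over-representation uses the upper-tail hypergeometric test per term
with BH adjustment across terms. Gene-set content is user input (GMT);
no annotation database ships with the package. The universe defaults to
the loaded gene models for sweep-derived lists and the expressed set for
expression-derived lists — any web tool's internal universe is
unknowable, so it is explicit here. All terms are reported with padj;
no significance cutoff is hard-coded.

## Synthetic data: what it does and does not emulate

`simulate_genotypes()` draws independent sites under the Balding–Nichols
model: ancestral frequency p ~ U(0.05, 0.95), population frequencies
Beta-distributed around p with background F = 0.05, three populations
sized 17/22/21 (RJF/PPNT/PPP), one 5-Mb chromosome at one SNP per
250 bp. Five non-overlapping 100-kb sweeps in the focal population
replace its frequencies with Beta(18, 2) draws (mean 0.9), which raises
differentiation and depresses focal diversity simultaneously — the joint
signature the scan targets. The model gives direct analytic control of
Fst (the genome-wide ratio-of-sums estimate equals the simulated F) at
the cost of all linkage structure: windows aggregate independent sites,
so the generator cannot probe haplotype-based statistics, and window
counts of truly swept windows are optimistic relative to hitchhiking in
real genomes. Passing the planted-recovery tests therefore shows the
scan machinery is correct, not that its power on real linked data equals
the simulated power.

`simulate_toy_genome()` plants four two-exon genes (both strands,
complete ORFs) in a 12-kb chromosome and a 17-variant panel covering
every major category, with truth recorded by construction.
`simulate_counts()` builds the 2 × 4 × 6 design with NB dispersion 0.1,
log-normal baselines (median 150) and library factors, six multiplicative
temporal templates (flat, rise, fall, peak-day-8, peak-day-9, dip) and a
planted 150-gene 8-fold day-9 effect in VE — mirroring the observed
day-9 divergence qualitatively. Flat-template genes z-score into
isotropic noise; they are mostly absorbed by one cluster or left
unassigned, which is why recovery is scored on hardened assignments.

## Problem sizes and reproducibility

The shipped workflows and the acceptance script use one 5-Mb chromosome
(20,000 sites, 60 samples, ~500 windows) and 5,000-gene count matrices —
sizes chosen so a full run completes in seconds on a laptop while every
statistic still operates far from small-sample edge cases. All
randomness flows from explicit seeds; the workflow drivers write TSVs
with fixed numeric formatting and record md5 checksums, and a rerun with
the same seed is byte-identical.

## Known limitations

No linkage, demography or recombination-map awareness in the simulator;
no haplotype statistics (iHS, XP-EHH); no VQSR or genotype-level
filtering; InDel left-normalisation is assumed done upstream; no
isoform-level expression or batch correction; no GO DAG propagation in
enrichment; and the DE stage intentionally trades shrinkage-based power
at low counts for transparency.
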