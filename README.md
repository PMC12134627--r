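# polysweep

Integrated population-genomic and transcriptomic analysis of polydactyly
in chicken, packaged as a tested, reusable R pipeline. The package is for
researchers who want to (a) scan multi-population genotype data for
selective sweeps with windowed nucleotide diversity and F_ST, and
(b) analyse a 2-condition × 4-timepoint embryonic RNA-seq design with
negative-binomial differential expression and fuzzy c-means temporal
clustering — with synthetic-data generators standing in for raw
sequencing data, so every stage is verifiable end to end on a laptop.

## What it computes

**Sweep arm.** After two-tier variant filtering (GATK-style INFO hard
filters; sample/site call rate, MAF > 1%, exact Hardy–Weinberg test at
p ≥ 10⁻⁵; 5-bp proximity thinning), the scan tiles the genome with 40-kb
windows sliding in 10-kb steps and computes, per window and population
pair:

- θπ per bp: Σ over sites of 2c(n−c)/(n(n−1)), divided by the window width;
- Hudson's F_ST as a ratio of sums, per site
  N = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1),
  D = p₁(1−p₂) + p₂(1−p₁), window F_ST = ΣN/ΣD;
- log₂(π_ref/π_focal), positive when the focal population lost diversity.

Windows in the top 5% of *both* F_ST and the π ratio (nearest-rank,
inclusive) are sweep candidates; adjacent candidates merge into regions,
which get Mann–Whitney background p-values (exact for small samples, tie
corrected) and gene-level ranking by peak F_ST. A simplified
ANNOVAR-style classifier places SNPs/InDels into the standard category
taxonomy (synonymous/nonsynonymous/stopgain/stoploss, frameshift and
nonframeshift InDels, splicing, upstream/downstream, intronic,
intergenic) against GTF gene models plus the genome FASTA.

**Expression arm.** TPM quantification, the expressed-gene filter
(TPM ≥ 0.5 in ≥ 2 replicates of one group), median-of-ratios size
factors, an NB Wald test (DEG: padj < 0.01 and |log₂FC| > 2), pairwise
DEG matrices over all (condition, timepoint) groups, sample PCA and
Spearman correlation, fuzzy c-means clustering of z-scored temporal
profiles (c = 6, empirical fuzzifier estimate, seeded initialisation),
and hypergeometric over-representation against user-supplied GMT gene
sets.

The generators (`simulate_genotypes`, `simulate_toy_genome`,
`simulate_counts`) produce Balding–Nichols genotypes with planted
sweeps, a toy genome with variants of known effect, and NB count
matrices with planted temporal templates and DE genes — each with a
truth table, so recovery is measurable.

## Worked example

The numbered scripts under `analysis/` run the two workflows on the
shipped synthetic configurations (`Rscript analysis/01_simulate_data.R`
through `07_enrichment.R`, in order; outputs land in `results/`).
Highlights of an actual run:

```
$ Rscript analysis/02_filter_variants.R
input 20000 sites -> kept 19333 (96.7%)
            criterion removed
1    info_hard_filter       0
2 not_biallelic_track       0
3      site_call_rate       0
4                 maf      80
5                 hwe     210
6            thinning     377
```

80 sites fail the 1% MAF floor, 210 the exact HWE test (pooling across
differentiated populations also catches Wahlund-type departures), 377
fall to 5-bp thinning.

```
$ Rscript analysis/03_sweep_scan.R
19 outlier windows past Fst >= 0.3952 and log2 ratio >= 1.014
planted sweeps recovered: 5/5; false regions: 0
```

The joint top-5% rule finds 19 candidate windows which merge into five
regions — exactly the five planted 100-kb sweeps, no false positives.

```
$ Rscript analysis/05_expression_de.R
same-day FE-vs-VE DEG counts:
   group_A group_B n_deg n_up n_down
4      FE6     VE6     0    0      0
11     FE7     VE7     0    0      0
17     FE8     VE8     0    0      0
22     FE9     VE9   150  150      0
planted DE genes recovered in FE9-vs-VE9: 150/150

$ Rscript analysis/06_temporal_clustering.R
FE: 5000 genes, m = 2.526, 29 iterations, 4805 assigned, ARI vs truth 0.999
VE: 5000 genes, m = 2.526, 28 iterations, 4800 assigned, ARI vs truth 0.959
```

The day-9 condition contrast carries all 150 planted DEGs (all
upregulated in VE, as planted) while earlier days stay clean, and the
six planted temporal templates are recovered with adjusted Rand index
≈ 0.96–1.0.

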