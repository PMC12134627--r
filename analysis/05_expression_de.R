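#!/usr/bin/env Rscript
# Transcriptome overview and differential expression: TPM, the
# expressed-gene filter, sample PCA and Spearman correlation, and the
# pairwise DEG matrix over the eight (condition, timepoint) groups with
# the padj < 0.01, |log2FC| > 2 decision rule.

library(polysweep)

cm <- read_counts("results/sim/counts.tsv", meta = "results/sim/samples.tsv")
truth <- read.table("results/sim/truth.tsv", header = TRUE, sep = "\t")

tpm_mat <- tpm(cm$counts, cm$lengths)
keep <- expressed_filter(tpm_mat, cm$meta)
message(sum(keep), " of ", length(keep),
        " genes expressed (TPM >= 0.5 in >= 2 replicates of one group)")

pca <- sample_pca(tpm_mat[keep, , drop = FALSE])
write_tsv(data.frame(sample = rownames(pca$scores), pca$scores,
                     var_explained_pc1 = pca$var_explained[1L]),
          "results/pca_scores.tsv")
sp <- sample_spearman(tpm_mat[keep, , drop = FALSE])
write_tsv(data.frame(sample = rownames(sp), sp, check.names = FALSE),
          "results/spearman.tsv")

deg <- pairwise_deg_matrix(cm, genes = which(keep))
write_tsv(deg$pairs, "results/deg_pairs.tsv")
write_tsv(data.frame(group = rownames(deg$matrix), deg$matrix,
                     check.names = FALSE), "results/deg_matrix.tsv")

same_day <- deg$pairs[substr(deg$pairs$group_A, 3, 3) ==
                        substr(deg$pairs$group_B, 3, 3) &
                        substr(deg$pairs$group_A, 1, 2) !=
                        substr(deg$pairs$group_B, 1, 2), ]
message("same-day FE-vs-VE DEG counts:")
print(same_day)
message("the day-9 contrast carries the planted condition divergence")

# recall of the planted day-9 DE genes in the FE9 vs VE9 test
t9 <- deg$tests[[grep("(FE9_vs_VE9|VE9_vs_FE9)", names(deg$tests))[1L]]]
de_true <- truth$gene[truth$is_de]
hits <- sum(rownames(t9)[t9$is_deg] %in% de_true)
message(sprintf("planted DE genes recovered in FE9-vs-VE9: %d/%d",
                hits, length(de_true)))
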