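#!/usr/bin/env Rscript
# Classify the toy-genome variant panel against its gene models and
# genome sequence, check the planted truth, and emit the category
# summary (counts and percentages per SNP/InDel class).

library(polysweep)

models <- read_gtf("results/sim/toy.gtf")
genome <- Biostrings::readDNAStringSet("results/sim/toy.fa")
names(genome) <- sub(" .*", "", names(genome))
variants <- read_vcf("results/sim/toy_variants.vcf")
truth <- read.table("results/sim/variant_truth.tsv", header = TRUE,
                    sep = "\t")

ann <- classify_variants(variants, models, genome)
write_tsv(ann, "results/variant_annotation.tsv")
agree <- mean(ann$category == truth$category)
message(sprintf("planted-category agreement: %.0f%%", 100 * agree))

summ <- summarize_annotations(ann)
write_tsv(summ, "results/annotation_summary.tsv")
print(summ)
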