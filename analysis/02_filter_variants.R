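#!/usr/bin/env Rscript
# Two-tier variant filtering of the simulated cohort: INFO hard filters,
# biallelic-SNP restriction, sample/site call-rate, MAF and exact-HWE
# filters, then 5-bp proximity thinning.

library(polysweep)

gs <- read_vcf("results/sim/sim.vcf")
popmap <- read_population_map("results/sim/popmap.tsv")

res <- cohort_filter(gs, filter_config(), track = "snp", popmap = popmap)
write_tsv(res$report, "results/filter_report.tsv")
write_vcf(res$gs, "results/kept.vcf")

message(sprintf("input %d sites -> kept %d (%.1f%%)",
                res$n_input, res$n_kept, 100 * res$n_kept / res$n_input))
print(res$report)
if (length(res$removed_samples))
  message("samples removed: ", paste(res$removed_samples, collapse = ", "))
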