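#!/usr/bin/env Rscript
# Generate the synthetic study inputs: Balding-Nichols genotypes for the
# three chicken populations (wild RJF reference, four-toed PPNT,
# five-toed PPP) with five planted 100-kb sweeps in PPP; a toy genome
# with planted variant effects; and the NB embryonic time-course count
# matrix (FE/VE x day 6-9 x 6 replicates) with planted temporal
# templates and a day-9 condition effect.

library(polysweep)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating genotypes (3 populations, 5 Mb, 5 planted sweeps) ...")
gsim <- simulate_genotypes(genotype_sim_config(), seed = 1L)
paths_g <- write_genotype_sim(gsim, out)
message("  ", n_sites(gsim$gs), " sites x ", length(gsim$gs$samples),
        " samples -> ", paths_g[["vcf"]])

message("Simulating toy genome with planted variant effects ...")
toy <- simulate_toy_genome(out, seed = 42L)
write_tsv(toy$truth, file.path(out, "variant_truth.tsv"))
v <- file.path(out, "toy_variants.vcf")
write_vcf(toy$variants, v)
message("  ", nrow(toy$truth), " planted variants -> ", v)

message("Simulating NB time-course counts (2 x 4 x 6 design) ...")
csim <- simulate_counts(counts_sim_config(), seed = 1L)
paths_c <- write_counts_sim(csim, out)
message("  ", nrow(csim$cm$counts), " genes x ", ncol(csim$cm$counts),
        " samples -> ", paths_c[["counts"]])
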