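test_that("Balding-Nichols output matches its own F parameter", {
  cfg <- genotype_sim_config(
    pops = c(P1 = 20L, P2 = 20L), f_bg = 0.10,
    sweeps = data.frame(start = integer(0), end = integer(0),
                        focal = character(0)))
  sim <- simulate_genotypes(cfg, seed = 5)
  expect_identical(n_sites(sim$gs), 20000L)
  cnt1 <- polysweep:::.pop_counts(sim$gs, sim$popmap, "P1")
  cnt2 <- polysweep:::.pop_counts(sim$gs, sim$popmap, "P2")
  fst <- hudson_fst(cnt1$ac / cnt1$an, cnt1$an,
                    cnt2$ac / cnt2$an, cnt2$an)$fst
  expect_gte(fst, 0.08)
  expect_lte(fst, 0.13)
})

test_that("sweep sites carry near-fixed focal frequencies", {
  sim <- simulate_genotypes(genotype_sim_config(), seed = 5)
  sw <- sim$truth$in_sweep
  expect_gt(sum(sw), 1000L)   # ~ 500 kb of 5 Mb at 1/250 bp
  mean_focal <- mean(sim$truth$freq[sw, "PPP"])
  expect_equal(mean_focal, 18 / 20, tolerance = 0.02)
  # non-focal populations are unaffected at the same sites
  expect_lt(abs(mean(sim$truth$freq[sw, "RJF"]) - 0.5), 0.05)
})

test_that("generator output parses through the readers without warnings", {
  d <- withr::local_tempdir()
  cfg <- genotype_sim_config(chrom_len = 2e5, site_density = 1 / 500,
                             sweeps = data.frame(start = 1L, end = 2L,
                                                 focal = "PPP"))
  sim <- simulate_genotypes(cfg, seed = 2)
  paths <- write_genotype_sim(sim, d)
  expect_no_warning(gs <- read_vcf(paths["vcf"]))
  expect_identical(n_sites(gs), n_sites(sim$gs))
  pm <- read_population_map(paths["popmap"])
  expect_identical(pm, sim$popmap)
})

test_that("planted toy-genome variants classify to their recorded truth", {
  d <- withr::local_tempdir()
  toy <- simulate_toy_genome(d, seed = 42)
  models <- read_gtf(toy$gtf)
  genome <- Biostrings::readDNAStringSet(toy$fasta)
  names(genome) <- sub(" .*", "", names(genome))
  ann <- classify_variants(toy$variants, models, genome)
  expect_identical(ann$category, toy$truth$category)
  expect_identical(ann$class, toy$truth$class)
  # the truth panel covers both strands and all major category groups
  expect_true(all(c("exonic_synonymous", "exonic_nonsynonymous",
                    "exonic_stopgain", "exonic_stoploss",
                    "frameshift_deletion", "nonframeshift_deletion",
                    "frameshift_insertion", "nonframeshift_insertion",
                    "splicing", "intronic", "intergenic", "upstream",
                    "downstream", "upstream/downstream") %in%
                    toy$truth$category))
})

test_that("count simulation honours design, templates and planted DE", {
  sim <- simulate_counts(counts_sim_config(n_genes = 900L, n_de = 90L),
                         seed = 13)
  cm <- sim$cm
  expect_identical(dim(cm$counts), c(900L, 48L))
  expect_identical(sort(unique(cm$meta$timepoint)), 6:9)
  expect_identical(sort(unique(cm$meta$condition)), c("FE", "VE"))
  # planted genes respond only in the (VE, day 9) cell
  de <- sim$truth$gene[sim$truth$is_de]
  grp <- paste0(cm$meta$condition, cm$meta$timepoint)
  m_ve9 <- rowMeans(cm$counts[de, grp == "VE9", drop = FALSE])
  m_fe9 <- rowMeans(cm$counts[de, grp == "FE9", drop = FALSE])
  expect_gt(median(m_ve9 / pmax(m_fe9, 1)), 4)
  m_ve8 <- rowMeans(cm$counts[de, grp == "VE8", drop = FALSE])
  m_fe8 <- rowMeans(cm$counts[de, grp == "FE8", drop = FALSE])
  expect_lt(median(m_ve8 / pmax(m_fe8, 1)), 2)
})

test_that("planted temporal templates are recovered by the clustering stage", {
  sim <- simulate_counts(counts_sim_config(), seed = 11)
  cm <- sim$cm
  tp <- tpm(cm$counts, cm$lengths)
  keep <- expressed_filter(tp, cm$meta)
  prof <- prepare_profiles(tp[keep, , drop = FALSE], cm$meta, "FE")
  fc <- fuzzy_cmeans(prof, c = 6, seed = 150)
  rep_ <- cluster_report(fc)
  truth <- sim$truth$template[match(rownames(prof), sim$truth$gene)]
  ari <- adjusted_rand_index(rep_$assignment, truth)
  expect_gte(ari, 0.8)
})
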