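# helper: genotype set from a dosage matrix on one chromosome
gs_from_dosage <- function(dos, pos, pops) {
  n <- nrow(dos); k <- ncol(dos)
  a1 <- ifelse(dos >= 1L, 1L, 0L); a1[is.na(dos)] <- NA_integer_
  a2 <- ifelse(dos == 2L, 1L, 0L); a2[is.na(dos)] <- NA_integer_
  samples <- sprintf("s%03d", seq_len(k))
  list(gs = genotype_set(rep("chr1", n), pos, rep("A", n), rep("C", n),
                         a1, a2, samples),
       popmap = setNames(pops, samples))
}

test_that("window tiling emits only full-width windows on the step grid", {
  w <- make_windows(c(chr1 = 100000L))
  expect_identical(nrow(w), 7L)
  expect_identical(w$start, 1L + 10000L * 0:6)
  expect_identical(unique(w$end - w$start + 1L), 40000L)
  expect_identical(nrow(make_windows(c(c1 = 40000L))), 1L)
  expect_identical(nrow(make_windows(c(c1 = 39999L))), 0L)
  expect_error(make_windows(c(c1 = 1e5), width = 0), "width")
})

test_that("site_pi is the mean pairwise difference at a site", {
  expect_equal(site_pi(2, 4), 2 / 3, tolerance = 1e-12)
  expect_identical(site_pi(0, 10), 0)
  expect_identical(site_pi(10, 10), 0)
  expect_identical(site_pi(1, 1), 0)   # n < 2 is uninformative
})

test_that("windowed theta-pi equals the all-pairs oracle on 10 diploids x 200 sites", {
  set.seed(31)
  n_sites <- 200L
  dos <- matrix(rbinom(n_sites * 10L, 2L, runif(n_sites * 10L, 0.05, 0.95)),
                n_sites, 10L)
  dos[sample(length(dos), 40L)] <- NA   # unphased, missing-tolerant
  ac <- rowSums(dos, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(dos))
  width <- 40000L
  impl <- window_pi(site_pi(ac, an), width)
  oracle <- oracle_window_pi(ac, an, width)
  expect_equal(impl, oracle, tolerance = 1e-12)
})

test_that("Hudson Fst handles fixed differences, negatives, and label swaps", {
  # fixed difference -> 1 regardless of sample sizes
  for (n in c(4, 10, 100)) {
    h <- hudson_fst(1, n, 0, 2 * n)
    expect_equal(h$fst, 1, tolerance = 1e-12)
  }
  # plug-in arithmetic at p1 = p2 = 0.5, n = 10: negative value retained
  h <- hudson_fst(0.5, 10, 0.5, 10)
  expect_equal(h$fst, (0 - 0.25 / 9 - 0.25 / 9) / 0.5, tolerance = 1e-12)
  expect_equal(h$fst, -1 / 9, tolerance = 1e-12)
  # label swap leaves window Fst unchanged
  set.seed(8)
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(hudson_fst(p1, 20, p2, 30)$fst,
               hudson_fst(p2, 30, p1, 20)$fst, tolerance = 1e-12)
})

test_that("the scan's log2 ratio negates under population swap", {
  set.seed(9)
  toy <- gs_from_dosage(
    matrix(rbinom(4000L * 12L, 2L, 0.4), 4000L, 12L),
    sort(sample.int(2e5, 4000L)),
    rep(c("A", "B"), each = 6L))
  sa <- window_scan(toy$gs, toy$popmap, "A", "B",
                    chrom_lengths = c(chr1 = 2e5),
                    width = 40000L, step = 10000L)
  sb <- window_scan(toy$gs, toy$popmap, "B", "A",
                    chrom_lengths = c(chr1 = 2e5),
                    width = 40000L, step = 10000L)
  expect_equal(sa$windows$fst, sb$windows$fst, tolerance = 1e-12)
  expect_equal(sa$windows$log2_ratio, -sb$windows$log2_ratio,
               tolerance = 1e-12)
})

test_that("joint outliers respect the nearest-rank quantile and tie inclusion", {
  sim <- simulate_genotypes(genotype_sim_config(), seed = 7)
  scan <- window_scan(sim$gs, sim$popmap, "PPP", "RJF",
                      chrom_lengths = c(chr1 = 5e6))
  out <- joint_outlier_windows(scan, q = 0.95)
  n_def <- sum(scan$windows$defined & scan$windows$sufficient)
  expect_lte(nrow(out), ceiling(0.05 * n_def) + 5L)  # + possible ties
  expect_true(all(out$fst >= attr(out, "fst_threshold")))
  expect_true(all(out$log2_ratio >= attr(out, "ratio_threshold")))
  # q = 1 keeps only the argmax window(s) on each axis jointly
  out1 <- joint_outlier_windows(scan, q = 1.0)
  expect_lte(nrow(out1), 1L)
  # too few windows for stable quantiles
  small <- scan
  small$windows <- scan$windows[1:50, ]
  expect_error(joint_outlier_windows(small), "100")
})

test_that("region merging unions overlapping and book-ended windows", {
  w <- data.frame(chrom = "chr1",
                  start = c(1L, 10001L), end = c(40000L, 50000L),
                  fst = c(0.5, 0.6), log2_ratio = c(1, 2))
  r <- merge_regions(w, step = 10000L)
  expect_identical(nrow(r), 1L)
  expect_identical(c(r$start, r$end), c(1L, 50000L))
  expect_identical(r$n_windows, 2L)
  expect_equal(r$peak_fst, 0.6)

  w2 <- data.frame(chrom = "chr1",
                   start = c(1L, 100001L), end = c(40000L, 140000L),
                   fst = c(0.5, 0.6), log2_ratio = c(1, 2))
  expect_identical(nrow(merge_regions(w2, step = 10000L)), 2L)

  run <- data.frame(chrom = "chr1", start = 1L + 10000L * 0:4,
                    end = 40000L + 10000L * 0:4,
                    fst = seq(0.5, 0.7, length.out = 5),
                    log2_ratio = 1:5)
  r3 <- merge_regions(run, step = 10000L)
  expect_identical(r3$n_windows, 5L)
  expect_equal(r3$peak_fst, 0.7)
})

test_that("Mann-Whitney U matches exact enumeration, with and without ties", {
  res <- mannwhitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-10)
  # identical multisets: U = n1 n2 / 2, p ~ 1
  res2 <- mannwhitney_u(c(5, 6, 7), c(5, 6, 7))
  expect_equal(res2$U, 4.5)
  expect_gte(res2$p, 0.9)
  set.seed(12)
  for (rep in 1:5) {
    x <- sample(1:4, 6, replace = TRUE)   # tie-heavy: DP-exact route
    y <- sample(2:5, 7, replace = TRUE)
    expect_equal(mannwhitney_u(x, y)$p, oracle_mw_p(x, y),
                 tolerance = 1e-10)
  }
  for (rep in 1:5) {                      # tie-free: same exact route
    x <- runif(6); y <- runif(7)
    expect_equal(mannwhitney_u(x, y)$p, oracle_mw_p(x, y),
                 tolerance = 1e-10)
  }
  expect_error(mannwhitney_u(numeric(0), 1), "empty")
})

test_that("planted sweeps are recovered and flagged; null regions are not", {
  sim <- simulate_genotypes(genotype_sim_config(), seed = 7)
  filt <- cohort_filter(sim$gs, filter_config(), track = "snp")
  scan <- window_scan(filt$gs, sim$popmap, "PPP", "RJF",
                      chrom_lengths = c(chr1 = 5e6))
  out <- joint_outlier_windows(scan)
  reg <- merge_regions(out)
  reg <- region_significance(reg, scan)
  rec <- sweep_recovery(reg, sim$truth$sweeps)
  expect_gte(rec$n_true, 4L)
  expect_lte(rec$n_false, 2L)
  # planted regions stand far off the per-site background
  expect_true(all(reg$mw_p_fst[reg$n_informative >= 3L] < 1e-6))

  # a region drawn from the background is not extreme
  bg <- data.frame(chrom = "chr1", start = 2000001L, end = 2100000L,
                   n_windows = 7L, peak_fst = 0.1, peak_log2_ratio = 0.1)
  null_cfg <- genotype_sim_config(
    sweeps = data.frame(start = integer(0), end = integer(0),
                        focal = character(0)))
  nsim <- simulate_genotypes(null_cfg, seed = 19)
  nscan <- window_scan(nsim$gs, nsim$popmap, "PPP", "RJF",
                       chrom_lengths = c(chr1 = 5e6))
  nreg <- region_significance(bg, nscan)
  expect_gt(nreg$mw_p_fst, 0.001)
  expect_false(nreg$significant)
})

test_that("gene ranking takes the max peak Fst over overlapping regions", {
  d <- withr::local_tempdir()
  toy <- simulate_toy_genome(d, seed = 3)
  models <- read_gtf(toy$gtf)
  regions <- data.frame(chrom = "toy1",
                        start = c(2900L, 3200L, 6900L),
                        end = c(3100L, 3300L, 7400L),
                        peak_fst = c(0.6, 0.72, 0.5))
  tab <- rank_genes(regions, models)
  expect_identical(tab$gene_id[1L], "G1")   # overlaps two regions: max 0.72
  expect_equal(tab$gene_fst[1L], 0.72)
  expect_identical(tab$gene_id[2L], "G2")
  expect_equal(tab$gene_fst[2L], 0.5)
  expect_false("G3" %in% tab$gene_id)
  expect_error(rank_genes(regions, list()), "gene models")
})
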