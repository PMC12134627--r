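# End-to-end workflow drivers used by the numbered analysis scripts.
# Every output is a TSV written with fixed numeric formatting, so a rerun
# with the same seed is byte-identical.

#' Run the selective-sweep workflow on synthetic genotypes
#'
#' Simulates Balding-Nichols genotypes with planted sweeps, filters them,
#' scans windows for the focal/reference pair, calls joint top-quantile
#' outliers, merges regions, attaches Mann-Whitney background p-values,
#' and writes windows / regions / BED tables plus a manifest of output
#' checksums.
#'
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed driving the simulation.
#' @param config a [genotype_sim_config()].
#' @param focal,reference populations compared (defaults PPP vs RJF).
#' @param q outlier quantile.
#' @param width,step window geometry.
#' @return list with the computed objects (`scan`, `outliers`,
#'   `regions`) and `manifest` (file -> md5).
#' @export
run_sweep_workflow <- function(out_dir, seed = 1L,
                               config = genotype_sim_config(),
                               focal = "PPP", reference = "RJF",
                               q = 0.95, width = 40000L, step = 10000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(config, seed = seed)
  filt <- cohort_filter(sim$gs, filter_config(), track = "snp")
  scan <- window_scan(filt$gs, sim$popmap, focal, reference,
                      chrom_lengths = setNames(config$chrom_len,
                                               config$chrom),
                      width = width, step = step)
  outliers <- joint_outlier_windows(scan, q = q)
  regions <- merge_regions(outliers, step = step)
  regions <- region_significance(regions, scan)
  write_tsv(scan$windows, file.path(out_dir, "windows.tsv"))
  write_tsv(regions, file.path(out_dir, "regions.tsv"))
  write_bed(regions, file.path(out_dir, "regions.bed"))
  write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))
  files <- file.path(out_dir, c("windows.tsv", "regions.tsv",
                                "regions.bed", "filter_report.tsv"))
  list(sim = sim, filtered = filt, scan = scan, outliers = outliers,
       regions = regions,
       manifest = tools::md5sum(files))
}

#' Run the transcriptome workflow on synthetic counts
#'
#' Simulates the NB time-course, computes TPM, applies the
#' expressed-gene filter, builds the pairwise DEG matrix, the sample PCA
#' and Spearman correlation, clusters each condition's temporal profiles
#' with fuzzy c-means, and writes the result tables.
#'
#' @param out_dir output directory.
#' @param seed RNG seed driving the simulation.
#' @param config a [counts_sim_config()].
#' @param c,cluster_seed fuzzy c-means cluster count and seed.
#' @return list with `sim`, `tpm`, `expressed`, `deg`, `pca`,
#'   `spearman`, `clustering` (per condition), `manifest`.
#' @export
run_expression_workflow <- function(out_dir, seed = 1L,
                                    config = counts_sim_config(),
                                    c = 6L, cluster_seed = 150L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(config, seed = seed)
  cm <- sim$cm
  tpm_mat <- tpm(cm$counts, cm$lengths)
  expressed <- expressed_filter(tpm_mat, cm$meta)
  deg <- pairwise_deg_matrix(cm, genes = which(expressed))
  pca <- sample_pca(tpm_mat[expressed, , drop = FALSE])
  sp <- sample_spearman(tpm_mat[expressed, , drop = FALSE])
  clustering <- lapply(setNames(nm = unique(cm$meta$condition)),
                       function(cond) {
    prof <- prepare_profiles(tpm_mat[expressed, , drop = FALSE],
                             cm$meta, cond)
    fc <- fuzzy_cmeans(prof, c = c, seed = cluster_seed)
    list(profiles = prof, fit = fc, report = cluster_report(fc))
  })
  write_tsv(deg$pairs, file.path(out_dir, "deg_pairs.tsv"))
  write_tsv(data.frame(group = rownames(deg$matrix), deg$matrix,
                       check.names = FALSE),
            file.path(out_dir, "deg_matrix.tsv"))
  write_tsv(data.frame(sample = rownames(pca$scores), pca$scores,
                       check.names = FALSE),
            file.path(out_dir, "pca_scores.tsv"))
  for (cond in names(clustering)) {
    cent <- clustering[[cond]]$fit$centroids
    write_tsv(data.frame(cluster = seq_len(nrow(cent)), cent,
                         check.names = FALSE),
              file.path(out_dir, sprintf("centroids_%s.tsv", cond)))
  }
  files <- file.path(out_dir,
                     c("deg_pairs.tsv", "deg_matrix.tsv", "pca_scores.tsv",
                       sprintf("centroids_%s.tsv", names(clustering))))
  list(sim = sim, tpm = tpm_mat, expressed = expressed, deg = deg,
       pca = pca, spearman = sp, clustering = clustering,
       manifest = tools::md5sum(files))
}

#' Recall and false-discovery summary for planted sweeps
#'
#' A planted sweep counts as recovered when at least one merged region
#' overlaps it by 1 bp or more; a merged region counts as false when it
#' overlaps no planted sweep.
#'
#' @param regions merged regions data frame.
#' @param sweeps planted truth (`start`, `end`; single chromosome).
#' @return list with `n_true` recovered, `n_planted`, `n_false`.
#' @export
sweep_recovery <- function(regions, sweeps) {
  if (!nrow(regions))
    return(list(n_true = 0L, n_planted = nrow(sweeps),
                n_false = 0L))
  hit <- vapply(seq_len(nrow(sweeps)), function(i)
    any(regions$start <= sweeps$end[i] & regions$end >= sweeps$start[i]),
    TRUE)
  false <- vapply(seq_len(nrow(regions)), function(j)
    !any(sweeps$start <= regions$end[j] & sweeps$end >= regions$start[j]),
    TRUE)
  list(n_true = sum(hit), n_planted = nrow(sweeps),
       n_false = sum(false))
}
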