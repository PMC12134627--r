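# Two-tier variant filtering: GATK-style INFO hard filters on single
# records, then cohort-level sample/site filters and proximity thinning.

#' Filtering configuration
#'
#' Defaults follow the hard-filter thresholds and cohort criteria used in
#' resequencing practice: pass requires quality-by-depth > 10, mapping
#' quality > 40, FS < 60, MQRankSum > -12.5, ReadPosRankSum > -8;
#' cohort filters keep samples with call rate > 90%, sites with call rate
#' > 95%, minor allele frequency > 1% and Hardy-Weinberg exact p >= 1e-5;
#' SNPs closer than or equal to `thin_bp` (5 bp) to the previously kept
#' SNP are thinned out.
#'
#' @param qd_min,mq_min minimum QD / MQ (pass requires strictly greater).
#' @param fs_max maximum FS (pass requires strictly smaller).
#' @param mqranksum_min,readposranksum_min minimum rank-sum statistics
#'   (pass requires strictly greater).
#' @param sample_call_rate_min,site_call_rate_min call-rate thresholds in
#'   `[0,1]`.
#' @param maf_min minor-allele-frequency threshold (sites with MAF <=
#'   `maf_min` are dropped).
#' @param hwe_p_min sites with Hardy-Weinberg exact p below this are
#'   dropped.
#' @param thin_bp inter-site distance at or below which the later site is
#'   dropped.
#' @return a `filter_config` list.
#' @export
filter_config <- function(qd_min = 10, mq_min = 40, fs_max = 60,
                          mqranksum_min = -12.5, readposranksum_min = -8,
                          sample_call_rate_min = 0.90,
                          site_call_rate_min = 0.95,
                          maf_min = 0.01, hwe_p_min = 1e-5, thin_bp = 5L) {
  stopifnot(sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            site_call_rate_min >= 0, site_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1, thin_bp >= 0)
  structure(list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
                 mqranksum_min = mqranksum_min,
                 readposranksum_min = readposranksum_min,
                 sample_call_rate_min = sample_call_rate_min,
                 site_call_rate_min = site_call_rate_min,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 thin_bp = as.integer(thin_bp)),
            class = "filter_config")
}

#' INFO hard filter
#'
#' A site fails iff any PRESENT key violates its threshold; absent keys
#' never fail (GATK convention). Pass conditions are strict: QD > qd_min,
#' MQ > mq_min, FS < fs_max, MQRankSum > mqranksum_min, ReadPosRankSum >
#' readposranksum_min.
#'
#' @param info data frame of INFO values (columns QD, MQ, FS, MQRankSum,
#'   ReadPosRankSum; `NA` = absent), one row per site.
#' @param config a [filter_config()].
#' @return list with `pass` (logical per site) and `failing_keys`
#'   (character vector per site).
#' @export
info_hard_filter <- function(info, config = filter_config()) {
  fails <- cbind(
    QD = !is.na(info$QD) & info$QD <= config$qd_min,
    MQ = !is.na(info$MQ) & info$MQ <= config$mq_min,
    FS = !is.na(info$FS) & info$FS >= config$fs_max,
    MQRankSum = !is.na(info$MQRankSum) & info$MQRankSum <= config$mqranksum_min,
    ReadPosRankSum = !is.na(info$ReadPosRankSum) &
      info$ReadPosRankSum <= config$readposranksum_min)
  list(pass = rowSums(fails) == 0L,
       failing_keys = apply(fails, 1L, function(f) colnames(fails)[f],
                            simplify = FALSE))
}

#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test conditional on allele counts: heterozygote counts
#' `h` with the same parity as the observed count and consistent allele
#' totals follow the Levene/Haldane distribution; the p-value is the sum
#' of `Pr(h)` over all `h` with `Pr(h) <= Pr(observed)`. Computed with the
#' standard recurrence in log space for stability.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers,
#'   `n_AA + n_Aa + n_aa >= 1`).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("empty genotype table")
  nA <- 2L * n_AA + n_Aa
  na_ <- 2L * n_aa + n_Aa
  rare <- min(nA, na_)
  if (rare == 0L) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # recurrence: P(h+2)/P(h) = 4*nAA(h)*naa(h) / ((h+2)*(h+1)),
  # with nAA(h) = (nA - h)/2, naa(h) = (na - h)/2; work in logs
  logp <- numeric(length(hs))
  for (i in seq_along(hs)[-1L]) {
    h <- hs[i - 1L]
    logp[i] <- logp[i - 1L] +
      log(4 * ((nA - h) / 2) * ((na_ - h) / 2)) -
      log((h + 2) * (h + 1))
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- match(n_Aa, hs)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Greedy proximity thinning
#'
#' Left-to-right scan per chromosome: a site is kept iff its distance to
#' the last KEPT site exceeds `thin_bp`; the first site is always kept.
#'
#' @param positions sorted ascending integer positions (one chromosome).
#' @param thin_bp drop a site when `pos - last_kept <= thin_bp`.
#' @return logical keep vector aligned with `positions`.
#' @export
thin_by_distance <- function(positions, thin_bp = 5L) {
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  n <- length(positions)
  keep <- logical(n)
  if (n == 0L) return(keep)
  last <- -Inf
  for (i in seq_len(n)) {
    if (positions[i] - last > thin_bp) {
      keep[i] <- TRUE
      last <- positions[i]
    }
  }
  keep
}

#' Cohort-level variant filtering
#'
#' Applies, in order: (1) the INFO hard filter; (2) restriction to
#' biallelic SNPs (`track = "snp"`) or biallelic InDels
#' (`track = "indel"`); (3) removal of samples whose missingness over the
#' surviving sites exceeds `1 - sample_call_rate_min`; (4) site filters
#' over the kept samples — call rate, MAF, Hardy-Weinberg exact test;
#' (5) proximity thinning. Each dropped site is attributed to the first
#' criterion that removes it, so the report's removals sum exactly to
#' input minus output.
#'
#' @param gs a [genotype_set()] sorted by (chrom, pos).
#' @param config a [filter_config()].
#' @param track `"snp"` or `"indel"`.
#' @param popmap optional named vector (sample -> population); when given
#'   and `hwe_per_pop = TRUE`, the HWE p-value per site is the minimum
#'   over populations instead of the pooled test.
#' @param hwe_per_pop logical; default pooled across all kept samples.
#' @return list with `gs` (filtered genotype set), `report` (per-criterion
#'   removal counts), `removed_samples`.
#' @export
cohort_filter <- function(gs, config = filter_config(), track = "snp",
                          popmap = NULL, hwe_per_pop = FALSE) {
  track <- match.arg(track, c("snp", "indel"))
  o <- order(match(gs$chrom, unique(gs$chrom)), gs$pos)
  if (!identical(o, seq_along(o))) stop("input must be sorted by (chrom, pos)")
  n0 <- n_sites(gs)
  status <- rep(NA_character_, n0)   # first criterion that removed a site

  hard <- info_hard_filter(gs$info, config)
  status[!hard$pass] <- "info_hard_filter"

  type_ok <- if (track == "snp") is_snp(gs) else is_indel(gs)
  bi <- is_biallelic(gs) & type_ok
  status[is.na(status) & !bi] <- "not_biallelic_track"

  surviving <- which(is.na(status))
  if (!length(surviving)) stop("no sites survive the record-level filters")
  dos <- gs_dosage(gs)[surviving, , drop = FALSE]

  miss <- colMeans(is.na(dos))
  drop_samp <- miss > 1 - config$sample_call_rate_min
  removed_samples <- gs$samples[drop_samp]
  if (all(drop_samp)) stop("all samples fail the sample call-rate filter")
  dos <- dos[, !drop_samp, drop = FALSE]
  keep_samples <- gs$samples[!drop_samp]

  call_rate <- rowMeans(!is.na(dos))
  nn <- rowSums(!is.na(dos))          # called genotypes
  ac <- rowSums(dos, na.rm = TRUE)    # alt allele count
  an <- 2L * nn
  af <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(af, 1 - af)

  low_call <- call_rate < config$site_call_rate_min
  status[surviving[is.na(status[surviving]) & low_call]] <- "site_call_rate"

  idx <- which(is.na(status[surviving]))
  low_maf <- !is.na(maf) & maf <= config$maf_min
  bad <- intersect(idx, which(low_maf | is.na(maf)))
  status[surviving[bad]] <- "maf"

  idx <- which(is.na(status[surviving]))
  if (length(idx)) {
    hwe_p <- vapply(idx, function(i) {
      row <- dos[i, ]
      if (hwe_per_pop && !is.null(popmap)) {
        pops <- popmap[keep_samples]
        min(vapply(unique(pops), function(pp) {
          r <- row[!is.na(pops) & pops == pp]
          r <- r[!is.na(r)]
          if (!length(r)) return(1)
          hwe_exact_p(sum(r == 0L), sum(r == 1L), sum(r == 2L))
        }, 1))
      } else {
        r <- row[!is.na(row)]
        hwe_exact_p(sum(r == 0L), sum(r == 1L), sum(r == 2L))
      }
    }, 1)
    status[surviving[idx[hwe_p < config$hwe_p_min]]] <- "hwe"
  }

  # proximity thinning over the sites still alive, per chromosome
  alive <- which(is.na(status))
  for (ch in unique(gs$chrom[alive])) {
    ii <- alive[gs$chrom[alive] == ch]
    keep <- thin_by_distance(gs$pos[ii], config$thin_bp)
    status[ii[!keep]] <- "thinning"
  }

  kept <- which(is.na(status))
  report <- table(factor(status, levels = c("info_hard_filter",
                                            "not_biallelic_track",
                                            "site_call_rate", "maf", "hwe",
                                            "thinning")))
  out <- gs_subset(gs, sites = kept, samples = which(!drop_samp))
  list(gs = out,
       report = data.frame(criterion = names(report),
                           removed = as.integer(report)),
       removed_samples = removed_samples,
       n_input = n0, n_kept = length(kept))
}
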