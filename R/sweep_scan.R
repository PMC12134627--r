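# Sliding-window nucleotide diversity and Hudson's Fst, joint top-quantile
# outlier calling, region merging, Mann-Whitney background testing and
# gene-level ranking.

#' Tile a genome with full-width sliding windows
#'
#' Windows start at 1, 1+step, ...; only full-width windows are emitted,
#' so a chromosome of length `L` yields `floor((L - width)/step) + 1`
#' windows (zero when `L < width`).
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param width window width in bp (default 40 kb).
#' @param step slide step in bp (default 10 kb).
#' @return data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
make_windows <- function(chrom_lengths, width = 40000L, step = 10000L) {
  if (width <= 0) stop("width must be positive")
  if (step <= 0) stop("step must be positive")
  if (width < step) warning("width < step leaves gaps between windows")
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < width) return(NULL)
    nw <- (L - width) %/% step + 1L
    starts <- 1L + step * (seq_len(nw) - 1L)
    data.frame(chrom = ch, start = starts, end = starts + width - 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(0), start = integer(0),
                               end = integer(0))
  else out
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference at one site: with `c` alternate alleles among
#' `n` called alleles, `2 c (n - c) / (n (n - 1))`. Sites with `n < 2`
#' contribute 0 (uninformative).
#'
#' @param c alternate allele count(s).
#' @param n called allele count(s).
#' @return per-site pi, vectorised.
#' @export
site_pi <- function(c, n) {
  ifelse(n >= 2, 2 * c * (n - c) / (n * (n - 1)), 0)
}

#' Per-bp window diversity
#' @param site_pis per-site pi values for the sites falling in the window.
#' @param width window width in bp (the fixed denominator; callable-site
#'   denominators are not used).
#' @return per-bp theta-pi for the window.
#' @export
window_pi <- function(site_pis, width = 40000L) sum(site_pis) / width

#' Hudson's Fst (ratio of sums)
#'
#' Per-site numerator `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' and denominator `D = p1(1-p2) + p2(1-p1)`; the aggregate estimate is
#' `sum(N)/sum(D)` over contributing sites. Sites with `D = 0` or with
#' fewer than 2 called alleles in either population are skipped.
#'
#' @param p1,p2 alternate-allele frequencies per site.
#' @param n1,n2 called allele counts per site.
#' @return list with per-site `nhat`, `dhat`, the skipped mask `used`,
#'   and the aggregate `fst` (NA when `sum(D) = 0`).
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  nhat <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  dhat <- p1 * (1 - p2) + p2 * (1 - p1)
  nhat[!ok] <- NA_real_
  dhat[!ok] <- NA_real_
  used <- ok & !is.na(dhat) & dhat > 0
  sN <- sum(nhat[used])
  sD <- sum(dhat[used])
  list(nhat = nhat, dhat = dhat, used = used,
       fst = if (sD > 0) sN / sD else NA_real_)
}

# per-population alt-allele count and called-allele count at every site
.pop_counts <- function(gs, popmap, pop) {
  idx <- which(!is.na(popmap[gs$samples]) & popmap[gs$samples] == pop)
  if (length(idx) < 2L) stop("population ", pop, " has fewer than 2 samples")
  dos <- gs_dosage(gs)[, idx, drop = FALSE]
  list(ac = rowSums(dos, na.rm = TRUE),
       an = 2 * rowSums(!is.na(dos)))
}

# accumulate per-site values into sliding windows (vectorised over the
# <= ceiling(width/step) windows covering each site)
.window_accumulate <- function(pos, values, n_windows, width, step) {
  out <- numeric(n_windows)
  k <- ceiling(width / step)
  base_j <- (pos - 1L) %/% step + 1L
  for (off in 0:(k - 1L)) {
    j <- base_j - off
    valid <- j >= 1L & j <= n_windows & pos <= (j - 1L) * step + width &
      !is.na(values)
    if (!any(valid)) next
    t <- rowsum(values[valid], j[valid])
    out[as.integer(rownames(t))] <- out[as.integer(rownames(t))] + t[, 1L]
  }
  out
}

#' Windowed diversity and differentiation scan
#'
#' For one focal/reference population pair, computes per window: per-bp
#' theta-pi in each population, Hudson's Fst (ratio of sums), and
#' `log2(pi_reference / pi_focal)` — oriented so positive values mean
#' diversity loss in the focal population. Windows with fewer informative
#' sites than `min_sites` are flagged and excluded from downstream
#' quantiles; windows whose Fst denominator is zero are undefined.
#'
#' @param gs a biallelic-SNP [genotype_set()] (output of [cohort_filter()]).
#' @param popmap named vector sample -> population.
#' @param focal,reference population labels.
#' @param chrom_lengths named vector; defaults to max position per
#'   chromosome.
#' @param width,step window geometry in bp.
#' @param min_sites minimum informative sites for a window to enter
#'   quantile computations.
#' @return list with `windows` (one row per window: `chrom`, `start`,
#'   `end`, `n_sites`, `pi_focal`, `pi_ref`, `fst`, `log2_ratio`,
#'   `defined`, `sufficient`) and `sites` (per-site `chrom`, `pos`,
#'   `nhat`, `dhat`, `fst_site`).
#' @export
window_scan <- function(gs, popmap, focal, reference,
                        chrom_lengths = NULL,
                        width = 40000L, step = 10000L, min_sites = 10L) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(gs$pos, gs$chrom), max, 1L)
  }
  win <- make_windows(chrom_lengths, width, step)
  f <- .pop_counts(gs, popmap, focal)
  r <- .pop_counts(gs, popmap, reference)
  pi_f <- site_pi(f$ac, f$an)
  pi_r <- site_pi(r$ac, r$an)
  pf <- ifelse(f$an > 0, f$ac / f$an, NA_real_)
  pr <- ifelse(r$an > 0, r$ac / r$an, NA_real_)
  hf <- hudson_fst(pf, f$an, pr, r$an)
  informative <- f$an >= 2 & r$an >= 2

  per_chrom <- lapply(unique(win$chrom), function(ch) {
    wch <- win[win$chrom == ch, , drop = FALSE]
    nw <- nrow(wch)
    sel <- gs$chrom == ch
    pos <- gs$pos[sel]
    acc <- function(v) .window_accumulate(pos, v, nw, width, step)
    data.frame(
      chrom = ch, start = wch$start, end = wch$end,
      n_sites = as.integer(acc(as.numeric(informative[sel]))),
      pi_focal = acc(pi_f[sel]) / width,
      pi_ref = acc(pi_r[sel]) / width,
      sum_n = acc(ifelse(hf$used[sel], hf$nhat[sel], NA_real_)),
      sum_d = acc(ifelse(hf$used[sel], hf$dhat[sel], NA_real_)))
  })
  w <- do.call(rbind, per_chrom)
  w$fst <- ifelse(w$sum_d > 0, w$sum_n / w$sum_d, NA_real_)
  w$log2_ratio <- ifelse(w$pi_focal > 0 & w$pi_ref > 0,
                         log2(w$pi_ref / w$pi_focal), NA_real_)
  w$defined <- !is.na(w$fst)
  w$sufficient <- w$n_sites >= min_sites
  w$sum_n <- w$sum_d <- NULL
  sites <- data.frame(chrom = gs$chrom, pos = gs$pos,
                      nhat = hf$nhat, dhat = hf$dhat,
                      fst_site = ifelse(hf$used, hf$nhat / hf$dhat, NA_real_))
  list(windows = w, sites = sites,
       focal = focal, reference = reference, width = width, step = step)
}

# nearest-rank inclusive quantile: the value at rank ceiling(q * n)
.nearest_rank <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q * length(x)))]
}

#' Joint top-quantile outlier windows
#'
#' A window is an outlier for the focal population iff its Fst is at or
#' above the empirical `q` quantile of defined windows AND its
#' `log2(pi_ref/pi_focal)` is at or above the `q` quantile of finite
#' ratios (directional: diversity reduced in the focal population).
#' Quantiles are nearest-rank and inclusive, so ties at the threshold are
#' all outliers; with a degenerate (constant) distribution every window
#' passes.
#'
#' @param scan result of [window_scan()].
#' @param q quantile (default 0.95, the top 5%).
#' @return the outlier rows of `scan$windows`, with the thresholds as
#'   attributes `fst_threshold` and `ratio_threshold`.
#' @export
joint_outlier_windows <- function(scan, q = 0.95) {
  w <- scan$windows
  use <- w$defined & w$sufficient
  if (sum(use) < 100L)
    stop("fewer than 100 defined windows; quantiles unstable")
  thr_fst <- .nearest_rank(w$fst[use], q)
  ratios <- w$log2_ratio[use & is.finite(w$log2_ratio)]
  thr_ratio <- .nearest_rank(ratios, q)
  out <- w[use & w$fst >= thr_fst &
             is.finite(w$log2_ratio) & w$log2_ratio >= thr_ratio, ,
           drop = FALSE]
  attr(out, "fst_threshold") <- thr_fst
  attr(out, "ratio_threshold") <- thr_ratio
  out
}

#' Merge outlier windows into sweep regions
#'
#' Overlapping or book-ended windows (gap at most `step` bp) on the same
#' chromosome merge into one region spanning their union; the region
#' carries the number of merged windows and the peak window Fst and
#' log2 ratio.
#'
#' @param outliers data frame of outlier windows (from
#'   [joint_outlier_windows()]).
#' @param step the scan step, bounding the merge gap.
#' @return data frame of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_fst`, `peak_log2_ratio`.
#' @export
merge_regions <- function(outliers, step = 10000L) {
  if (!nrow(outliers))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      peak_fst = numeric(0), peak_log2_ratio = numeric(0)))
  o <- outliers[order(outliers$chrom, outliers$start), , drop = FALSE]
  new_run <- c(TRUE, o$chrom[-1L] != o$chrom[-nrow(o)] |
                 o$start[-1L] > o$end[-nrow(o)] + step + 1L)
  grp <- cumsum(new_run)
  do.call(rbind, lapply(split(o, grp), function(g)
    data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
               n_windows = nrow(g), peak_fst = max(g$fst),
               peak_log2_ratio = max(g$log2_ratio))))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. When `n1 * n2 <= 400` the
#' two-sided p-value is exact: the permutation distribution of U is built
#' by a subset-sum dynamic programme over the (doubled) midranks, which
#' handles ties exactly; `p = Pr(|U - n1 n2 / 2| >= |observed|)`. For
#' larger samples the normal approximation with tie-corrected variance
#' and continuity correction is used (via `stats::wilcox.test`).
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (number of (x, y) pairs with x > y, counting
#'   ties half) and two-sided `p`.
#' @export
mannwhitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("empty sample")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 400) {
    r2 <- as.integer(round(2 * r))        # doubled midranks are integers
    S <- sum(r2)
    # ways[j + 1, s + 1] = number of size-j subsets with doubled-rank sum s
    ways <- matrix(0, n1 + 1L, S + 1L)
    ways[1L, 1L] <- 1
    for (v in r2) {
      jmax <- n1
      for (j in jmax:1) {
        src <- ways[j, 1:(S + 1L - v)]
        if (any(src > 0))
          ways[j + 1L, (v + 1L):(S + 1L)] <-
            ways[j + 1L, (v + 1L):(S + 1L)] + src
      }
    }
    cnt <- ways[n1 + 1L, ]
    s_vals <- which(cnt > 0) - 1L
    u2 <- s_vals - n1 * (n1 + 1L)         # doubled U values
    dev_obs <- abs(2 * U - n1 * n2)
    p <- sum(cnt[s_vals + 1L][abs(u2 - n1 * n2) >= dev_obs - 1e-9]) /
      choose(n1 + n2, n1)
    p <- min(1, p)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                       correct = TRUE))
    p <- wt$p.value
  }
  list(U = unname(U), p = p)
}

#' Attach Mann-Whitney background p-values to sweep regions
#'
#' Compares each region's per-site Fst values (Hudson per-site N/D)
#' against the genome-wide per-site background, and the region's
#' per-window log2 pi ratios against all windows. The test reports and
#' flags; it never discards regions. Regions with fewer than 3
#' informative sites get `p = 1` and a flag.
#'
#' @param regions output of [merge_regions()].
#' @param scan output of [window_scan()] (supplies site- and window-level
#'   background).
#' @param flag_p regions with both p-values below this are flagged
#'   `significant` (default 1e-16).
#' @return `regions` with `mw_p_fst`, `mw_p_ratio`, `n_informative`,
#'   `significant` columns.
#' @export
region_significance <- function(regions, scan, flag_p = 1e-16) {
  sites <- scan$sites
  bg_fst <- sites$fst_site[!is.na(sites$fst_site)]
  w <- scan$windows
  bg_ratio <- w$log2_ratio[is.finite(w$log2_ratio)]
  res <- lapply(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    in_reg <- sites$chrom == rg$chrom & sites$pos >= rg$start &
      sites$pos <= rg$end & !is.na(sites$fst_site)
    x <- sites$fst_site[in_reg]
    if (length(x) < 3L) {
      c(mw_p_fst = 1, mw_p_ratio = 1, n_informative = length(x))
    } else {
      wr <- w$chrom == rg$chrom & w$start >= rg$start & w$end <= rg$end &
        is.finite(w$log2_ratio)
      p_ratio <- if (sum(wr) >= 1L)
        mannwhitney_u(w$log2_ratio[wr], bg_ratio)$p else 1
      c(mw_p_fst = mannwhitney_u(x, bg_fst)$p,
        mw_p_ratio = p_ratio, n_informative = length(x))
    }
  })
  res <- do.call(rbind, res)
  regions$mw_p_fst <- res[, "mw_p_fst"]
  regions$mw_p_ratio <- res[, "mw_p_ratio"]
  regions$n_informative <- as.integer(res[, "n_informative"])
  regions$significant <- regions$mw_p_fst < flag_p &
    regions$mw_p_ratio < flag_p
  regions
}

#' Rank genes by peak sweep Fst
#'
#' Each gene overlapping any sweep region (by at least 1 bp) is scored
#' with the maximum `peak_fst` over its overlapping regions; the table is
#' sorted descending. Genes without a name are reported as `"NA"`.
#'
#' @param regions sweep regions data frame.
#' @param models gene models from [read_gtf()].
#' @param top_n truncate the table (default all genes).
#' @return data frame `gene_id`, `gene_name`, `chrom`, `gene_fst`.
#' @export
rank_genes <- function(regions, models, top_n = Inf) {
  gr_genes <- gene_ranges(models)
  if (!nrow(regions))
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), gene_fst = numeric(0)))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start,
                                                    regions$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_reg, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), gene_fst = numeric(0)))
  df <- data.frame(gene = S4Vectors::queryHits(hits),
                   fst = regions$peak_fst[S4Vectors::subjectHits(hits)])
  agg <- tapply(df$fst, df$gene, max)
  gi <- as.integer(names(agg))
  nm <- vapply(models[gi], function(m)
    if (is.na(m$gene_name) || !nzchar(m$gene_name)) "NA" else m$gene_name, "")
  out <- data.frame(gene_id = names(gr_genes)[gi], gene_name = nm,
                    chrom = vapply(models[gi], `[[`, "", "chrom"),
                    gene_fst = as.numeric(agg))
  out <- out[order(-out$gene_fst), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
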