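# TPM quantification, expressed-gene filtering, median-of-ratios size
# factors, negative-binomial Wald differential expression, pairwise DEG
# matrices, and the sample-level PCA / Spearman summaries.

#' Transcripts per million
#'
#' `TPM_gj = 1e6 * (c_gj / l_g) / sum_i(c_ij / l_i)`; every column sums to
#' one million by construction.
#'
#' @param counts genes x samples matrix of raw counts.
#' @param lengths per-gene length in bp.
#' @return TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  rate <- counts / lengths
  cs <- colSums(rate)
  if (any(cs == 0)) stop("sample with zero total counts: ",
                         paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(rate, 2L, cs, "/") * 1e6
}

#' Expressed-gene filter
#'
#' A gene counts as expressed when at least `min_reps` replicates WITHIN a
#' single (condition, timepoint) group reach `tpm_min`; replicates spread
#' across groups do not qualify.
#'
#' @param tpm_mat TPM matrix (genes x samples).
#' @param meta sample metadata with `sample`, `condition`, `timepoint`.
#' @param tpm_min expression threshold (default 0.5 TPM).
#' @param min_reps replicate support required (default 2).
#' @return logical vector over genes.
#' @export
expressed_filter <- function(tpm_mat, meta, tpm_min = 0.5, min_reps = 2L) {
  grp <- interaction(meta$condition, meta$timepoint, drop = TRUE)
  hits <- tpm_mat >= tpm_min
  any_group <- rep(FALSE, nrow(tpm_mat))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    any_group <- any_group |
      rowSums(hits[, cols, drop = FALSE]) >= min_reps
  }
  any_group
}

#' Median-of-ratios size factors
#'
#' `s_j` is the median over genes with all-positive counts of
#' `c_gj / geomean_g(c_g.)`. No further rescaling is applied, so identical
#' samples get identical (not necessarily unit) factors.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors (> 0).
#' @export
size_factors <- function(counts) {
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("no gene has positive counts in every sample; ",
         "a pseudo-reference would be required")
  lc <- log(counts[allpos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(exp(lc - geo), 2L, median)
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with enforced monotonicity, capped at 1.
#' @param p p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Negative-binomial Wald test between two groups
#'
#' Works on size-factor-normalised counts. Per gene: group means
#' `mu_A`, `mu_B`; pooled method-of-moments dispersion
#' `alpha = max((s2 - mu)/mu^2, 1e-8)` from within-group variances;
#' `log2FC = log2((mu_B + 0.5)/(mu_A + 0.5))` (pseudocount 0.5 guards
#' zero means); `SE^2 = (1/ln 2)^2 * [(1/(n_A mu_A') + alpha/n_A) +
#' (1/(n_B mu_B') + alpha/n_B)]` with `mu' = mu + 0.5`; two-sided normal
#' p from `z = log2FC / SE`; BH across the tested genes. A gene is a DEG
#' iff `padj < alpha_deg` and `|log2FC| > lfc_min`.
#'
#' This is a deliberate simplification of shrinkage-based NB machinery:
#' no dispersion shrinkage, no outlier replacement.
#'
#' @param counts_A,counts_B genes x replicates count matrices (same genes,
#'   >= 2 replicates each).
#' @param sf_A,sf_B size factors for the two groups' samples.
#' @param alpha_deg,lfc_min DEG decision thresholds (defaults 0.01 and 2).
#' @return data frame per gene: `baseMean_A`, `baseMean_B`, `log2fc`,
#'   `se`, `wald_z`, `p`, `padj`, `is_deg`.
#' @export
nb_wald_test <- function(counts_A, counts_B, sf_A, sf_B,
                         alpha_deg = 0.01, lfc_min = 2) {
  stopifnot(nrow(counts_A) == nrow(counts_B),
            ncol(counts_A) >= 2L, ncol(counts_B) >= 2L,
            length(sf_A) == ncol(counts_A), length(sf_B) == ncol(counts_B))
  if (all(counts_A == 0) || all(counts_B == 0))
    stop("a group has all-zero counts for every gene")
  nA <- sweep(counts_A, 2L, sf_A, "/")
  nB <- sweep(counts_B, 2L, sf_B, "/")
  muA <- rowMeans(nA); muB <- rowMeans(nB)
  vA <- apply(nA, 1L, var); vB <- apply(nB, 1L, var)
  kA <- ncol(nA); kB <- ncol(nB)
  # pooled within-group variance and mean for the moment dispersion
  mu_pool <- (kA * muA + kB * muB) / (kA + kB)
  s2_pool <- ((kA - 1) * vA + (kB - 1) * vB) / (kA + kB - 2)
  alpha <- pmax((s2_pool - mu_pool) / mu_pool^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  muAp <- muA + 0.5; muBp <- muB + 0.5
  log2fc <- log2(muBp / muAp)
  se2 <- (1 / log(2))^2 *
    ((1 / (kA * muAp) + alpha / kA) + (1 / (kB * muBp) + alpha / kB))
  se <- sqrt(se2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  padj <- bh_adjust(p)
  data.frame(baseMean_A = muA, baseMean_B = muB, log2fc = log2fc,
             se = se, wald_z = z, p = p, padj = padj,
             is_deg = padj < alpha_deg & abs(log2fc) > lfc_min,
             row.names = rownames(counts_A))
}

#' Pairwise DEG matrix over (condition, timepoint) groups
#'
#' Runs [nb_wald_test()] for every unordered pair of groups and returns
#' the symmetric DEG-count matrix (zero diagonal) plus per-pair up/down
#' splits (up: `log2fc > lfc_min` among DEGs; down: `log2fc < -lfc_min`).
#' Size factors are computed once over all samples. Pairs involving a
#' group with fewer than 2 replicates are skipped with a warning.
#'
#' @param cm a [count_matrix()].
#' @param genes optional restriction (e.g. the expressed-gene set).
#' @param alpha_deg,lfc_min DEG thresholds.
#' @return list with `matrix` (groups x groups DEG counts), `pairs`
#'   (data frame: `group_A`, `group_B`, `n_deg`, `n_up`, `n_down`) and
#'   `tests` (named list of per-pair [nb_wald_test()] tables).
#' @export
pairwise_deg_matrix <- function(cm, genes = NULL, alpha_deg = 0.01,
                                lfc_min = 2) {
  counts <- cm$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  sf <- size_factors(cm$counts)
  grp <- paste0(cm$meta$condition, cm$meta$timepoint)
  glev <- unique(grp)
  m <- matrix(0L, length(glev), length(glev),
              dimnames = list(glev, glev))
  pairs <- list(); tests <- list()
  for (i in seq_along(glev)) for (j in seq_along(glev)) {
    if (j <= i) next
    ca <- which(grp == glev[i]); cb <- which(grp == glev[j])
    if (length(ca) < 2L || length(cb) < 2L) {
      warning("group with < 2 replicates; skipping ",
              glev[i], " vs ", glev[j])
      next
    }
    de <- nb_wald_test(counts[, ca, drop = FALSE],
                       counts[, cb, drop = FALSE],
                       sf[ca], sf[cb], alpha_deg, lfc_min)
    deg <- de[de$is_deg, , drop = FALSE]
    m[i, j] <- m[j, i] <- nrow(deg)
    key <- paste0(glev[i], "_vs_", glev[j])
    tests[[key]] <- de
    pairs[[key]] <- data.frame(group_A = glev[i], group_B = glev[j],
                               n_deg = nrow(deg),
                               n_up = sum(deg$log2fc > lfc_min),
                               n_down = sum(deg$log2fc < -lfc_min))
  }
  list(matrix = m, pairs = do.call(rbind, c(pairs, make.row.names = FALSE)),
       tests = tests)
}

#' Sample-level PCA on log TPM
#'
#' PCA of `log2(TPM + 1)`, gene-centred, via SVD; returns the sample
#' scores and the proportion of variance explained.
#'
#' @param tpm_mat TPM matrix (genes x samples).
#' @param n_pc number of components to keep.
#' @return list with `scores` (samples x PCs) and `var_explained`.
#' @export
sample_pca <- function(tpm_mat, n_pc = 5L) {
  x <- t(log2(tpm_mat + 1))           # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  k <- min(n_pc, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(scores) <- colnames(tpm_mat)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Spearman correlation between samples
#' @param tpm_mat TPM matrix (genes x samples).
#' @return samples x samples correlation matrix (midranks for ties).
#' @export
sample_spearman <- function(tpm_mat) {
  cor(tpm_mat, method = "spearman")
}
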