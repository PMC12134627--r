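# Fuzzy c-means clustering of per-stage mean expression profiles:
# missingness filter -> mean fill -> sd filter -> row z-score ->
# fuzzifier estimation -> seeded fuzzy c-means.

#' Build standardised temporal profiles for one condition
#'
#' Per (condition, timepoint) group, takes the replicate mean TPM, then:
#' drops genes with more than `na_threshold` missing timepoints, fills the
#' remaining missing entries with the gene's row mean, drops genes whose
#' row standard deviation is at or below `std_min`, and z-scores each row
#' (mean 0, sd 1).
#'
#' @param tpm_mat TPM matrix (genes x samples).
#' @param meta sample metadata (`sample`, `condition`, `timepoint`).
#' @param condition which condition to profile (e.g. `"FE"` or `"VE"`).
#' @param na_threshold maximum tolerated fraction of missing timepoints.
#' @param std_min genes with row sd at or below this are removed.
#' @return genes x timepoints matrix of z-scored mean profiles; column
#'   names are the sorted timepoints.
#' @export
prepare_profiles <- function(tpm_mat, meta, condition,
                             na_threshold = 0.25, std_min = 0) {
  sel <- meta$condition == condition
  if (!any(sel)) stop("no samples for condition ", condition)
  tps <- sort(unique(meta$timepoint[sel]))
  if (length(tps) < 2L) stop("need at least 2 timepoints")
  prof <- vapply(tps, function(tp) {
    cols <- which(sel & meta$timepoint == tp)
    rowMeans(tpm_mat[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(tpm_mat)))
  colnames(prof) <- as.character(tps)
  prof[is.nan(prof)] <- NA_real_
  keep <- rowMeans(is.na(prof)) <= na_threshold
  prof <- prof[keep, , drop = FALSE]
  rm_ <- rowMeans(prof, na.rm = TRUE)
  idx <- which(is.na(prof), arr.ind = TRUE)
  if (nrow(idx)) prof[idx] <- rm_[idx[, 1L]]
  sds <- apply(prof, 1L, sd)
  prof <- prof[sds > std_min, , drop = FALSE]
  sds <- sds[sds > std_min]
  (prof - rowMeans(prof)) / sds
}

#' Empirical fuzzifier estimate
#'
#' The published empirical rule relating the fuzzy c-means exponent `m`
#' to data dimensions:
#' `m = 1 + (1418/N + 22.05) D^-2 +
#'      (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`
#' for `N` genes and `D` timepoints.
#'
#' @param n_genes N (>= 2).
#' @param n_timepoints D (>= 2).
#' @return the fuzzifier m (> 1).
#' @export
mestimate <- function(n_genes, n_timepoints) {
  N <- n_genes; D <- n_timepoints
  if (N < 2 || D < 2) stop("need N >= 2 and D >= 2")
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering
#'
#' Minimises `J = sum_i sum_k u_ik^m ||x_i - v_k||^2` by alternating the
#' standard membership update `u_ik = 1 / sum_j (d_ik/d_jk)^(2/(m-1))`
#' and centroid update `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`.
#' Initialisation draws a random membership matrix (rows normalised to 1)
#' from the RNG seeded with `seed`; iterations stop when
#' `max |delta U| < tol`. A point coinciding with a centroid gets
#' membership 1 there. Deterministic given (seed, data, parameters).
#'
#' @param x genes x timepoints profile matrix (rows typically z-scored).
#' @param c number of clusters (default 6).
#' @param m fuzzifier (> 1); default from [mestimate()].
#' @param seed RNG seed for the membership initialisation (default 150).
#' @param tol,max_iter convergence controls.
#' @return a `fuzzy_clustering`: list with `membership` (genes x c),
#'   `centroids` (c x timepoints), `m`, `n_iter`, `objective` (the J
#'   trajectory, non-increasing).
#' @export
fuzzy_cmeans <- function(x, c = 6L, m = NULL, seed = 150L,
                         tol = 1e-6, max_iter = 1000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c > n) stop("more clusters than genes")
  if (is.null(m)) m <- mestimate(n, ncol(x))
  stopifnot(m > 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  u <- matrix(runif(n * c), n, c)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  u <- u / rowSums(u)
  obj <- numeric(0)
  it <- 0L
  for (it in seq_len(max_iter)) {
    um <- u^m
    v <- (t(um) %*% x) / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(v) +
      outer(rep(1, n), rowSums(v^2))
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0L
    if (any(hit)) {
      u_new[hit, ] <- 0
      u_new[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  um <- u^m
  v <- (t(um) %*% x) / colSums(um)
  rownames(u) <- rownames(x)
  colnames(v) <- colnames(x)
  structure(list(membership = u, centroids = v, m = m, n_iter = it,
                 objective = obj),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("fuzzy_clustering: %d genes, %d clusters, m = %.3f, %d iterations\n",
              nrow(x$membership), ncol(x$membership), x$m, x$n_iter))
  invisible(x)
}

#' Harden a fuzzy clustering into gene lists
#'
#' Assigns each gene to its argmax cluster when the maximum membership
#' reaches `membership_min`, else leaves it unassigned.
#'
#' @param fc a [fuzzy_cmeans()] result.
#' @param membership_min assignment threshold (default 0.5).
#' @return list with `assignment` (integer per gene, `NA` = unassigned),
#'   `clusters` (list of gene-id vectors), `centroids`.
#' @export
cluster_report <- function(fc, membership_min = 0.5) {
  u <- fc$membership
  amax <- max.col(u, ties.method = "first")
  top <- u[cbind(seq_len(nrow(u)), amax)]
  assignment <- ifelse(top >= membership_min, amax, NA_integer_)
  names(assignment) <- rownames(u)
  clusters <- lapply(seq_len(ncol(u)), function(k)
    rownames(u)[!is.na(assignment) & assignment == k])
  names(clusters) <- paste0("cluster_", seq_len(ncol(u)))
  list(assignment = assignment, clusters = clusters,
       centroids = fc$centroids)
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted temporal templates by hardened
#' cluster assignments. `NA` labels are dropped pairwise.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
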