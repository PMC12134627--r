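# Independent brute-force oracles used across the suite. These are
# deliberately naive (enumeration / all-pairs) and share no code with the
# package implementations they check.

# Exact HWE p by direct enumeration of the Levene/Haldane distribution:
# P(h | nA, na) = n! / (nAA! h! naa!) * 2^h * nA! * na! / (2n)! summed
# over all heterozygote counts with matching parity.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (na - h) / 2
    nAA <- (nA - h) / 2
    lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# All-pairs per-bp diversity from allele counts: expand each site into an
# explicit allele vector and average pairwise differences.
oracle_window_pi <- function(alt_counts, called_alleles, width) {
  tot <- 0
  for (i in seq_along(alt_counts)) {
    n <- called_alleles[i]
    if (n < 2) next
    al <- c(rep(1, alt_counts[i]), rep(0, n - alt_counts[i]))
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      diffs <- diffs + (al[a] != al[b])
      pairs <- pairs + 1
    }
    tot <- tot + diffs / pairs
  }
  tot / width
}

# Exact Mann-Whitney p by enumerating all C(n1+n2, n1) group labellings.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Exhaustive upper-tail hypergeometric.
oracle_hyper_p <- function(k, K, M, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(M - K, n - ks)) / choose(M, n)
}

# Step-up BH from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# The 8-record toy genotype set in which each doomed site violates
# exactly one cohort-filter criterion (survivors at 1000 and 2000).
# Built with 24 samples so the HWE-fail site (12 hom-ref / 0 het /
# 12 hom-alt) can actually reach p < 1e-5. Pair it with
# filter_config(sample_call_rate_min = 0.5) so the two missing calls at
# the call-rate site do not drop their samples (with 6 relevant sites
# any missing call exceeds a 10% per-sample missingness budget).
make_filter_toy <- function() {
  ns <- 24L
  half <- rep(c(0L, 1L), each = ns / 2)
  # dosage rows; -1 encodes a missing call
  rows <- list(
    qd_fail     = half,
    multi       = half,
    call_fail   = c(-1L, -1L, half[-(1:2)]),
    maf_fail    = rep(0L, ns),
    hwe_fail    = rep(c(0L, 2L), each = ns / 2),
    clean1      = half,
    thin_victim = half,
    clean2      = half)
  dos <- do.call(rbind, rows)
  a1 <- ifelse(dos >= 1L, 1L, 0L); a1[dos < 0L] <- NA_integer_
  a2 <- ifelse(dos == 2L, 1L, 0L); a2[dos < 0L] <- NA_integer_
  pos <- c(100L, 200L, 300L, 400L, 500L, 1000L, 1004L, 2000L)
  alt <- c("T", "T,G", "T", "T", "T", "T", "T", "T")
  info <- data.frame(QD = c(9.9, rep(25, 7)), MQ = 50, FS = 5,
                     MQRankSum = 0, ReadPosRankSum = 0)
  genotype_set(rep("chr1", 8L), pos, rep("A", 8L), alt, a1, a2,
               sprintf("S%02d", seq_len(ns)), info = info)
}
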