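test_that("TPM normalises rates to one million per sample", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  out <- tpm(counts, c(1000, 2000))
  expect_equal(as.numeric(out), c(666666.6667, 333333.3333),
               tolerance = 1e-9)
  one <- tpm(matrix(5, 1, 1), 500)
  expect_equal(as.numeric(one), 1e6)
  set.seed(3)
  big <- matrix(rpois(200, 50), 20, 10)
  expect_equal(colSums(tpm(big, rep(1000, 20))), rep(1e6, 10),
               tolerance = 1e-6)
  expect_error(tpm(matrix(0, 2, 1), c(100, 100)), "zero")
})

test_that("expressed filter requires support within a single group", {
  meta <- data.frame(sample = c("FE6_1", "FE6_2", "FE7_1", "FE7_2"),
                     condition = "FE", timepoint = c(6, 6, 7, 7),
                     replicate = c(1, 2, 1, 2))
  tpm_mat <- rbind(two_in_group = c(0.6, 0.7, 0, 0),
                   split_groups = c(0.6, 0, 0.6, 0),
                   zeros = c(0, 0, 0, 0))
  keep <- expressed_filter(tpm_mat, meta)
  expect_identical(unname(keep), c(TRUE, FALSE, FALSE))
})

test_that("size factors follow the median-of-ratios construction", {
  sf <- size_factors(matrix(c(2, 4, 4, 8), 2, 2, byrow = TRUE))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)
  # identical samples: equal factors (no rescaling applied)
  sfe <- size_factors(matrix(c(3, 3, 7, 7), 2, 2, byrow = TRUE))
  expect_equal(unname(sfe), c(1, 1))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)),
               "pseudo-reference")
})

test_that("BH adjustment matches the step-up definition", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(bh_adjust(p), c(0.004, 0.02, 0.02666667, 0.8),
               tolerance = 1e-6)
  set.seed(4)
  pr <- runif(50)
  expect_equal(bh_adjust(pr), oracle_bh(pr), tolerance = 1e-12)
  expect_identical(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
})

test_that("NB Wald test is null-calibrated and antisymmetric", {
  set.seed(21)
  mu <- rlnorm(500, log(200), 0.8)
  A <- matrix(rnbinom(500 * 6, mu = mu, size = 10), 500, 6)
  B <- matrix(rnbinom(500 * 6, mu = mu, size = 10), 500, 6)
  rownames(A) <- rownames(B) <- sprintf("g%03d", 1:500)
  de <- nb_wald_test(A, B, rep(1, 6), rep(1, 6))
  expect_lt(median(abs(de$log2fc)), 0.5)
  expect_identical(sum(de$is_deg), 0L)
  expect_true(all(de$padj >= de$p))
  # group swap: log2fc negates, p unchanged
  de_swap <- nb_wald_test(B, A, rep(1, 6), rep(1, 6))
  expect_equal(de_swap$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_equal(de_swap$p, de$p, tolerance = 1e-12)
})

test_that("planted 8-fold genes are detected with high power", {
  set.seed(22)
  n <- 400L
  mu <- rep(200, n)
  fold <- rep(1, n); fold[1:100] <- 8
  A <- matrix(rnbinom(n * 6, mu = mu, size = 10), n, 6)
  B <- matrix(rnbinom(n * 6, mu = mu * fold, size = 10), n, 6)
  rownames(A) <- rownames(B) <- sprintf("g%03d", 1:n)
  de <- nb_wald_test(A, B, rep(1, 6), rep(1, 6))
  expect_gte(mean(de$is_deg[1:100]), 0.9)
  expect_equal(median(de$log2fc[1:100]), 3, tolerance = 0.15)
  expect_lte(sum(de$is_deg[101:n]), 2L)
})

test_that("pairwise DEG matrix is symmetric with up/down partition", {
  sim <- simulate_counts(counts_sim_config(n_genes = 600L, n_de = 60L,
                                           flat_only = TRUE),
                         seed = 31)
  res <- pairwise_deg_matrix(sim$cm)
  expect_true(isSymmetric(res$matrix))
  expect_identical(unname(diag(res$matrix)), rep(0L, 8L))
  expect_identical(res$pairs$n_deg, res$pairs$n_up + res$pairs$n_down)
  # planted day-9 condition effect dominates same-day contrasts
  same_day <- res$pairs[paste0(res$pairs$group_A, res$pairs$group_B) %in%
                          c("FE6VE6", "FE7VE7", "FE8VE8", "FE9VE9"), ]
  expect_identical(
    paste0(same_day$group_A[which.max(same_day$n_deg)],
           same_day$group_B[which.max(same_day$n_deg)]), "FE9VE9")
  # a fully null simulation yields an (almost) empty matrix
  null_sim <- simulate_counts(counts_sim_config(n_genes = 600L, n_de = 0L,
                                                flat_only = TRUE),
                              seed = 32)
  null_res <- pairwise_deg_matrix(null_sim$cm)
  expect_lte(max(null_res$matrix), 2L)
})

test_that("sample PCA matches a dense eigendecomposition and Spearman behaves", {
  set.seed(41)
  tp <- matrix(rlnorm(30, 5, 1), 10, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  res <- sample_pca(tp, n_pc = 2)
  x <- scale(t(log2(tp + 1)), center = TRUE, scale = FALSE)
  eig <- eigen(tcrossprod(x))
  scores_oracle <- x %*% svd(x)$v[, 1:2]
  for (k in 1:2)
    expect_equal(abs(res$scores[, k]), abs(scores_oracle[, k]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(res$var_explained <= 1), 2L)

  # duplicated sample: identical coordinates, Spearman 1; anti-monotone: -1
  tp2 <- cbind(s1 = tp[, 1], s2 = tp[, 1], s3 = max(tp[, 1]) + 1 - tp[, 1])
  p2 <- sample_pca(tp2, n_pc = 2)
  expect_equal(p2$scores["s1", ], p2$scores["s2", ], tolerance = 1e-9)
  sp <- sample_spearman(tp2)
  expect_equal(sp["s1", "s2"], 1)
  expect_equal(sp["s1", "s3"], -1)
})
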