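test_that("profile preparation filters, fills and standardises", {
  meta <- data.frame(sample = c("FE6_1", "FE6_2", "FE7_1", "FE8_1", "FE9_1"),
                     condition = "FE", timepoint = c(6, 6, 7, 8, 9),
                     replicate = c(1, 2, 1, 1, 1))
  tp <- rbind(ok       = c(1, 3, 4, 6, 8),
              one_gap  = c(2, 4, NA, 5, 7),    # 1/4 timepoints missing
              two_gaps = c(2, 2, NA, NA, 7),   # 2/4 missing -> dropped
              constant = c(5, 5, 5, 5, 5))
  prof <- prepare_profiles(tp, meta, "FE")
  expect_identical(rownames(prof), c("ok", "one_gap"))
  expect_equal(unname(rowMeans(prof)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(prof, 1, sd)), c(1, 1), tolerance = 1e-12)
  # the filled value is the row mean of observed timepoints, i.e. 0 after
  # z-scoring only if it equals the mean; here check fill happened
  expect_false(anyNA(prof))
  expect_error(prepare_profiles(tp, meta[meta$timepoint == 6, ], "FE"),
               "timepoints")
})

test_that("the fuzzifier estimate follows the empirical rule", {
  expect_equal(mestimate(1000, 4), 2.614653, tolerance = 1e-6)
  # strictly decreasing in D at fixed N
  ms <- vapply(2:10, function(D) mestimate(1000, D), 1)
  expect_true(all(diff(ms) < 0))
  # N -> Inf limit
  lim <- 1 + 22.05 / 16 + 0.243 * 4^(-0.0406 * log(1e9) - 0.1134)
  expect_equal(mestimate(1e9, 4), lim, tolerance = 1e-6)
  expect_error(mestimate(1, 4), "N >= 2")
})

test_that("fuzzy c-means satisfies its algebraic invariants", {
  set.seed(61)
  x <- matrix(rnorm(200), 50, 4)
  fc <- fuzzy_cmeans(x, c = 3, m = 2, seed = 150)
  expect_equal(unname(rowSums(fc$membership)), rep(1, 50),
               tolerance = 1e-9)
  expect_true(all(fc$membership >= 0 & fc$membership <= 1))
  expect_true(all(diff(fc$objective) <= 1e-9))
  # deterministic given seed
  fc2 <- fuzzy_cmeans(x, c = 3, m = 2, seed = 150)
  expect_identical(fc$membership, fc2$membership)
  # c = 1: trivial solution
  fc1 <- fuzzy_cmeans(x, c = 1, m = 2)
  expect_equal(unname(fc1$membership[, 1]), rep(1, 50))
  expect_equal(as.numeric(fc1$centroids), colMeans(x), tolerance = 1e-9)
  expect_error(fuzzy_cmeans(x, c = 51), "clusters")
  # duplicated points collapse onto their centroid: membership exactly 1
  x2 <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  fcd <- fuzzy_cmeans(x2, c = 2, m = 2, seed = 2)
  expect_true(all(apply(fcd$membership, 1, max) == 1))
})

test_that("two well-separated templates are recovered exactly", {
  set.seed(62)
  a <- matrix(rep(c(-1, -0.5, 0.5, 1), each = 30) + rnorm(120, 0, 0.05),
              30, 4)
  b <- matrix(rep(c(1, 0.5, -0.5, -1), each = 30) + rnorm(120, 0, 0.05),
              30, 4)
  x <- rbind(a, b)
  rownames(x) <- sprintf("g%02d", 1:60)
  fc <- fuzzy_cmeans(x, c = 2, m = 1.8, seed = 150)
  rep_ <- cluster_report(fc)
  truth <- rep(c(1, 2), each = 30)
  expect_equal(adjusted_rand_index(rep_$assignment, truth), 1)
  # as m -> 1+, hardened assignments agree with k-means from the centroids
  fc_low <- fuzzy_cmeans(x, c = 2, m = 1.05, seed = 150)
  km <- apply(x, 1, function(row)
    which.min(colSums((t(fc_low$centroids) - row)^2)))
  hard <- max.col(fc_low$membership)
  expect_equal(adjusted_rand_index(hard, km), 1)
})

test_that("cluster_report applies the membership threshold and partitions", {
  u <- rbind(c(0.9, 0.1), c(0.45, 0.55), c(0.5, 0.5), c(0.3, 0.7))
  rownames(u) <- paste0("g", 1:4)
  fc <- structure(list(membership = u,
                       centroids = matrix(0, 2, 4), m = 2,
                       n_iter = 1L, objective = 0),
                  class = "fuzzy_clustering")
  rep_ <- cluster_report(fc, membership_min = 0.5)
  expect_identical(unname(rep_$assignment), c(1L, 2L, 1L, 2L))
  rep_2 <- cluster_report(fc, membership_min = 0.6)
  expect_identical(unname(rep_2$assignment), c(1L, NA, NA, 2L))
  n_assigned <- sum(!is.na(rep_2$assignment))
  expect_identical(n_assigned + sum(is.na(rep_2$assignment)), 4L)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(63)
  x <- rbind(matrix(rnorm(120, -2, 0.3), 30, 4),
             matrix(rnorm(120, 2, 0.3), 30, 4))
  fc <- fuzzy_cmeans(x, c = 2, m = 2, seed = 150)
  cm <- e1071::cmeans(x, centers = 2, m = 2)
  ours <- max.col(fc$membership)
  theirs <- cm$cluster
  expect_equal(adjusted_rand_index(ours, theirs), 1)
})
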