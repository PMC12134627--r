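test_that("hard filter fails only on present keys violating thresholds", {
  info <- data.frame(
    QD = c(12, 9.9, NA, 25, 25),
    MQ = c(50, 50, NA, 39, 50),
    FS = c(10, 10, NA, 5, 70),
    MQRankSum = c(0, 0, NA, 0, 0),
    ReadPosRankSum = c(0, 0, NA, 0, 0))
  res <- info_hard_filter(info, filter_config())
  expect_identical(res$pass, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(res$failing_keys[[2L]], "QD")
  expect_identical(res$failing_keys[[4L]], "MQ")
  expect_identical(res$failing_keys[[5L]], "FS")
  # boundary: QD exactly at the threshold fails (pass requires > 10)
  expect_false(info_hard_filter(data.frame(QD = 10, MQ = NA, FS = NA,
                                           MQRankSum = NA,
                                           ReadPosRankSum = NA))$pass)
})

test_that("HWE exact p matches full enumeration for every table with n <= 10", {
  for (n in 1:10) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(hwe_exact_p(n_AA, n_Aa, n_aa),
                   oracle_hwe_p(n_AA, n_Aa, n_aa),
                   tolerance = 1e-12,
                   label = sprintf("(%d,%d,%d)", n_AA, n_Aa, n_aa))
    }
  }
  expect_identical(hwe_exact_p(5, 0, 0), 1)   # monomorphic
})

test_that("thinning keeps the first site of a close pair, greedily", {
  expect_identical(thin_by_distance(c(100L, 104L, 111L), 5L),
                   c(TRUE, FALSE, TRUE))
  expect_identical(thin_by_distance(100L, 1000L), TRUE)
  # thin = 0 keeps everything except duplicate positions
  expect_identical(thin_by_distance(c(1L, 1L, 2L), 0L),
                   c(TRUE, FALSE, TRUE))
  expect_error(thin_by_distance(c(5L, 1L), 5L), "sorted")
})

test_that("the 8-record toy yields exactly 2 survivors with full attribution", {
  toy <- make_filter_toy()
  cfg <- filter_config(sample_call_rate_min = 0.5)
  res <- cohort_filter(toy, cfg, track = "snp")
  expect_identical(res$gs$pos, c(1000L, 2000L))
  expect_identical(res$n_kept, 2L)
  rep <- setNames(res$report$removed, res$report$criterion)
  expect_identical(rep[["info_hard_filter"]], 1L)
  expect_identical(rep[["not_biallelic_track"]], 1L)
  expect_identical(rep[["site_call_rate"]], 1L)
  expect_identical(rep[["maf"]], 1L)
  expect_identical(rep[["hwe"]], 1L)
  expect_identical(rep[["thinning"]], 1L)
  # removals sum exactly to input - output
  expect_identical(sum(res$report$removed), res$n_input - res$n_kept)
})

test_that("cohort_filter is idempotent and maf_min = 0 drops only invariants", {
  toy <- make_filter_toy()
  cfg <- filter_config(sample_call_rate_min = 0.5)
  once <- cohort_filter(toy, cfg, track = "snp")
  twice <- cohort_filter(once$gs, cfg, track = "snp")
  expect_identical(twice$gs$pos, once$gs$pos)
  expect_identical(sum(twice$report$removed), 0L)

  cfg0 <- filter_config(sample_call_rate_min = 0.5, maf_min = 0,
                        site_call_rate_min = 0, hwe_p_min = 0,
                        thin_bp = 0L)
  res0 <- cohort_filter(toy, cfg0, track = "snp")
  rep0 <- setNames(res0$report$removed, res0$report$criterion)
  expect_identical(rep0[["maf"]], 1L)  # only the invariant site
})
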