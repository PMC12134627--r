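test_that("hypergeometric p matches combinatorial arithmetic and enumeration", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(T1 = universe[1:5])
  res <- hypergeom_enrich(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-9)
  expect_equal(res$p, 6.449948e-5, tolerance = 1e-6)
  # exhaustive oracle for all (k, K, n) at M <= 15
  for (M in c(8, 15)) {
    uni <- sprintf("u%02d", 1:M)
    for (K in c(2, 5)) for (n in c(3, 6))
      for (k in max(0, n - (M - K)):min(K, n)) {
      query <- c(uni[seq_len(k)],
                 if (n > k) uni[K + seq_len(n - k)])
      sets2 <- list(S = uni[seq_len(K)])
      got <- hypergeom_enrich(query, sets2, uni)
      expect_equal(got$p, oracle_hyper_p(k, K, M, n), tolerance = 1e-12,
                   label = sprintf("M=%d K=%d n=%d k=%d", M, K, n, k))
    }
  }
})

test_that("degenerate enrichment cases behave as documented", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(T1 = universe[1:5], empty = character(0))
  # k = 0: upper tail sums everything -> 1
  res0 <- hypergeom_enrich(universe[6:10], sets, universe)
  expect_equal(res0$p[res0$term == "T1"], 1)
  # query = universe: saturation, p = 1 for every term
  resu <- hypergeom_enrich(universe, sets, universe)
  expect_true(all(resu$p == 1))
  # terms with no genes in the universe are skipped
  expect_false("empty" %in% res0$term)
  expect_error(hypergeom_enrich("g01", sets, character(0)), "universe")
  expect_warning(hypergeom_enrich(c("g01", "zz"), sets, universe),
                 "dropped")
})

test_that("the report is sorted by p with ties broken by count", {
  universe <- sprintf("g%02d", 1:30)
  sets <- list(A = universe[1:10], B = universe[1:3], C = universe[25:30])
  res <- hypergeom_enrich(universe[1:6], sets, universe)
  expect_identical(res$p, sort(res$p))
  rep_ <- enrich_report(res, top_n = 2)
  expect_identical(nrow(rep_), 2L)
  expect_identical(names(rep_), c("term", "count", "p", "padj"))
  expect_identical(nrow(enrich_report(res, 0)), 0L)
  # stable under permutation of the input sets
  res_perm <- hypergeom_enrich(universe[1:6], sets[c(3, 1, 2)], universe)
  expect_identical(res$term, res_perm$term)
})
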