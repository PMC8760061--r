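# Gene-set overlap statistics.

test_that("overlap percentages and DEX tallies are plain bookkeeping", {
  expect_equal(overlap_percent(0, 227), 0)
  expect_equal(overlap_percent(39, 227), 100 * 39 / 227)
  expect_error(overlap_percent(5, 0), "positive")
  expect_error(overlap_percent(10, 5), "<= n")
  tally <- dex_tally(185, 78, generic = 180)
  expect_equal(tally$total, 263)
  expect_equal(tally$layer_enriched, 83)
  expect_error(dex_tally(5, 2, generic = 10), "generic")
})

test_that("binomial tail equals direct summation and handles edges", {
  # independent oracle: explicit term-by-term tail sum
  direct <- sum(dbinom(5:20, 20, 0.1))
  expect_equal(binomial_overlap_test(5, 20, 10, 100), direct, tolerance = 1e-12)
  expect_equal(binomial_overlap_test(0, 20, 10, 100), 1)
  expect_equal(binomial_overlap_test(20, 20, 100, 100), 1)
  expect_warning(p0 <- binomial_overlap_test(1, 5, 0, 100), "impossible")
  expect_equal(p0, 0)
})

test_that("hypergeometric tail equals exhaustive enumeration on a toy", {
  # N = 10, K = 4, n = 3: enumerate all C(10,3) draws
  sets <- combn(10, 3)
  in_K <- function(draw) sum(draw <= 4)
  counts <- apply(sets, 2, in_K)
  for (k in 0:3) {
    expect_equal(hypergeometric_overlap_test(k, 3, 4, 10),
                 mean(counts >= k), tolerance = 1e-12)
  }
  # sampling-without-replacement limit: matches binomial when n/N is small
  p_h <- hypergeometric_overlap_test(10, 50, 1000, 10000)
  p_b <- binomial_overlap_test(10, 50, 1000, 10000)
  expect_lt(abs(p_h - p_b), 0.02)
})

test_that("the resampling null reproduces the hypergeometric model", {
  u <- sprintf("G%03d", 1:100)
  set <- gene_set("disease", u[1:10])
  rs <- resampling_null(5, 20, set, u, R = 1000, seed = 83)
  expect_gte(rs$p_permutation, 1 / 1001)
  expect_lte(rs$p_permutation, 1)
  # null mean overlap ~ n*K/N within 3 SE
  se <- sd(rs$null_overlaps) / sqrt(rs$R)
  expect_lt(abs(mean(rs$null_overlaps) - 20 * 10 / 100), 3 * se)
  # permutation p within 2 MC SE of the hypergeometric tail
  p_h <- hypergeometric_overlap_test(5, 20, 10, 100)
  se_p <- sqrt(p_h * (1 - p_h) / rs$R)
  expect_lt(abs(rs$p_permutation - p_h), 2 * se_p + 1 / rs$R)
  expect_error(resampling_null(5, 20, set, u, R = 0), "R must")
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.2, 0.03, 0.5)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrich_report reproduces counts and is label-order invariant", {
  u <- sprintf("G%03d", 1:200)
  dex <- gene_set("dex", u[1:40])
  sets <- list(gene_set("s1", u[21:60]), gene_set("s2", c(u[150:190], "XXX")))
  rep1 <- enrich_report(dex, sets, u, R = 200, seed = 89)
  expect_equal(rep1$k, c(20L, 0L))
  expect_equal(rep1$n, c(40L, 40L))
  expect_equal(rep1$K, c(40L, 41L))
  expect_equal(rep1$N, c(200L, 200L))
  expect_equal(rep1$out_of_universe, c(0L, 1L))
  expect_equal(rep1$percent_reported, round(100 * rep1$k / rep1$n, 1))
  expect_equal(rep1$q_bh, bh_adjust(rep1$p_binomial))
  # case and order of identifiers must not matter
  rep2 <- enrich_report(gene_set("dex", rev(tolower(u[1:40]))), sets, u,
                        R = 200, seed = 89)
  expect_equal(rep1$k, rep2$k)
  expect_equal(rep1$p_binomial, rep2$p_binomial)
  expect_error(enrich_report(gene_set("dex", "ZZZ"), sets, u), "no genes")
})

test_that("null and planted-enrichment operating characteristics hold", {
  run_q <- function(fold, seed) {
    g <- gen_gene_universe(enrichment_sim_config(2000, 200, 100, fold = fold,
                                                 seed = seed))
    enrich_report(g$dex_set, list(g$disease_set), g$universe,
                  R = 200, seed = seed)$q_bh
  }
  q_null <- vapply(1:100, function(s) run_q(1, s), numeric(1))
  expect_gte(mean(q_null > 0.05), 0.9)
  q_alt <- vapply(1:100, function(s) run_q(3, 1000 + s), numeric(1))
  expect_gte(mean(q_alt < 0.05), 0.9)
})
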