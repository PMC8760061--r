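# Synthetic-data generators: determinism, planted effects, configuration
# validation.

test_that("gen_columns is a pure function of its config", {
  cfg <- column_sim_config(seed = 11)
  expect_identical(gen_columns(cfg), gen_columns(cfg))
  cfg2 <- column_sim_config(seed = 12)
  expect_false(identical(gen_columns(cfg), gen_columns(cfg2)))
})

test_that("gen_columns respects the exchangeable null and planted shifts", {
  # no genotype shift, no hierarchy: genotype mean depths agree closely
  cfg0 <- column_sim_config(
    genotype_shifts = c(WT = 0, KO = 0),
    n_animals_per_genotype = 2, slices_per_animal = 2,
    cells_per_slice = 2000, animal_sd = 0, slice_sd = 0, seed = 21
  )
  cells <- gen_columns(cfg0)
  mu <- tapply(cells$depth_fraction, cells$genotype, mean)
  expect_lt(abs(mu[["KO"]] - mu[["WT"]]), 0.01)

  # single layer at 0.5 with a +0.05 KO shift: the mean-depth difference
  # recovers the planted shift (law of large numbers at 1e4 cells/genotype)
  cfg1 <- column_sim_config(
    layers = list(layer_spec("L", 0.5, 0.05, 1)),
    genotype_shifts = c(WT = 0, KO = 0.05),
    n_animals_per_genotype = 1, slices_per_animal = 1,
    cells_per_slice = 10000, animal_sd = 0, slice_sd = 0, seed = 22
  )
  cells1 <- gen_columns(cfg1)
  mu1 <- tapply(cells1$depth_fraction, cells1$genotype, mean)
  expect_gte(mu1[["KO"]] - mu1[["WT"]], 0.045)
  expect_lte(mu1[["KO"]] - mu1[["WT"]], 0.055)

  expect_true(all(cells$depth_fraction >= 0 & cells$depth_fraction <= 1))
  expect_setequal(unique(cells$genotype), c("WT", "KO"))
})

test_that("invalid column configs are rejected", {
  expect_error(
    column_sim_config(layers = list(layer_spec("a", 0.4, 0.1, 0.6),
                                    layer_spec("b", 0.6, 0.1, 0.6))),
    "sum to 1"
  )
  expect_error(layer_spec("a", 1.5, 0.1, 1), "depth_center")
  expect_error(layer_spec("a", 0.5, 0, 1), "depth_sd")
  expect_error(column_sim_config(genotype_shifts = c(0, 0.1)), "named")
  expect_error(column_sim_config(cells_per_slice = 0), "counts")
})

test_that("gen_gene_universe plants the requested expected overlap", {
  overlap_of <- function(cfg) {
    g <- gen_gene_universe(cfg)
    length(intersect(g$dex_set$members, g$disease_set$members))
  }
  # fold = 1: mean overlap over 200 seeds within 3 MC SE of n*K/N
  N <- 1000; K <- 100; n <- 50
  ov <- vapply(1:200, function(s) {
    overlap_of(enrichment_sim_config(N, K, n, fold = 1, seed = s))
  }, numeric(1))
  se <- sd(ov) / sqrt(length(ov))
  expect_lt(abs(mean(ov) - n * K / N), 3 * se)

  # fold = 0: overlap always zero
  ov0 <- vapply(1:25, function(s) {
    overlap_of(enrichment_sim_config(N, K, n, fold = 0, seed = s))
  }, numeric(1))
  expect_true(all(ov0 == 0))

  # fold = 2.5 on the N=100, K=10, n=20 toy: mean overlap ~ 5
  ov25 <- vapply(1:200, function(s) {
    overlap_of(enrichment_sim_config(100, 10, 20, fold = 2.5, seed = s))
  }, numeric(1))
  se25 <- sd(ov25) / sqrt(length(ov25))
  expect_lt(abs(mean(ov25) - 5), 3 * se25)

  expect_error(enrichment_sim_config(100, 50, 20, fold = 3), "fold")
})

test_that("gen_expression hits the target within-module correlation", {
  cfg <- expression_sim_config(n_genes = 30, n_samples = 50,
                               module_assignment = c(rep(1L, 10),
                                                     rep(NA_integer_, 20)),
                               within_module_r = 0.9, seed = 31)
  x <- gen_expression(cfg)
  expect_true(all(x >= 0))
  expect_identical(x, gen_expression(cfg))
  L <- log2(x + 1)
  r <- cor(t(L[1:10, ]))
  mean_r <- mean(r[upper.tri(r)])
  expect_gte(mean_r, 0.8)
  expect_lte(mean_r, 0.97)

  # null: no module structure leaves correlations near zero at 100 samples
  cfg0 <- expression_sim_config(n_genes = 20, n_samples = 100,
                                module_assignment = rep(NA_integer_, 20),
                                within_module_r = 0, seed = 32)
  L0 <- log2(gen_expression(cfg0) + 1)
  r0 <- cor(t(L0))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.2)
})

test_that("gen_spines produces valid surveys with the planted difference", {
  s <- gen_spines(seed = 41)
  expect_s3_class(s, "spine_survey")
  expect_true(all(s$n_lost <= s$n_day0))
  expect_true(all(s$n_day0 >= 1))
  expect_identical(s, gen_spines(seed = 41))
  rates <- turnover_rates(s)
  mu <- tapply(rates$net_addition_pct, rates$genotype, mean)
  expect_gt(mu[["KO"]], mu[["WT"]])
})
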