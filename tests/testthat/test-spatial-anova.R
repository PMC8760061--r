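# Two-way factorial ANOVA and the spatially adjusted pipeline.

test_that("type-II F statistics match an independent least-squares oracle", {
  # unbalanced 2 x 3 toy so that type-II adjustment matters
  set.seed(47)
  g <- factor(rep(c("A", "B"), times = c(8, 10)))
  b <- factor(c(rep(1:3, length.out = 8), rep(1:3, length.out = 10)))
  y <- rnorm(18) + as.numeric(b) + 0.5 * (g == "B") * (b == "2")
  ours <- two_way_anova(y, g, b)
  oracle <- car::Anova(lm(y ~ g * b), type = 2)
  expect_equal(ours$table$sum_sq, oracle[["Sum Sq"]][1:3], tolerance = 1e-10)
  expect_equal(ours$table$F, oracle[["F value"]][1:3], tolerance = 1e-10)
  expect_equal(ours$table$p, oracle[["Pr(>F)"]][1:3], tolerance = 1e-10)
  expect_equal(ours$df_res, oracle[["Df"]][4])
  # residuals reproduce the lm fit
  expect_equal(ours$residuals, unname(residuals(lm(y ~ g * b))), tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  g <- factor(rep(c("A", "B"), each = 6))
  b <- factor(rep(1:3, 4))
  expect_error(two_way_anova(rep(1, 12), g, b), "residual variance is zero")
  # empty cell named
  b2 <- b
  b2[g == "B" & b == "3"] <- "1"
  expect_error(two_way_anova(rnorm(12), g, droplevels(b2)), "empty cell")
  expect_error(two_way_anova(rnorm(12), factor(rep("A", 12)), b), "two levels")
})

test_that("a pure bin effect does not masquerade as a genotype effect", {
  set.seed(53)
  g <- factor(rep(c("WT", "KO"), each = 24))
  b <- factor(rep(rep(1:6, each = 4), 2))
  hits <- vapply(1:100, function(i) {
    y <- as.numeric(b) * 2 + rnorm(48)
    two_way_anova(y, g, b)$table$p[1] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("adjusted_anova reduces to the classical ANOVA when gates pass", {
  # Gaussian, spatially uncorrelated profiles (not compositional): both
  # gates should pass and the F table must equal the plain two-way ANOVA.
  set.seed(59)
  S <- 12; B <- 8
  profiles <- data.frame(
    slice_id = sprintf("s%02d", 1:S),
    genotype = rep(c("WT", "KO"), each = S / 2),
    stringsAsFactors = FALSE
  )
  bins <- matrix(rnorm(S * B, mean = rep(10 + seq_len(B), each = S)), S, B)
  colnames(bins) <- sprintf("bin_%02d", 1:B)
  profiles <- cbind(profiles, bins, n_cells = 100L)
  class(profiles) <- c("bin_profile_table", "data.frame")

  res <- adjusted_anova(profiles, n_perm = 199, moran_n_perm = 199, seed = 61)
  expect_gte(res$gates$shapiro_p, 0.05)
  expect_gte(res$gates$moran_p, 0.05)
  expect_identical(res$branch, "classical")
  expect_false(res$compositional)
  expect_true(is.na(res$rho))

  y <- as.vector(t(bins))
  ref <- two_way_anova(y, rep(profiles$genotype, each = B),
                       rep(seq_len(B), S))
  expect_equal(res$table$F, ref$table$F, tolerance = 1e-10)
  expect_equal(res$table$p, ref$table$p, tolerance = 1e-10)
  expect_true(all(is.na(res$table$p_permutation)))
})

test_that("adjusted_anova output is reproducible and well-formed", {
  cells <- gen_columns(column_sim_config(seed = 67))
  pr <- bin_profiles(cells)
  r1 <- adjusted_anova(pr, n_perm = 199, moran_n_perm = 99, seed = 5)
  r2 <- adjusted_anova(pr, n_perm = 199, moran_n_perm = 99, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$posthoc, r2$posthoc)
  expect_identical(r1$branch, r2$branch)
  expect_true(r1$compositional)
  # compositional df correction: (B-1)(S-G) instead of B(S-G)
  S <- nrow(pr); G <- 2L; B <- 20L
  expect_equal(r1$df_res, (B - 1L) * (S - G))
  # Bonferroni post hoc is min(1, raw * B)
  expect_equal(r1$posthoc$p_bonferroni, pmin(1, r1$posthoc$p_raw * 20))
  # gates are always reported
  expect_true(is.finite(r1$gates$shapiro_p))
  expect_true(is.finite(r1$gates$levene_p))
  expect_true(is.finite(r1$gates$moran_p))
})

test_that("the planted superficial shift is detected and localized", {
  cells <- gen_columns(calibration_config(delta = 0.05, seed = 71))
  res <- adjusted_anova(bin_profiles(cells), n_perm = 499, moran_n_perm = 99,
                        seed = 7)
  expect_lt(res$table$p[res$table$term == "interaction"], 0.05)
  # at least one bin contrast survives Bonferroni
  expect_true(any(res$posthoc$p_bonferroni < 0.05))
  # mean laminar position recovers the planted shift (~100 * delta)
  mu <- tapply(cells$depth_fraction, cells$genotype, mean) * 100
  expect_gt(mu[["KO"]] - mu[["WT"]], 3)
  expect_lt(mu[["KO"]] - mu[["WT"]], 7)
})

test_that("spatially autocorrelated profiles trigger the lag filter", {
  # build profiles whose within-slice noise is a smooth (AR) process along
  # bins, so Moran's I on residuals must fire and rho must be positive
  set.seed(73)
  S <- 20; B <- 20
  bins <- t(vapply(seq_len(S), function(s) {
    10 + as.numeric(stats::filter(rnorm(B), 0.7, method = "recursive"))
  }, numeric(B)))
  colnames(bins) <- sprintf("bin_%02d", 1:B)
  profiles <- cbind(
    data.frame(slice_id = sprintf("s%02d", 1:S),
               genotype = rep(c("WT", "KO"), each = S / 2),
               stringsAsFactors = FALSE),
    bins, n_cells = 100L
  )
  res <- adjusted_anova(profiles, n_perm = 199, moran_n_perm = 199, seed = 11)
  expect_lt(res$gates$moran_p, 0.05)
  expect_match(res$branch, "spatial_filtered")
  expect_gt(res$rho, 0.2)
})

test_that("input contracts on profiles are enforced", {
  cells <- gen_columns(column_sim_config(seed = 79,
                                         n_animals_per_genotype = 1,
                                         slices_per_animal = 1))
  expect_error(adjusted_anova(bin_profiles(cells)), "2 slices")
  expect_error(adjusted_anova(data.frame(genotype = "WT")), "bin_XX")
})
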