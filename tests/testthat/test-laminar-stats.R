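# Laminar descriptive statistics and the median permutation test.

test_that("normalize_depths rescales and validates raw coordinates", {
  raw <- data.frame(cell_id = c("c1", "c2", "c3"),
                    y_um = c(500, 0, 1000), column_height_um = 1000,
                    slice_id = "s1", animal_id = "a1", genotype = "WT")
  out <- normalize_depths(raw)
  expect_equal(out$depth_fraction, c(0.5, 0, 1))
  raw$y_um[2] <- 1001
  expect_error(normalize_depths(raw), "c2")
  expect_error(normalize_depths(transform(raw, column_height_um = 0)), "> 0")
})

test_that("bin_profile bins half-open, ventral to pial", {
  mk <- function(d) data.frame(cell_id = sprintf("c%d", seq_along(d)),
                               depth_fraction = d, slice_id = "s",
                               animal_id = "a", genotype = "WT")
  # one cell per bin
  even <- bin_profile(mk((seq_len(20) - 0.5) / 20))
  expect_equal(even$percentages, rep(5, 20))
  # everything superficial
  top <- bin_profile(mk(rep(0.99, 7)))
  expect_equal(top$percentages[20], 100)
  expect_equal(sum(top$percentages), 100)
  # hand binning: 0.04 -> bin 1, 0.12 -> bin 3, 0.93 -> bin 19
  three <- bin_profile(mk(c(0.04, 0.12, 0.93)))
  expect_equal(which(three$percentages > 0), c(1L, 3L, 19L))
  expect_equal(three$percentages[c(1, 3, 19)], rep(100 / 3, 3))
  # boundary: depth 1.0 joins the pial bin, not a 21st
  expect_equal(which(bin_profile(mk(c(1, 1)))$percentages > 0), 20L)
  # empty slice errors rather than returning a zero profile
  expect_error(bin_profile(toy_cells(), slice_id = "nope"), "no cells")
})

test_that("bin_profiles collects one row per slice and round-trips sums", {
  pr <- bin_profiles(toy_cells())
  expect_equal(nrow(pr), 4L)
  bins <- as.matrix(pr[, grep("^bin_", names(pr))])
  expect_equal(unname(rowSums(bins)), rep(100, 4))
  expect_equal(pr$n_cells, rep(10L, 4))
})

test_that("mean laminar position is the depth mean in percent", {
  expect_equal(mean_laminar_position(0.5), 50)
  expect_equal(mean_laminar_position(c(0.2, 0.4, 0.6)), 40)
  u <- withr::with_seed(5, runif(1e5))
  expect_lt(abs(mean_laminar_position(u) - 50), 0.5)
  expect_error(mean_laminar_position(numeric(0)), "undefined")
})

test_that("median permutation test: exact enumeration and invariants", {
  same <- median_position_test(c(0.2, 0.5, 0.7), c(0.2, 0.5, 0.7), n_perm = 50)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # A = {0,0}, B = {1,1}: 6 assignments, 2 are as extreme
  ex <- median_position_test(c(0, 0), c(1, 1), n_perm = 10)
  expect_true(ex$exhaustive)
  expect_equal(ex$p_value, 2 / 6)
  # seeded random branch is reproducible and respects the p floor
  a <- rnorm(30, 0.4, 0.1); b <- rnorm(30, 0.5, 0.1)
  r1 <- median_position_test(a, b, n_perm = 300, seed = 9)
  r2 <- median_position_test(a, b, n_perm = 300, seed = 9)
  expect_false(r1$exhaustive)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 301)
  # contract note for very small n_perm
  small <- median_position_test(c(0, 0), c(1, 1), n_perm = 50)
  expect_match(small$note, "resolution")
  expect_error(median_position_test(numeric(0), c(1)), "nonempty")
})

test_that("median permutation test equals a brute-force oracle when feasible", {
  for (s in 1:5) {
    set.seed(s)
    a <- round(runif(3), 2)
    b <- round(runif(4), 2)
    res <- median_position_test(a, b, n_perm = 5000)
    expect_true(res$exhaustive)
    pooled <- c(a, b)
    idx <- combn(7, 3)
    obs <- abs(median(a) - median(b))
    stats_all <- apply(idx, 2, function(i) {
      abs(median(pooled[i]) - median(pooled[-i]))
    })
    expect_equal(res$p_value, mean(stats_all >= obs - 1e-12))
  }
})

test_that("depth density integrates to one and finds the mode", {
  set.seed(7)
  x <- pmin(pmax(rnorm(1e4, 0.5, 0.1), 0), 1)
  d <- depth_density(x)
  expect_true(all(d$density >= 0))
  integral <- laminapipe:::trapezoid(d$grid, d$density)
  expect_gte(integral, 0.99)
  expect_lte(integral, 1.01)
  expect_gte(d$argmax, 0.45)
  expect_lte(d$argmax, 0.55)
  # symmetry about 0.5 for a symmetric sample
  xs <- c(x, 1 - x)
  ds <- depth_density(xs)
  expect_lt(max(abs(ds$density - rev(ds$density))), 1e-6)
  # boundary-heavy data still conserve mass (the reflection's purpose)
  xb <- pmin(pmax(abs(rnorm(5e3, 0, 0.06)), 0), 1)
  db <- depth_density(xb)
  expect_gte(laminapipe:::trapezoid(db$grid, db$density), 0.99)
  expect_error(depth_density(rep(0.4, 10)), "bin_profile")
})

test_that("depth ECDF counts at-or-below fractions", {
  expect_equal(depth_ecdf(c(0.2, 0.4, 0.6), x = 0.5), 2 / 3)
  expect_equal(depth_ecdf(c(0.2, 0.4, 0.6), x = 0.7), 1)
  expect_equal(depth_ecdf(c(0.2, 0.4, 0.6), x = 0.1), 0)
  f <- depth_ecdf(toy_cells())
  expect_s3_class(f, "ecdf")
})

test_that("density and ECDF agree as distribution summaries", {
  set.seed(11)
  x <- pmin(pmax(c(rnorm(5e3, 0.35, 0.08), rnorm(5e3, 0.6, 0.1)), 0), 1)
  d <- depth_density(x)
  cdf_from_density <- cumsum(c(0, diff(d$grid) *
                                 (d$density[-1] + d$density[-length(d$density)]) / 2))
  ecdf_vals <- depth_ecdf(x, x = d$grid)
  expect_lt(max(abs(cdf_from_density - ecdf_vals)), 0.02)
})
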