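# Repeated-simulation experiments: operating characteristics of the
# spatially adjusted ANOVA (type-I error and power against a planted
# laminar shift), spatial-lag parameter recovery, and the spine-turnover
# detection power.  These are the package's own parameter-recovery checks;
# each is a pure function of its seed.

#' Study conditions for the ANOVA calibration experiments
#'
#' The exchangeable-null / planted-shift configuration used by
#' [anova_rejection_rate()]: one dominant marker band over a diffuse
#' background, 150 cells per column, 5 animals x 5 slices per genotype and
#' no hierarchical intercepts, so that with `delta = 0` the slices are iid
#' and the data satisfy the null of the factorial F test exactly.
#'
#' @param delta genotype shift (depth fraction, positive = toward pia)
#'   planted in the KO group.
#' @param seed integer seed.
#' @return a [column_sim_config()].
#' @export
calibration_config <- function(delta = 0, seed = 1L) {
  column_sim_config(
    layers = default_cortical_layers(),
    genotype_shifts = c(WT = 0, KO = delta),
    n_animals_per_genotype = 5,
    slices_per_animal = 5,
    cells_per_slice = 150,
    animal_sd = 0, slice_sd = 0,
    seed = seed
  )
}

#' Rejection rate of the adjusted ANOVA over repeated simulations
#'
#' Simulates `n_runs` independent datasets from [calibration_config()],
#' runs [adjusted_anova()] on each, and returns the fraction of runs in
#' which the selected p-value of `term` falls below `alpha`.  With
#' `delta = 0` this estimates the type-I error (target: the nominal
#' `alpha`); with a planted shift it estimates power.
#'
#' @param n_runs number of simulated datasets.
#' @param delta planted KO shift (0 for the null).
#' @param alpha test level.
#' @param term `"interaction"` (default), `"genotype"` or `"bin"`.
#' @param n_perm,moran_n_perm permutation sizes passed to
#'   [adjusted_anova()].
#' @param seed seed; run `i` uses `seed + i` for its data and analysis.
#' @return list with `rate`, `n_runs`, `rejections`, and the branch
#'   frequencies over the runs.
#' @export
anova_rejection_rate <- function(n_runs = 500L, delta = 0, alpha = 0.05,
                                 term = "interaction", n_perm = 499L,
                                 moran_n_perm = 199L, seed = 1L) {
  branches <- character(n_runs)
  reject <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    cells <- gen_columns(calibration_config(delta = delta, seed = seed + i))
    res <- adjusted_anova(bin_profiles(cells), n_perm = n_perm,
                          moran_n_perm = moran_n_perm, seed = seed + i)
    branches[i] <- res$branch
    reject[i] <- res$table$p[res$table$term == term] < alpha
  }
  list(rate = mean(reject), n_runs = n_runs, rejections = sum(reject),
       branches = table(branches))
}

#' Spatial-lag parameter recovery over repeated simulations
#'
#' Simulates `y = (I - rho W)^{-1}(X beta + eps)` on chain weights
#' (`n_slices` columns of `n_bins` bins) and refits by maximum likelihood,
#' returning the mean of the `rho` estimates.
#'
#' @param n_sims number of simulations.
#' @param rho true autocorrelation parameter.
#' @param n_bins,n_slices geometry of the stacked chains.
#' @param beta coefficients of the (intercept + 1 covariate) design.
#' @param sigma noise sd.
#' @param seed seed; simulation `i` uses `seed + i`.
#' @return list with `mean_rho`, `sd_rho`, and the estimates `rho_hat`.
#' @export
lag_recovery <- function(n_sims = 100L, rho = 0.6, n_bins = 20L,
                         n_slices = 20L, beta = c(1, 0.5), sigma = 1,
                         seed = 1L) {
  W <- chain_weights(n_bins, n_slices)
  n <- n_bins * n_slices
  rho_hat <- vapply(seq_len(n_sims), function(i) {
    X <- with_seed(seed + i, cbind(1, stats::rnorm(n)))
    y <- simulate_spatial_lag(rho, X, beta, W, sigma = sigma,
                              seed = seed + i + 100000L)
    fit_spatial_lag(y, X, W)$rho
  }, numeric(1))
  list(mean_rho = mean(rho_hat), sd_rho = stats::sd(rho_hat), rho_hat = rho_hat)
}

#' Power to detect a planted spine net-gain difference
#'
#' Simulates [gen_spines()] surveys with the given planted genotype
#' difference and counts how often [group_turnover()] detects the net
#' addition difference at `alpha`.
#'
#' @param n_sims number of simulated experiments.
#' @param net_gain_pct named per-genotype mean net addition rates.
#' @param n_animals named animals per genotype.
#' @param animal_sd_pct animal-level sd of the net rate.
#' @param alpha test level.
#' @param seed seed; simulation `i` uses `seed + i`.
#' @return list with `power`, `n_sims`, `detections`.
#' @export
turnover_power <- function(n_sims = 200L, net_gain_pct = c(WT = 0, KO = 6),
                           n_animals = c(WT = 8, KO = 6), animal_sd_pct = 2,
                           alpha = 0.05, seed = 1L) {
  detect <- vapply(seq_len(n_sims), function(i) {
    s <- gen_spines(n_animals = n_animals, net_gain_pct = net_gain_pct,
                    animal_sd_pct = animal_sd_pct, seed = seed + i)
    cmp <- group_turnover(s)$comparisons
    cmp$p_value[cmp$measure == "net_addition_pct"] < alpha
  }, logical(1))
  list(power = mean(detect), n_sims = n_sims, detections = sum(detect))
}
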