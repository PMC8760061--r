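# Two-way factorial ANOVA of stacked bin percentages and the spatially
# adjusted pipeline: assumption gates (Shapiro-Wilk, Levene), Moran's I on
# the residuals against chain-contiguity weights, spatial-lag filtering of
# the response when autocorrelation is detected, permutation F tests when
# residual normality fails, and Bonferroni per-bin post hoc contrasts.

# Design/projection bundle shared by the OLS fit and the permutation engine.
two_way_design <- function(genotype, bin) {
  genotype <- droplevels(as.factor(genotype))
  bin <- droplevels(as.factor(bin))
  if (nlevels(genotype) < 2L || nlevels(bin) < 2L) {
    stop("both factors need at least two levels")
  }
  cell <- table(genotype, bin)
  if (any(cell == 0L)) {
    empty <- which(cell == 0L, arr.ind = TRUE)[1L, ]
    stop("design has an empty cell: genotype '", rownames(cell)[empty[1]],
         "' x bin '", colnames(cell)[empty[2]], "'")
  }
  X_full <- stats::model.matrix(~ genotype * bin)
  list(
    genotype = genotype, bin = bin,
    G = nlevels(genotype), B = nlevels(bin), n = length(genotype),
    X_full = X_full,
    Q_full = qr.Q(qr(X_full)),
    Q_gb = qr.Q(qr(stats::model.matrix(~ genotype + bin))),
    Q_g = qr.Q(qr(stats::model.matrix(~ genotype))),
    Q_b = qr.Q(qr(stats::model.matrix(~ bin)))
  )
}

# Residual sums of squares of Y (vector or matrix of columns) under the
# projection Q; RSS = ||y||^2 - ||Q'y||^2.
rss_under <- function(Q, Y) {
  if (is.matrix(Y)) {
    colSums(Y^2) - colSums(crossprod(Q, Y)^2)
  } else {
    sum(Y^2) - sum(crossprod(Q, Y)^2)
  }
}

# Type-II F statistics for genotype, bin and their interaction.
anova_F_stats <- function(Y, d, df_res) {
  r_full <- rss_under(d$Q_full, Y)
  r_gb <- rss_under(d$Q_gb, Y)
  r_g <- rss_under(d$Q_g, Y)
  r_b <- rss_under(d$Q_b, Y)
  df <- c(genotype = d$G - 1L, bin = d$B - 1L,
          interaction = (d$G - 1L) * (d$B - 1L))
  ss <- rbind(genotype = r_b - r_gb, bin = r_g - r_gb, interaction = r_gb - r_full)
  ms_res <- r_full / df_res
  list(ss = ss, df = df, F = sweep(ss / df, 2L, ms_res, "/"), rss = r_full)
}

#' Two-way factorial ANOVA with type-II sums of squares
#'
#' Ordinary least-squares fit of `y ~ genotype * bin` with type-II sums of
#' squares (each main effect adjusted for the other, the interaction
#' adjusted for both), chosen because slice counts per genotype are
#' typically unbalanced.  Residuals are returned for the diagnostic gates
#' of [adjusted_anova()].
#'
#' @param y numeric response (stacked bin percentages).
#' @param genotype,bin factors of the same length as `y`.
#' @return an object of class `anova_result`: `table` (term, df, sum_sq,
#'   mean_sq, F, p), `residuals`, `fitted`, `df_res`.
#' @examples
#' cells <- gen_columns(column_sim_config(seed = 1))
#' pr <- bin_profiles(cells)
#' bins <- grep("^bin_", names(pr))
#' y <- as.vector(t(as.matrix(pr[, bins])))
#' two_way_anova(y, rep(pr$genotype, each = 20), rep(seq_len(20), nrow(pr)))
#' @export
two_way_anova <- function(y, genotype, bin) {
  d <- two_way_design(genotype, bin)
  if (length(y) != d$n) stop("y and the factors differ in length")
  df_res <- d$n - d$G * d$B
  if (df_res < 1L) stop("no residual degrees of freedom: need replicate slices")
  st <- anova_F_stats(y, d, df_res)
  if (st$rss <= .Machine$double.eps^0.75 * max(sum((y - mean(y))^2), 1)) {
    stop("residual variance is zero: F statistics are undefined")
  }
  tab <- data.frame(
    term = names(st$df),
    df = as.integer(st$df),
    sum_sq = as.numeric(st$ss),
    mean_sq = as.numeric(st$ss) / st$df,
    F = as.numeric(st$F),
    p = stats::pf(as.numeric(st$F), st$df, df_res, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  fitted <- as.numeric(d$Q_full %*% crossprod(d$Q_full, y))
  structure(
    list(table = tab, residuals = y - fitted, fitted = fitted,
         df_res = df_res, design = d),
    class = "anova_result"
  )
}

profiles_to_frame <- function(profiles) {
  if (inherits(profiles, "bin_profile")) profiles <- list(profiles)
  if (is.list(profiles) && !is.data.frame(profiles) &&
      all(vapply(profiles, inherits, logical(1), "bin_profile"))) {
    n_bins <- length(profiles[[1]]$percentages)
    rows <- lapply(profiles, function(p) {
      row <- as.data.frame(as.list(p$percentages))
      names(row) <- sprintf("bin_%02d", seq_len(n_bins))
      cbind(data.frame(slice_id = p$slice_id, genotype = p$genotype,
                       stringsAsFactors = FALSE),
            row, n_cells = p$n_cells)
    })
    profiles <- do.call(rbind, rows)
  }
  if (!is.data.frame(profiles)) {
    stop("profiles must be a bin_profile_table data frame or a list of bin_profile")
  }
  profiles
}

# Safe per-bin two-group contrast; constant identical groups give p = 1.
bin_contrast_p <- function(values, groups, method) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) > 2L) {
    return(tryCatch(stats::oneway.test(values ~ g)$p.value, error = function(e) 1))
  }
  a <- values[g == levels(g)[1]]
  b <- values[g == levels(g)[2]]
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  p <- tryCatch(
    if (method == "t") stats::t.test(a, b)$p.value
    else stats::wilcox.test(a, b, exact = FALSE)$p.value,
    error = function(e) NA_real_
  )
  if (is.na(p)) 1 else p
}

#' Spatially adjusted two-way ANOVA of laminar bin profiles
#'
#' Tests genotype, bin and genotype-by-bin effects on per-slice bin
#' percentages while honouring the two-way ANOVA assumptions:
#'
#' 1. stack the profiles into a response with crossed `genotype` and `bin`
#'    factors (one replicate slice per profile) and fit the OLS factorial
#'    model with type-II sums of squares;
#' 2. gate the assumptions — Shapiro-Wilk on the residuals (normality),
#'    Levene/Brown-Forsythe across genotype-by-bin cells
#'    (homoscedasticity), and Moran's I of the residuals against
#'    chain-contiguity weights (independence of adjacent bins);
#' 3. if Moran's I is significant at `alpha_gate`, estimate the spatial lag
#'    parameter `rho` by maximum likelihood and re-analyze the filtered
#'    response `y - rho W y`, from which the autocorrelation has been
#'    removed;
#' 4. if residual normality fails at `alpha_gate`, replace the parametric F
#'    p-values with permutation p-values (`n_perm` draws, `+1` corrected)
#'    using the F statistics as test statistics.  The permutations respect
#'    the replicate hierarchy: for the genotype and interaction terms whole
#'    slice profiles are reassigned across genotypes (slices are the
#'    exchangeable unit, so the reference distribution is exact even when
#'    per-bin variances are heterogeneous, as they are for percentage
#'    profiles); for the bin term, bins are shuffled within each slice;
#' 5. per-bin genotype contrasts (Welch t or Wilcoxon) on the analyzed
#'    response, Bonferroni-corrected by the number of bins.
#'
#' Because each slice's percentages sum to exactly 100, the residual vector
#' of every slice loses one free dimension; the residual degrees of freedom
#' are reduced accordingly (`(B-1)(S-G)` instead of `B(S-G)`) whenever the
#' profiles are detected to be compositional, which keeps the parametric F
#' test calibrated.
#'
#' @param profiles a `bin_profile_table` (see [bin_profiles()]) or list of
#'   [bin_profile()] objects; at least 2 genotypes with 2 slices each.
#' @param alpha_gate significance level of the assumption gates.
#' @param n_perm permutations for the F test branch.
#' @param moran_n_perm permutations for the Moran gate.
#' @param seed optional seed controlling both permutation streams.
#' @param posthoc_method `"t"` (Welch) or `"wilcox"` per-bin contrasts.
#' @return an object of class `adjusted_anova_result`: gate p-values
#'   (`shapiro_p`, `levene_p`, `moran_p`, and the Moran `I`), the `branch`
#'   taken (`classical`, `permutation`, `spatial_filtered`, or
#'   `spatial_filtered_permutation`), the F `table` with parametric and (if
#'   run) permutation p-values plus the branch-selected `p`, `rho` (NA
#'   unless filtered), the Bonferroni `posthoc` table, and bookkeeping
#'   (`n_perm`, `seed`, `compositional`, `df_res`).
#' @examples
#' cells <- gen_columns(column_sim_config(seed = 7))
#' res <- adjusted_anova(bin_profiles(cells), n_perm = 199, moran_n_perm = 99,
#'                       seed = 1)
#' res$branch
#' @export
adjusted_anova <- function(profiles, alpha_gate = 0.05, n_perm = 5000L,
                           moran_n_perm = 999L, seed = NULL,
                           posthoc_method = c("t", "wilcox")) {
  posthoc_method <- match.arg(posthoc_method)
  profiles <- profiles_to_frame(profiles)
  bin_cols <- grep("^bin_\\d+$", names(profiles), value = TRUE)
  if (length(bin_cols) < 2L) stop("profiles contain no bin_XX columns")
  B <- length(bin_cols)
  S <- nrow(profiles)
  gt <- as.factor(profiles$genotype)
  if (nlevels(droplevels(gt)) < 2L || any(table(gt) < 2L)) {
    stop("need at least 2 genotypes with at least 2 slices each")
  }
  G <- nlevels(droplevels(gt))
  P <- as.matrix(profiles[, bin_cols])
  y <- as.vector(t(P))  # slice-major: bins ventral-to-pial within each slice
  genotype_f <- rep(gt, each = B)
  bin_f <- factor(rep(seq_len(B), S))
  d <- two_way_design(genotype_f, bin_f)

  compositional <- max(abs(rowSums(P) - mean(rowSums(P)))) < 1e-6
  df_res <- d$n - d$G * d$B
  if (compositional) df_res <- df_res - (S - G)

  ols <- anova_F_stats(y, d, df_res)
  e <- y - as.numeric(d$Q_full %*% crossprod(d$Q_full, y))

  shapiro_e <- if (length(e) > 5000) {
    with_seed(if (is.null(seed)) NULL else seed + 10L, sample(e, 5000L))
  } else e
  shapiro_p <- stats::shapiro.test(shapiro_e)$p.value
  lev <- car::leveneTest(y, group = interaction(genotype_f, bin_f), center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1L]
  W <- chain_weights(B, S)
  moran <- morans_i(e, W, n_perm = moran_n_perm,
                    seed = if (is.null(seed)) NULL else seed + 1L,
                    alternative = "greater")

  spatial <- moran$p_value < alpha_gate
  rho <- NA_real_
  lag_fit <- NULL
  y_f <- y
  if (spatial) {
    lag_fit <- fit_spatial_lag(y, d$X_full, W)
    rho <- lag_fit$rho
    y_f <- lag_fit$y_filtered
  }
  st <- if (spatial) anova_F_stats(y_f, d, df_res) else ols

  permute <- shapiro_p < alpha_gate
  p_param <- stats::pf(as.numeric(st$F), st$df, df_res, lower.tail = FALSE)
  p_perm <- rep(NA_real_, 3L)
  if (permute) {
    obs_F <- as.numeric(st$F)
    tol <- 1e-12
    bin_offsets <- (seq_len(S) - 1L) * B
    # Restricted permutations respecting the slice hierarchy: genotype and
    # interaction nulls reassign whole slice profiles across genotypes
    # (exact under exchangeability of slices, robust to per-bin variance
    # heterogeneity); the bin null shuffles bins within each slice.
    perm_idx <- with_seed(if (is.null(seed)) NULL else seed + 2L, {
      idx_slice <- vapply(seq_len(n_perm), function(...) {
        as.integer(outer(seq_len(B), bin_offsets[sample.int(S)], "+"))
      }, integer(d$n))
      idx_bin <- vapply(seq_len(n_perm), function(...) {
        as.integer(vapply(bin_offsets, function(o) o + sample.int(B),
                          integer(B)))
      }, integer(d$n))
      list(slice = idx_slice, bin = idx_bin)
    })
    F_slice <- anova_F_stats(matrix(y_f[perm_idx$slice], d$n, n_perm), d, df_res)$F
    F_bin <- anova_F_stats(matrix(y_f[perm_idx$bin], d$n, n_perm), d, df_res)$F
    null_F <- rbind(genotype = F_slice["genotype", ],
                    bin = F_bin["bin", ],
                    interaction = F_slice["interaction", ])
    p_perm <- vapply(seq_len(3L), function(i) {
      (1 + sum(null_F[i, ] >= obs_F[i] - tol)) / (n_perm + 1)
    }, numeric(1))
  }
  branch <- paste0(if (spatial) "spatial_filtered" else "",
                   if (spatial && permute) "_" else "",
                   if (permute) "permutation" else "")
  if (branch == "") branch <- "classical"

  tab <- data.frame(
    term = names(st$df),
    df = as.integer(st$df),
    sum_sq = as.numeric(st$ss),
    F = as.numeric(st$F),
    p_parametric = p_param,
    p_permutation = p_perm,
    p = if (permute) p_perm else p_param,
    stringsAsFactors = FALSE
  )

  Yf <- matrix(y_f, nrow = B)  # bins x slices
  p_raw <- vapply(seq_len(B), function(b) {
    bin_contrast_p(Yf[b, ], gt, posthoc_method)
  }, numeric(1))
  posthoc <- data.frame(
    bin = seq_len(B),
    p_raw = p_raw,
    p_bonferroni = pmin(1, p_raw * B)
  )

  structure(
    list(gates = list(shapiro_p = shapiro_p, levene_p = levene_p,
                      moran_p = moran$p_value, moran_I = moran$I),
         branch = branch, table = tab, rho = rho, lag_fit = lag_fit,
         posthoc = posthoc, n_perm = if (permute) n_perm else NA_integer_,
         moran_n_perm = moran_n_perm, seed = seed, alpha_gate = alpha_gate,
         compositional = compositional, df_res = df_res,
         n_bins = B, n_slices = S, n_genotypes = G),
    class = "adjusted_anova_result"
  )
}
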