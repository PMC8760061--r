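# Moran's I spatial autocorrelation statistic with a permutation null.

#' Moran's I for a residual vector against spatial weights
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the mean-centered input and
#' `S0` the sum of all weights.  Significance is assessed by permutation:
#' the values of `z` are randomly reassigned to the spatial units.  When
#' `n!` does not exceed `n_perm` all permutations are enumerated and the
#' p-value is exact; otherwise `n_perm` random permutations are drawn with
#' the `+1` correction.  A normal approximation under the randomization
#' assumption is available as `method = "normal_approx"`.
#'
#' @param e numeric vector (typically ANOVA residuals), non-constant.
#' @param W a [chain_weights()] object or a weights matrix of matching
#'   dimension.
#' @param n_perm permutations (default 999).
#' @param seed optional seed.
#' @param alternative `"greater"` (positive autocorrelation, the default
#'   gate for the spatially adjusted ANOVA), `"less"`, or `"two.sided"`.
#' @param method `"permutation"` or `"normal_approx"`.
#' @return an object of class `moran_result`: `I`, `expected_I = -1/(n-1)`,
#'   `p_value`, `method`, `n_perm`, `exhaustive`, `alternative`, and the
#'   permutation `null_values` when applicable.
#' @examples
#' w <- chain_weights(4)
#' morans_i(c(1, -1, 1, -1), w)$I  # exactly -1 on the alternating chain
#' @export
morans_i <- function(e, W, n_perm = 999L, seed = NULL,
                     alternative = c("greater", "less", "two.sided"),
                     method = c("permutation", "normal_approx")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  Wm <- weights_matrix(W)
  n <- length(e)
  if (nrow(Wm) != n) stop("length(e) does not match dim(W)")
  if (stats::sd(e) == 0) stop("e is constant: Moran's I is undefined")
  z <- e - mean(e)
  S0 <- sum(Wm)
  denom <- sum(z^2)
  I_of <- function(zz) (n / S0) * sum(zz * as.numeric(Wm %*% zz)) / denom
  I_obs <- I_of(z)
  expected <- -1 / (n - 1)

  if (method == "normal_approx") {
    # moments under the randomization (permutation) distribution
    Wd <- as.matrix(Wm)
    S1 <- sum((Wd + t(Wd))^2) / 2
    S2 <- sum((rowSums(Wd) + colSums(Wd))^2)
    b2 <- n * sum(z^4) / denom^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
               b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - expected^2
    zscore <- (I_obs - expected) / sqrt(varI)
    p <- switch(alternative,
                greater = stats::pnorm(zscore, lower.tail = FALSE),
                less = stats::pnorm(zscore),
                two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE))
    return(structure(
      list(I = I_obs, expected_I = expected, p_value = p,
           method = "normal_approx", n_perm = NA_integer_, exhaustive = FALSE,
           alternative = alternative, var_I = varI),
      class = "moran_result"
    ))
  }

  exhaustive <- factorial(n) <= n_perm
  tol <- 1e-12
  if (exhaustive) {
    perms <- all_permutations(n)
    Z <- matrix(z[t(perms)], nrow = n)  # one permuted z per column
  } else {
    Z <- with_seed(seed, {
      matrix(z[vapply(seq_len(n_perm), function(...) sample.int(n), integer(n))],
             nrow = n)
    })
  }
  WZ <- as.matrix(Wm %*% Z)
  null_I <- (n / S0) * colSums(Z * WZ) / denom
  count <- switch(alternative,
                  greater = sum(null_I >= I_obs - tol),
                  less = sum(null_I <= I_obs + tol),
                  two.sided = sum(abs(null_I - expected) >= abs(I_obs - expected) - tol))
  p <- if (exhaustive) count / ncol(Z) else (1 + count) / (n_perm + 1)
  structure(
    list(I = I_obs, expected_I = expected, p_value = p,
         method = "permutation", n_perm = ncol(Z), exhaustive = exhaustive,
         alternative = alternative, null_values = null_I),
    class = "moran_result"
  )
}
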