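# Compact print methods for the package's result objects.

#' @export
print.group_comparison <- function(x, ...) {
  cat(switch(x$method,
             median_permutation = "Permutation test for medians",
             anderson_darling_k = "k-sample Anderson-Darling test (midrank)"),
      "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      "  p =", format.pval(x$p_value, digits = 3), "\n")
  if (identical(x$method, "median_permutation")) {
    cat("  permutations:", x$n_permutations,
        if (x$exhaustive) "(exhaustive)" else "(random, +1 corrected)", "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran's I:", format(x$I, digits = 4),
      " (null expectation", format(x$expected_I, digits = 4), ")\n")
  cat("  p =", format.pval(x$p_value, digits = 3),
      " [", x$method,
      if (identical(x$method, "permutation"))
        paste0(", ", x$n_perm, if (x$exhaustive) " exhaustive" else " random"),
      ", alternative: ", x$alternative, "]\n", sep = "")
  invisible(x)
}

#' @export
print.spatial_lag_fit <- function(x, ...) {
  cat("Spatial lag model (ML)\n")
  cat("  rho =", format(x$rho, digits = 4),
      "  sigma2 =", format(x$sigma2, digits = 4), "\n")
  cat("  loglik =", format(x$loglik, digits = 6),
      " (OLS at rho = 0:", format(x$loglik0, digits = 6), ")\n")
  invisible(x)
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (type-II sums of squares)\n")
  print(x$table, row.names = FALSE)
  cat("residual df:", x$df_res, "\n")
  invisible(x)
}

#' @export
print.adjusted_anova_result <- function(x, ...) {
  cat("Spatially adjusted two-way ANOVA\n")
  cat("  gates: Shapiro p =", format.pval(x$gates$shapiro_p, digits = 3),
      "| Levene p =", format.pval(x$gates$levene_p, digits = 3),
      "| Moran I =", format(x$gates$moran_I, digits = 3),
      "(p =", format.pval(x$gates$moran_p, digits = 3), ")\n")
  cat("  branch:", x$branch,
      if (!is.na(x$rho)) paste0("(rho = ", format(x$rho, digits = 4), ")"), "\n")
  print(x$table[, c("term", "df", "F", "p")], row.names = FALSE)
  sig <- x$posthoc$bin[x$posthoc$p_bonferroni < 0.05]
  cat("  post hoc (Bonferroni x", x$n_bins, "): ",
      if (length(sig)) paste("bins", paste(sig, collapse = ", "), "< 0.05")
      else "no bin below 0.05", "\n", sep = "")
  invisible(x)
}

#' @export
print.bin_profile <- function(x, ...) {
  cat("Bin profile for slice", x$slice_id,
      "(", x$genotype, ",", x$n_cells, "cells )\n")
  p <- round(x$percentages, 2)
  names(p) <- sprintf("b%02d", seq_along(p))
  print(p)
  invisible(x)
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Pearson co-expression network:", length(x$genes), "genes, threshold r >=",
      x$threshold, "\n")
  cat("  edges:", sum(x$adjacency) / 2L,
      if (length(x$dropped)) paste0(" (", length(x$dropped),
                                    " zero-variance genes dropped)"), "\n")
  invisible(x)
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("Depth density estimate (Gaussian kernel, boundary reflection)\n")
  cat("  bandwidth =", format(x$bandwidth, digits = 4),
      "  mode at depth", format(x$argmax, digits = 3),
      "(density", format(x$max, digits = 4), ")\n")
  invisible(x)
}
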