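# Laminar cell-distribution statistics: depth normalization, 20-bin
# profiles, mean laminar position, depth density/ECDF and group comparisons
# (permutation test for medians; the k-sample Anderson-Darling test lives
# in anderson-darling.R).

depths_of <- function(cells) {
  if (is.data.frame(cells)) {
    if (!"depth_fraction" %in% names(cells)) {
      stop("expected a cell table with a 'depth_fraction' column")
    }
    cells$depth_fraction
  } else {
    as.numeric(cells)
  }
}

#' Normalize raw cell Y coordinates to depth fractions
#'
#' Converts per-cell micrometre positions within a cortical column to
#' fractions of the cortical thickness (`0` = ventral boundary, `1` = pia):
#' `depth_fraction = y_um / column_height_um`.
#'
#' @param raw_positions data frame with columns `cell_id`, `y_um`,
#'   `column_height_um`, `slice_id`, `animal_id`, `genotype`.
#' @return a `cell_position_table` (see [gen_columns()] for the layout).
#' @examples
#' raw <- data.frame(cell_id = "c1", y_um = 500, column_height_um = 1000,
#'                   slice_id = "s1", animal_id = "a1", genotype = "WT")
#' normalize_depths(raw)$depth_fraction  # 0.5
#' @export
normalize_depths <- function(raw_positions) {
  need <- c("cell_id", "y_um", "column_height_um", "slice_id", "animal_id", "genotype")
  miss <- setdiff(need, names(raw_positions))
  if (length(miss)) {
    stop("raw_positions is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(raw_positions$column_height_um <= 0)) {
    stop("column_height_um must be > 0")
  }
  bad <- raw_positions$y_um < 0 | raw_positions$y_um > raw_positions$column_height_um
  if (any(bad)) {
    stop("y coordinate outside the column for cell_id(s): ",
         paste(raw_positions$cell_id[bad], collapse = ", "))
  }
  out <- data.frame(
    cell_id = raw_positions$cell_id,
    depth_fraction = raw_positions$y_um / raw_positions$column_height_um,
    slice_id = raw_positions$slice_id,
    animal_id = raw_positions$animal_id,
    genotype = raw_positions$genotype,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_position_table", "data.frame")
  out
}

bin_index <- function(depth, n_bins) {
  idx <- floor(depth * n_bins) + 1L
  idx[depth >= 1] <- n_bins  # depth exactly 1.0 belongs to the pial bin
  as.integer(idx)
}

#' Bin distribution of one cortical column
#'
#' Divides the column depth into `n_bins` half-open bins of equal size,
#' `[(i-1)/n, i/n)` with bin 1 at the ventral boundary and the last
#' (pia-adjacent) bin closed at depth 1, and returns the percentage of the
#' slice's cells falling in each bin.
#'
#' @param cells a `cell_position_table`.
#' @param slice_id slice to profile; may be omitted when `cells` holds a
#'   single slice.
#' @param n_bins number of bins (default 20).
#' @return an object of class `bin_profile`: list with `slice_id`,
#'   `genotype`, `percentages` (length `n_bins`, sums to 100) and `n_cells`.
#' @examples
#' cells <- gen_columns(column_sim_config(seed = 1))
#' bin_profile(cells, slice_id = cells$slice_id[1])
#' @export
bin_profile <- function(cells, slice_id = NULL, n_bins = 20L) {
  stopifnot(is_count(n_bins, min = 2L))
  if (!is.null(slice_id)) {
    cells <- cells[cells$slice_id == slice_id, , drop = FALSE]
  } else {
    slice_id <- unique(cells$slice_id)
    if (length(slice_id) != 1L) {
      stop("cells spans several slices; give slice_id (or use bin_profiles())")
    }
  }
  if (!nrow(cells)) {
    stop("slice '", slice_id, "' has no cells; a bin profile is undefined")
  }
  counts <- tabulate(bin_index(cells$depth_fraction, n_bins), nbins = n_bins)
  structure(
    list(slice_id = slice_id,
         genotype = unique(cells$genotype)[1],
         percentages = 100 * counts / sum(counts),
         n_cells = sum(counts)),
    class = "bin_profile"
  )
}

#' Bin distributions for every slice of a cell table
#'
#' @inheritParams bin_profile
#' @return data frame of class `bin_profile_table` with columns `slice_id`,
#'   `genotype`, `bin_01` ... `bin_<n>` (percentages) and `n_cells`; one row
#'   per slice.
#' @export
bin_profiles <- function(cells, n_bins = 20L) {
  slices <- unique(cells$slice_id)
  rows <- lapply(slices, function(s) {
    p <- bin_profile(cells, s, n_bins)
    row <- as.data.frame(as.list(p$percentages))
    names(row) <- sprintf("bin_%02d", seq_len(n_bins))
    cbind(data.frame(slice_id = p$slice_id, genotype = p$genotype,
                     stringsAsFactors = FALSE),
          row, n_cells = p$n_cells)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bin_profile_table", "data.frame")
  out
}

#' Mean laminar position, as a percentage of the cortical thickness
#'
#' @param cells a `cell_position_table` or a numeric vector of depth
#'   fractions.
#' @return `100 * mean(depth_fraction)`.
#' @examples
#' mean_laminar_position(c(0.2, 0.4, 0.6))  # 40
#' @export
mean_laminar_position <- function(cells) {
  d <- depths_of(cells)
  if (!length(d)) stop("no cells: mean laminar position is undefined")
  100 * mean(d)
}

#' Permutation test for a difference in group medians
#'
#' The statistic is `|median(a) - median(b)|`; its null distribution is
#' obtained by reassigning the pooled observations to the two groups.  When
#' the number of distinct assignments `choose(na + nb, na)` does not exceed
#' `n_perm` the test enumerates them all and the p-value is the exact
#' fraction of assignments at least as extreme as the observed one;
#' otherwise `n_perm` random assignments are drawn and the `+1`-corrected
#' estimate `(1 + #extreme) / (n_perm + 1)` is reported.
#'
#' @param group_a,group_b numeric vectors of depth fractions (cell-level
#'   permutation; aggregate to slice means first for a slice-level test).
#' @param n_perm number of random permutations (and the enumeration
#'   threshold).
#' @param seed optional seed for the random-permutation branch.
#' @return an object of class `group_comparison` with fields `statistic`,
#'   `p_value`, `n_permutations`, `exhaustive`, `method`, `groups`, and
#'   `note` when `n_perm < 100`.
#' @examples
#' median_position_test(c(0, 0), c(1, 1), n_perm = 10)$p_value  # exact 1/3
#' @export
median_position_test <- function(group_a, group_b, n_perm = 5000L, seed = NULL) {
  a <- depths_of(group_a)
  b <- depths_of(group_b)
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  obs <- abs(stats::median(a) - stats::median(b))
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  tol <- 1e-12
  n_comb <- choose(n, na)
  if (n_comb <= n_perm) {
    idx <- utils::combn(n, na)
    stat <- apply(idx, 2L, function(i) {
      abs(stats::median(pooled[i]) - stats::median(pooled[-i]))
    })
    p <- sum(stat >= obs - tol) / n_comb
    n_used <- n_comb
    exhaustive <- TRUE
  } else {
    stat <- with_seed(seed, {
      vapply(seq_len(n_perm), function(...) {
        i <- sample.int(n, na)
        abs(stats::median(pooled[i]) - stats::median(pooled[-i]))
      }, numeric(1))
    })
    p <- (1 + sum(stat >= obs - tol)) / (n_perm + 1)
    n_used <- n_perm
    exhaustive <- FALSE
  }
  res <- structure(
    list(statistic = obs, p_value = p, n_permutations = n_used,
         exhaustive = exhaustive, method = "median_permutation",
         groups = c(deparse1(substitute(group_a)), deparse1(substitute(group_b)))),
    class = "group_comparison"
  )
  if (n_perm < 100) {
    res$note <- "n_perm < 100: the permutation p-value has very coarse resolution"
  }
  res
}

#' Depth probability density with boundary reflection
#'
#' Gaussian kernel estimate of the cell-depth density on `[0, 1]`.  Mass
#' leaking past the boundaries is folded back by reflecting the sample at 0
#' and 1, so the estimate integrates to ~1 on the support.  The default
#' bandwidth is Silverman's rule on the unreflected sample.
#'
#' @param cells a `cell_position_table` or numeric vector of depths
#'   (at least two distinct values).
#' @param bandwidth `"auto"` (Silverman) or a numeric bandwidth in
#'   depth-fraction units.
#' @param n_grid number of evaluation points on `[0, 1]`.
#' @return an object of class `density_estimate`: list with `grid`,
#'   `density`, `bandwidth`, plus the `argmax` and `max` of the estimate.
#' @export
depth_density <- function(cells, bandwidth = "auto", n_grid = 512L) {
  d <- depths_of(cells)
  if (length(unique(d)) < 2L) {
    stop("all depths identical: a density is undefined; use bin_profile() instead")
  }
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(d) else {
    stopifnot(is_number(bandwidth), bandwidth > 0)
    bandwidth
  }
  reflected <- c(d, -d, 2 - d)
  dens <- stats::density(reflected, bw = bw, from = 0, to = 1, n = n_grid)
  y <- 3 * dens$y  # the two mirror copies each carry 1/3 of the mass
  structure(
    list(grid = dens$x, density = y, bandwidth = bw,
         argmax = dens$x[which.max(y)], max = max(y)),
    class = "density_estimate"
  )
}

#' Empirical cumulative distribution of cell depths
#'
#' The probability that a cell lies at or below depth `x` (right-continuous
#' step function).
#'
#' @param cells a `cell_position_table` or numeric vector of depths.
#' @param x optional depth(s) at which to evaluate; if omitted the ECDF
#'   function itself is returned.
#' @return probabilities at `x`, or a function of class `ecdf`.
#' @examples
#' depth_ecdf(c(0.2, 0.4, 0.6), x = 0.5)  # 2/3
#' @export
depth_ecdf <- function(cells, x = NULL) {
  d <- depths_of(cells)
  if (!length(d)) stop("no cells: the ECDF is undefined")
  f <- stats::ecdf(d)
  if (is.null(x)) f else f(x)
}
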