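# Shared fixtures and independent oracles used across test files.

# A small deterministic cell table: two genotypes, two slices each,
# depths spread over the column.
toy_cells <- function() {
  depths <- list(
    WT_s1 = c(0.12, 0.18, 0.33, 0.41, 0.47, 0.52, 0.58, 0.66, 0.74, 0.88),
    WT_s2 = c(0.15, 0.22, 0.36, 0.44, 0.49, 0.55, 0.61, 0.69, 0.78, 0.91),
    KO_s1 = c(0.21, 0.28, 0.42, 0.50, 0.57, 0.62, 0.68, 0.75, 0.83, 0.95),
    KO_s2 = c(0.19, 0.31, 0.45, 0.53, 0.59, 0.64, 0.71, 0.79, 0.86, 0.97)
  )
  do.call(rbind, lapply(names(depths), function(s) {
    gt <- sub("_.*", "", s)
    data.frame(
      cell_id = sprintf("%s_c%02d", s, seq_along(depths[[s]])),
      depth_fraction = depths[[s]],
      slice_id = s,
      animal_id = paste0(gt, "_a1"),
      genotype = gt,
      stringsAsFactors = FALSE
    )
  }))
}

# Independent permutation enumerator (distinct from the implementation's
# recursive generator): builds all permutations of seq_len(n) by repeated
# column expansion over expand.grid-filtered index tuples.
oracle_permutations <- function(n) {
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  keep <- apply(grid, 1L, function(r) length(unique(r)) == n)
  as.matrix(grid[keep, , drop = FALSE])
}

# Brute-force Moran's I of a centered vector against a weights matrix.
oracle_moran_I <- function(e, W) {
  z <- e - mean(e)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * z[i] * z[j]
    }
  }
  (n / sum(W)) * num / sum(z^2)
}
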