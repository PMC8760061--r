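# Contiguity spatial weights for stacked bin profiles.

#' Chain-contiguity spatial weights for binned columns
#'
#' Builds the binary contiguity matrix in which bin `i` of a column is a
#' neighbour of bins `i - 1` and `i + 1` of the same column (value 1,
#' otherwise 0), assembled block-diagonally over slices — bins are spatially
#' adjacent only within their own cortical column — and then row-normalizes
#' it (each row divided by its total), matching the weighting used for
#' Moran's I and the spatial lag model.
#'
#' @param n_bins bins per column (`>= 2`).
#' @param slices number of columns stacked (the response vector is assumed
#'   ordered slice by slice, bins ventral to pial within each slice).
#' @param normalize row-normalize? (default `TRUE`).
#' @return an object of class `spatial_weights`: list with the sparse
#'   matrix `W`, `scheme`, `normalized`, `n_bins`, `slices`, and the
#'   eigenvalues of one row-normalized block (`block_eigen`), which are the
#'   eigenvalues of the full block-diagonal `W`, each repeated `slices`
#'   times.
#' @examples
#' chain_weights(3, slices = 1)$W
#' @export
chain_weights <- function(n_bins, slices = 1L, normalize = TRUE) {
  if (!is_count(n_bins, min = 2L)) stop("n_bins must be an integer >= 2")
  stopifnot(is_count(slices))
  block <- Matrix::bandSparse(n_bins, n_bins, k = c(-1L, 1L),
                              diagonals = list(rep(1, n_bins - 1L),
                                               rep(1, n_bins - 1L)))
  if (normalize) {
    block <- block / Matrix::rowSums(block)
  }
  W <- if (slices == 1L) block else Matrix::bdiag(rep(list(block), slices))
  structure(
    list(W = methods::as(W, "generalMatrix"), scheme = "chain_contiguity",
         normalized = normalize, n_bins = as.integer(n_bins),
         slices = as.integer(slices),
         block_eigen = eigen(as.matrix(block), only.values = TRUE)$values),
    class = "spatial_weights"
  )
}

weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else W
}

weights_eigen <- function(W) {
  if (inherits(W, "spatial_weights")) {
    rep(W$block_eigen, W$slices)
  } else {
    eigen(as.matrix(W), only.values = TRUE)$values
  }
}
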