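# Thresholded Pearson co-expression network and degree centrality.

#' Log-transform an expression matrix
#'
#' Elementwise `log2(x + 1)`, the scale on which pairwise correlations are
#' computed.
#'
#' @param x nonnegative numeric matrix (genes in rows).
#' @return transformed matrix of the same shape.
#' @examples
#' log_transform(matrix(c(0, 1, 7, 3), 2))
#' @export
log_transform <- function(x) {
  x <- as.matrix(x)
  if (any(is.na(x))) stop("expression matrix contains missing values")
  if (any(x < 0)) stop("expression values must be nonnegative")
  log2(x + 1)
}

#' Thresholded Pearson co-expression network
#'
#' Computes all pairwise Pearson correlations between gene rows and keeps
#' an (undirected) edge wherever the signed correlation reaches the
#' threshold; anti-correlated pairs never form edges.  Genes with zero
#' variance across samples are dropped (and reported) rather than failing
#' the run.
#'
#' @param x numeric matrix, genes in rows, at least 3 sample columns
#'   (typically the output of [log_transform()]).
#' @param threshold minimum signed correlation for an edge (default 0.7).
#' @return an object of class `correlation_network`: `genes`, the full
#'   correlation matrix `r`, `threshold`, the logical `adjacency` (zero
#'   diagonal), and `dropped` (zero-variance gene names).
#' @export
pearson_network <- function(x, threshold = 0.7) {
  x <- as.matrix(x)
  if (ncol(x) < 3L) stop("need at least 3 samples to correlate")
  if (!is_number(threshold) || threshold > 1) stop("threshold must be <= 1")
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene_%d", seq_len(nrow(x)))
  sds <- apply(x, 1L, stats::sd)
  dropped <- rownames(x)[sds == 0]
  if (length(dropped)) {
    message(length(dropped), " zero-variance gene(s) dropped from the network")
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("fewer than 2 genes with variance: no network")
  r <- stats::cor(t(x))
  adjacency <- r >= threshold
  diag(adjacency) <- FALSE
  structure(
    list(genes = rownames(x), r = r, threshold = threshold,
         adjacency = adjacency, dropped = dropped),
    class = "correlation_network"
  )
}

#' Degree centrality and neighbourhoods in a correlation network
#'
#' Degree centrality is the raw neighbour count: the number of genes whose
#' correlation with the gene reaches the network threshold.
#'
#' @param net a [pearson_network()] object.
#' @param focal optional gene name; if given, that gene's degree and
#'   neighbour set are returned, otherwise the whole table.
#' @return for a focal gene, a list with `gene`, `degree`, `neighbors`;
#'   otherwise a data frame (`gene`, `degree`) with the neighbour sets in a
#'   list column `neighbors`.
#' @export
degree_and_neighbors <- function(net, focal = NULL) {
  stopifnot(inherits(net, "correlation_network"))
  if (!is.null(focal)) {
    if (!focal %in% net$genes) {
      near <- agrep(focal, net$genes, max.distance = 0.3, value = TRUE)
      stop("unknown gene '", focal, "'",
           if (length(near)) paste0("; closest matches: ",
                                    paste(utils::head(near, 5), collapse = ", ")))
    }
    nb <- net$genes[net$adjacency[focal, ]]
    return(list(gene = focal, degree = length(nb), neighbors = nb))
  }
  deg <- rowSums(net$adjacency)
  out <- data.frame(gene = net$genes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out$neighbors <- lapply(net$genes, function(g) net$genes[net$adjacency[g, ]])
  rownames(out) <- NULL
  out
}

#' Edge list with display weights rescaled over a correlation window
#'
#' Each edge's weight is the linear rescaling of its correlation from the
#' window `[w_min_r, 1]` to `[0, 1]`, clipped at the ends — the convention
#' used to scale edge thickness in network figures.
#'
#' @param net a [pearson_network()] object.
#' @param w_min_r lower end of the correlation window (default 0.5; must be
#'   `< 1`).
#' @return data frame `gene_a`, `gene_b`, `r`, `weight`, one row per
#'   undirected edge.
#' @export
edge_weight_scaling <- function(net, w_min_r = 0.5) {
  stopifnot(inherits(net, "correlation_network"))
  if (!is_number(w_min_r) || w_min_r >= 1) stop("w_min_r must be < 1")
  idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  r <- net$r[idx]
  data.frame(
    gene_a = net$genes[idx[, 1L]],
    gene_b = net$genes[idx[, 2L]],
    r = r,
    weight = pmin(1, pmax(0, (r - w_min_r) / (1 - w_min_r))),
    stringsAsFactors = FALSE
  )
}
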