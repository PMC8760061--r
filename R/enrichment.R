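# Gene-set overlap enrichment: binomial, hypergeometric and resampling
# p-values with Benjamini-Hochberg control across sets.

#' Construct a gene set
#'
#' Gene identifiers are upper-cased, whitespace-stripped and de-duplicated
#' so that matching across files is deterministic.
#'
#' @param name set label.
#' @param members character vector of gene identifiers.
#' @return an object of class `gene_set` with fields `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- unique(normalize_gene_ids(members))
  if (!length(members)) stop("gene set '", name, "' has no members")
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

normalize_gene_ids <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

#' Percentage of a gene list that overlaps a set
#'
#' @param k overlap count (`0 <= k <= n`).
#' @param n list size (`> 0`).
#' @return `100 * k / n`, unrounded; round to one decimal for reporting.
#' @examples
#' round(overlap_percent(39, 227), 1)  # 17.2
#' @export
overlap_percent <- function(k, n) {
  if (!is_count(n, min = 1L)) stop("n must be a positive count")
  if (!is_count(k, min = 0L) || k > n) stop("k must satisfy 0 <= k <= n")
  100 * k / n
}

check_overlap_counts <- function(k, n, K, N) {
  stopifnot(is_count(N), is_count(K, 0L), is_count(n, 0L), is_count(k, 0L))
  if (K > N || n > N) stop("K and n cannot exceed the universe size N")
  if (K > 0L && k > min(n, K)) stop("k cannot exceed min(n, K)")
  if (K == 0L && k > n) stop("k cannot exceed n")
}

#' One-sided binomial test for gene-set overlap enrichment
#'
#' Models each of the `n` list genes as falling in the set independently
#' with probability `K / N` and returns the upper tail
#' `P(X >= k)` for `X ~ Binomial(n, K / N)`.
#'
#' @param k observed overlap; `n` list size; `K` set size within the
#'   universe; `N` universe size.
#' @param n,K,N see above.
#' @return one-sided p-value.
#' @examples
#' binomial_overlap_test(5, 20, 10, 100)  # ~0.043
#' @export
binomial_overlap_test <- function(k, n, K, N) {
  check_overlap_counts(k, n, K, N)
  if (K == 0 && k > 0) {
    warning("overlap is impossible under the model (K = 0 but k > 0)")
    return(0)
  }
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
}

#' One-sided hypergeometric test for gene-set overlap enrichment
#'
#' Upper tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the exact
#' null of drawing the `n`-gene list from the universe without replacement.
#'
#' @inheritParams binomial_overlap_test
#' @return one-sided p-value.
#' @export
hypergeometric_overlap_test <- function(k, n, K, N) {
  check_overlap_counts(k, n, K, N)
  if (K == 0 && k > 0) {
    warning("overlap is impossible under the model (K = 0 but k > 0)")
    return(0)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Resampling null for a gene-set overlap
#'
#' Draws `R` random lists of `n` genes from the universe without
#' replacement, recomputes the overlap with the set each time, and returns
#' the `+1`-corrected permutation p-value
#' `(1 + #{null overlap >= k}) / (R + 1)` together with the null counts.
#' With `two_way = TRUE` the set is also redrawn (size `K`) at every
#' resample.
#'
#' @param k observed overlap.
#' @param n list size.
#' @param set a [gene_set()] (its members are intersected with the
#'   universe).
#' @param universe character vector of background gene ids.
#' @param R number of resamples (default 1000).
#' @param seed optional seed.
#' @param two_way also randomize the set?  Off by default.
#' @return list with `p_permutation`, `null_overlaps`, `R`.
#' @export
resampling_null <- function(k, n, set, universe, R = 1000L, seed = NULL,
                            two_way = FALSE) {
  if (!is_count(R)) stop("R must be a count >= 1")
  universe <- unique(normalize_gene_ids(universe))
  N <- length(universe)
  if (n > N) stop("n cannot exceed the universe size")
  members <- intersect(set$members, universe)
  in_set <- universe %in% members
  K <- sum(in_set)
  null_overlaps <- with_seed(seed, {
    vapply(seq_len(R), function(...) {
      idx <- in_set
      if (two_way) {
        idx <- logical(N)
        idx[sample.int(N, K)] <- TRUE
      }
      sum(idx[sample.int(N, n)])
    }, numeric(1))
  })
  list(p_permutation = (1 + sum(null_overlaps >= k)) / (R + 1),
       null_overlaps = null_overlaps, R = R)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values with monotonicity enforced, in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Overlap enrichment report for a DEX list against several gene sets
#'
#' For every set, intersects both the set and the DEX list with the
#' expressed-gene universe, counts the overlap and computes the one-sided
#' binomial test, the exact hypergeometric test, and the resampling
#' (permutation) p-value; binomial p-values are BH-adjusted across the sets
#' of the report.
#'
#' @param dex a [gene_set()]: the differentially-expressed gene list.
#' @param sets list of [gene_set()] objects to test against.
#' @param universe character vector of expressed-gene ids.
#' @param R resamples for the permutation p-value.
#' @param seed optional seed.
#' @param two_way passed to [resampling_null()].
#' @return data frame of class `overlap_report`, one row per set:
#'   `set_name`, `k`, `n`, `K`, `N`, `percent`, `percent_reported` (one
#'   decimal), `p_binomial`, `p_hypergeometric`, `p_permutation`, `q_bh`,
#'   `n_resamples`, `out_of_universe`.
#' @examples
#' u <- sprintf("G%03d", 1:100)
#' rep <- enrich_report(gene_set("dex", u[1:20]),
#'                      list(gene_set("disease", u[11:20])), u, R = 200, seed = 1)
#' rep$k  # 10
#' @export
enrich_report <- function(dex, sets, universe, R = 1000L, seed = NULL,
                          two_way = FALSE) {
  stopifnot(inherits(dex, "gene_set"))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  universe <- unique(normalize_gene_ids(universe))
  N <- length(universe)
  dex_members <- intersect(dex$members, universe)
  if (!length(dex_members)) {
    stop("the DEX list shares no genes with the universe")
  }
  n <- length(dex_members)
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    members <- intersect(s$members, universe)
    K <- length(members)
    k <- length(intersect(dex_members, members))
    rs <- resampling_null(k, n, s, universe, R = R,
                          seed = if (is.null(seed)) NULL else seed + i,
                          two_way = two_way)
    data.frame(
      set_name = s$name, k = k, n = n, K = K, N = N,
      percent = overlap_percent(k, n),
      percent_reported = round(overlap_percent(k, n), 1),
      p_binomial = binomial_overlap_test(k, n, K, N),
      p_hypergeometric = hypergeometric_overlap_test(k, n, K, N),
      p_permutation = rs$p_permutation,
      n_resamples = R,
      out_of_universe = length(s$members) - K,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p_binomial)
  out <- out[, c("set_name", "k", "n", "K", "N", "percent", "percent_reported",
                 "p_binomial", "p_hypergeometric", "p_permutation", "q_bh",
                 "n_resamples", "out_of_universe")]
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Tally a differentially-expressed gene list from its printed components
#'
#' Bookkeeping for DEX-list summaries: the list total is the sum of its
#' down- and up-regulated parts, and the layer-enriched remainder is the
#' total minus the genes generic to all layers.
#'
#' @param down,up counts of down- and up-regulated genes.
#' @param generic optional count of genes generic to all layers.
#' @return list with `total` and (when `generic` is given)
#'   `layer_enriched`.
#' @examples
#' dex_tally(185, 78, generic = 180)
#' @export
dex_tally <- function(down, up, generic = NULL) {
  stopifnot(is_count(down, 0L), is_count(up, 0L))
  out <- list(total = down + up)
  if (!is.null(generic)) {
    stopifnot(is_count(generic, 0L), generic <= out$total)
    out$layer_enriched <- out$total - generic
  }
  out
}
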