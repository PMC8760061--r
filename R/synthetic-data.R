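# Seeded generators for synthetic inputs that reproduce the statistical
# structure assumed by the downstream analyses: layered depth distributions
# with genotype shifts and animal/slice hierarchy, gene universes with a
# planted overlap between a "differentially expressed" list and a disease
# set, and module-structured expression matrices.

# --- cortical column cell positions ----------------------------------------

#' Describe one layer of a simulated cortical column
#'
#' A layer is a truncated-Gaussian band of cell depths.  Depth is expressed
#' as a fraction of the cortical thickness: 0 is the ventral boundary of the
#' column, 1 the pial surface.
#'
#' @param name layer label.
#' @param depth_center center of the band, in `[0, 1]`.
#' @param depth_sd spread of the band (depth-fraction units), `> 0`.
#' @param weight mixing proportion of the layer within its column; the
#'   weights of all layers in a [column_sim_config()] must sum to 1.
#' @return an object of class `layer_spec`.
#' @examples
#' layer_spec("L5", depth_center = 0.45, depth_sd = 0.08, weight = 1)
#' @export
layer_spec <- function(name, depth_center, depth_sd, weight) {
  if (!is_fraction(depth_center)) {
    stop_config("layer depth_center must lie in [0, 1]")
  }
  if (!is_number(depth_sd) || depth_sd <= 0) {
    stop_config("layer depth_sd must be > 0")
  }
  if (!is_number(weight) || weight < 0) {
    stop_config("layer weight must be >= 0")
  }
  structure(
    list(name = as.character(name), depth_center = depth_center,
         depth_sd = depth_sd, weight = weight),
    class = "layer_spec"
  )
}

#' Default layer mixture for a single-marker column
#'
#' One dominant band (a marker-positive layer) over a diffuse background of
#' scattered marker-positive cells, so that every depth bin has nonzero
#' expected occupancy, as in real immunolabeled columns.
#'
#' @return list of [layer_spec()] objects.
#' @export
default_cortical_layers <- function() {
  list(
    layer_spec("band", depth_center = 0.45, depth_sd = 0.08, weight = 0.85),
    layer_spec("background", depth_center = 0.5, depth_sd = 0.4, weight = 0.15)
  )
}

#' Configuration for simulated cortical-column cell positions
#'
#' @param layers list of [layer_spec()]; weights must sum to 1.
#' @param genotype_shifts named numeric vector, one entry per genotype:
#'   a signed depth-fraction shift added to every layer center (positive =
#'   toward the pia), encoding an over-migration effect.
#' @param n_animals_per_genotype animals per genotype; scalar or vector
#'   recycled over genotypes (groups may be unbalanced).
#' @param slices_per_animal slices (cortical columns) imaged per animal.
#' @param cells_per_slice cells counted per column.
#' @param animal_sd,slice_sd standard deviations of Gaussian random
#'   intercepts on the shift at the animal and slice level, emulating the
#'   replicate hierarchy (slices nested in animals).  Set both to 0 for a
#'   fully exchangeable null.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return an object of class `column_sim_config`.
#' @seealso [gen_columns()]
#' @export
column_sim_config <- function(layers = default_cortical_layers(),
                              genotype_shifts = c(WT = 0, KO = 0.05),
                              n_animals_per_genotype = 5,
                              slices_per_animal = 5,
                              cells_per_slice = 150,
                              animal_sd = 0.005,
                              slice_sd = 0.01,
                              seed = 1L) {
  if (!length(layers) || !all(vapply(layers, inherits, logical(1), "layer_spec"))) {
    stop_config("layers must be a non-empty list of layer_spec objects")
  }
  w <- vapply(layers, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    stop_config("layer weights must sum to 1 (got ", format(sum(w)), ")")
  }
  if (is.null(names(genotype_shifts)) || any(names(genotype_shifts) == "")) {
    stop_config("genotype_shifts must be a named vector")
  }
  n_gt <- length(genotype_shifts)
  n_animals_per_genotype <- rep_len(n_animals_per_genotype, n_gt)
  for (v in c(n_animals_per_genotype, slices_per_animal, cells_per_slice)) {
    if (!is_count(v)) stop_config("counts must be integers >= 1")
  }
  if (animal_sd < 0 || slice_sd < 0) stop_config("hierarchy sds must be >= 0")
  structure(
    list(layers = layers, genotype_shifts = genotype_shifts,
         n_animals_per_genotype = n_animals_per_genotype,
         slices_per_animal = slices_per_animal,
         cells_per_slice = cells_per_slice,
         animal_sd = animal_sd, slice_sd = slice_sd, seed = seed),
    class = "column_sim_config"
  )
}

#' Simulate per-cell laminar positions in cortical columns
#'
#' Draws cell depths from the configured layer mixture: each cell picks a
#' layer with probability equal to its weight, then a truncated-Gaussian
#' depth (rejection sampling within `[0, 1]`) around the layer center
#' shifted by the genotype effect plus animal- and slice-level random
#' intercepts.  Shifted centers are clipped to `[0, 1]`.
#'
#' @param config a [column_sim_config()].
#' @return a `cell_position_table`: a data frame with columns `cell_id`,
#'   `depth_fraction` (in `[0, 1]`), `slice_id`, `animal_id`, `genotype`.
#' @examples
#' cells <- gen_columns(column_sim_config(seed = 42))
#' head(cells)
#' @export
gen_columns <- function(config) {
  stopifnot(inherits(config, "column_sim_config"))
  with_seed(config$seed, {
    layers <- config$layers
    centers <- vapply(layers, `[[`, numeric(1), "depth_center")
    sds <- vapply(layers, `[[`, numeric(1), "depth_sd")
    weights <- vapply(layers, `[[`, numeric(1), "weight")
    genotypes <- names(config$genotype_shifts)
    out <- vector("list", 0L)
    for (g in seq_along(genotypes)) {
      gt <- genotypes[g]
      delta_g <- config$genotype_shifts[[g]]
      for (a in seq_len(config$n_animals_per_genotype[g])) {
        animal_id <- sprintf("%s_a%02d", gt, a)
        delta_a <- delta_g + stats::rnorm(1, 0, config$animal_sd)
        for (s in seq_len(config$slices_per_animal)) {
          slice_id <- sprintf("%s_s%02d", animal_id, s)
          delta_s <- delta_a + stats::rnorm(1, 0, config$slice_sd)
          n <- config$cells_per_slice
          layer_idx <- sample.int(length(layers), n, replace = TRUE, prob = weights)
          mu <- pmin(1, pmax(0, centers[layer_idx] + delta_s))
          depth <- numeric(n)
          for (li in unique(layer_idx)) {
            sel <- layer_idx == li
            depth[sel] <- rtruncnorm01(sum(sel), mu[sel], sds[li])
          }
          out[[length(out) + 1L]] <- data.frame(
            cell_id = sprintf("%s_c%04d", slice_id, seq_len(n)),
            depth_fraction = depth,
            slice_id = slice_id,
            animal_id = animal_id,
            genotype = gt,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    class(tab) <- c("cell_position_table", "data.frame")
    tab
  })
}

# --- gene universe and planted overlap -------------------------------------

#' Configuration for a synthetic gene universe with a planted overlap
#'
#' @param universe_size `N`, number of expressed background genes.
#' @param set_size `K`, size of the disease/annotation set.
#' @param dex_size `n`, size of the differentially-expressed (DEX) list.
#' @param fold enrichment multiplier `>= 0`: the expected overlap between
#'   the DEX list and the set is `fold * n * K / N` (`fold = 1` is the
#'   random-sampling null, `fold = 0` forces zero overlap).
#' @param seed integer seed.
#' @return an object of class `enrichment_sim_config`.
#' @seealso [gen_gene_universe()]
#' @export
enrichment_sim_config <- function(universe_size = 10000,
                                  set_size = 850,
                                  dex_size = 227,
                                  fold = 1,
                                  seed = 1L) {
  if (!is_count(universe_size) || !is_count(set_size) || !is_count(dex_size)) {
    stop_config("universe_size, set_size and dex_size must be counts >= 1")
  }
  if (set_size > universe_size || dex_size > universe_size) {
    stop_config("set_size and dex_size cannot exceed universe_size")
  }
  if (!is_number(fold) || fold < 0) stop_config("fold must be >= 0")
  if (fold * set_size / universe_size > 1) {
    stop_config("fold * K / N exceeds 1; the planted overlap probability is not valid")
  }
  structure(
    list(universe_size = universe_size, set_size = set_size,
         dex_size = dex_size, fold = fold, seed = seed),
    class = "enrichment_sim_config"
  )
}

#' Simulate a gene universe, a disease set and a DEX list
#'
#' The overlap count between the DEX list and the disease set is drawn from
#' `Binomial(n, fold * K / N)` (clamped to the feasible range), the
#' overlapping members are sampled from the set and the remaining DEX
#' members from outside it, so the expected overlap is exactly
#' `fold * n * K / N` up to clamping.
#'
#' @param config an [enrichment_sim_config()].
#' @return list with elements `universe` (character vector of gene ids),
#'   `disease_set` and `dex_set` (both [gene_set()] objects).
#' @export
gen_gene_universe <- function(config) {
  stopifnot(inherits(config, "enrichment_sim_config"))
  with_seed(config$seed, {
    N <- config$universe_size
    K <- config$set_size
    n <- config$dex_size
    universe <- sprintf("G%06d", seq_len(N))
    disease <- sample(universe, K)
    p <- min(1, config$fold * K / N)
    m <- stats::rbinom(1L, n, p)
    m <- max(min(m, K, n), n - (N - K))
    dex <- c(
      if (m > 0) sample(disease, m),
      if (n - m > 0) sample(setdiff(universe, disease), n - m)
    )
    list(
      universe = universe,
      disease_set = gene_set("disease", disease),
      dex_set = gene_set("dex", dex)
    )
  })
}

# --- module-structured expression ------------------------------------------

#' Configuration for a synthetic expression matrix with co-expression modules
#'
#' Genes assigned to the same module share a latent sample factor so that on
#' the `log2(x + 1)` scale their pairwise Pearson correlation targets
#' `within_module_r`; unassigned genes are independent noise.
#'
#' @param n_genes,n_samples matrix dimensions (`n_samples >= 3`).
#' @param module_assignment integer vector of length `n_genes` giving each
#'   gene's module id, `NA` for background genes.  Default: the first 15
#'   genes form module 1.
#' @param within_module_r target within-module Pearson correlation in `[0, 1)`.
#' @param noise_sd gene-level noise standard deviation on the log2 scale.
#' @param seed integer seed.
#' @return an object of class `expression_sim_config`.
#' @seealso [gen_expression()]
#' @export
expression_sim_config <- function(n_genes = 60,
                                  n_samples = 50,
                                  module_assignment = c(rep(1L, min(15L, n_genes)),
                                                        rep(NA_integer_,
                                                            max(0L, n_genes - 15L))),
                                  within_module_r = 0.9,
                                  noise_sd = 1,
                                  seed = 1L) {
  if (!is_count(n_genes) || !is_count(n_samples, min = 3L)) {
    stop_config("n_genes must be >= 1 and n_samples >= 3")
  }
  if (length(module_assignment) != n_genes) {
    stop_config("module_assignment must have one entry per gene")
  }
  if (!is_number(within_module_r) || within_module_r < 0 || within_module_r >= 1) {
    stop_config("within_module_r must lie in [0, 1)")
  }
  if (!is_number(noise_sd) || noise_sd <= 0) stop_config("noise_sd must be > 0")
  structure(
    list(n_genes = n_genes, n_samples = n_samples,
         module_assignment = module_assignment,
         within_module_r = within_module_r, noise_sd = noise_sd, seed = seed),
    class = "expression_sim_config"
  )
}

#' Simulate a nonnegative RPKM-scale expression matrix
#'
#' Builds `log2(x + 1)` values from a one-factor model per module,
#' `L = mu_gene + a * f_module + noise_sd * eps` with
#' `a = noise_sd * sqrt(r / (1 - r))`, which gives within-module Pearson
#' correlation `r` on the log scale, then back-transforms `x = 2^L - 1`.
#' Log values are floored at 0 so the matrix is nonnegative; gene means are
#' drawn in `[2, 6]` so flooring is rare and the achieved correlation stays
#' close to the target.
#'
#' @param config an [expression_sim_config()].
#' @return numeric matrix, genes in rows (named `GENE...`), samples in
#'   columns (named `S...`), all entries `>= 0`.
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(config$seed, {
    p <- config$n_genes
    n <- config$n_samples
    r <- config$within_module_r
    a <- config$noise_sd * sqrt(r / (1 - r))
    mods <- config$module_assignment
    mu <- stats::runif(p, 2, 6)
    L <- matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
    for (m in unique(mods[!is.na(mods)])) {
      f <- stats::rnorm(n)
      sel <- which(!is.na(mods) & mods == m)
      L[sel, ] <- L[sel, ] + rep(a * f, each = length(sel))
    }
    L <- pmax(L + mu, 0)
    x <- 2^L - 1
    dimnames(x) <- list(sprintf("GENE%04d", seq_len(p)), sprintf("S%03d", seq_len(n)))
    x
  })
}

# --- dendritic spine surveys ------------------------------------------------

#' Simulate longitudinal spine-count surveys with a planted net-gain shift
#'
#' Each animal receives a net spine-addition rate drawn around its genotype
#' mean; per dendritic segment the baseline spine count is Poisson and the
#' gained/lost counts are binomial at the animal's formation/elimination
#' rates, so segment-level sampling noise rides on top of the planted
#' animal-level effect.
#'
#' @param n_animals named vector of animals per genotype.
#' @param segments_per_animal dendritic segments imaged per animal.
#' @param n_day0_mean mean baseline spine count per segment.
#' @param base_rate_pct baseline formation and elimination rate (percent of
#'   baseline spines over the interval).
#' @param net_gain_pct named vector: mean net addition (formation minus
#'   elimination, percent) per genotype.
#' @param animal_sd_pct animal-level standard deviation of the net rate.
#' @param interval_days interval between imaging sessions.
#' @param seed integer seed.
#' @return a `spine_survey` data frame with columns `segment_id`,
#'   `animal_id`, `genotype`, `n_day0`, `n_gained`, `n_lost`,
#'   `interval_days`.
#' @seealso [turnover_rates()], [group_turnover()]
#' @export
gen_spines <- function(n_animals = c(WT = 8, KO = 6),
                       segments_per_animal = 8,
                       n_day0_mean = 50,
                       base_rate_pct = 10,
                       net_gain_pct = c(WT = 0, KO = 6),
                       animal_sd_pct = 2,
                       interval_days = 3,
                       seed = 1L) {
  stopifnot(!is.null(names(n_animals)),
            identical(sort(names(n_animals)), sort(names(net_gain_pct))))
  with_seed(seed, {
    rows <- list()
    for (gt in names(n_animals)) {
      for (a in seq_len(n_animals[[gt]])) {
        animal_id <- sprintf("%s_a%02d", gt, a)
        net <- stats::rnorm(1, net_gain_pct[[gt]], animal_sd_pct)
        p_form <- max(0, (base_rate_pct + net / 2) / 100)
        p_elim <- min(max(0, (base_rate_pct - net / 2) / 100), 1)
        for (s in seq_len(segments_per_animal)) {
          n0 <- stats::rpois(1, n_day0_mean - 1) + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            segment_id = sprintf("%s_seg%02d", animal_id, s),
            animal_id = animal_id,
            genotype = gt,
            n_day0 = n0,
            n_gained = stats::rbinom(1L, n0, min(p_form, 1)),
            n_lost = stats::rbinom(1L, n0, p_elim),
            interval_days = interval_days,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("spine_survey", "data.frame")
    out
  })
}
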