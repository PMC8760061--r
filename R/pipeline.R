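# End-to-end pipeline driver: simulate -> laminar -> spatial-anova ->
# enrich -> network -> turnover, with a run record capturing the config,
# seeds and per-stage branch decisions.

#' Default pipeline configuration
#'
#' @param seed master seed; each stochastic stage derives its own seed from
#'   it (recorded in the run record).
#' @param output_dir where stage outputs are written.
#' @param stages subset of
#'   `c("simulate", "laminar", "spatial_anova", "enrich", "network",
#'   "turnover")`, executed in that order.
#' @param n_perm,moran_n_perm,resamples,alpha_gate,n_bins analysis
#'   defaults, see [adjusted_anova()] and [enrich_report()].
#' @return config list suitable for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, output_dir = "laminapipe_out",
                            stages = c("simulate", "laminar", "spatial_anova",
                                       "enrich", "network", "turnover"),
                            n_perm = 1000L, moran_n_perm = 199L,
                            resamples = 1000L, alpha_gate = 0.05,
                            n_bins = 20L) {
  list(seed = seed, output_dir = output_dir, stages = stages,
       n_perm = n_perm, moran_n_perm = moran_n_perm, resamples = resamples,
       alpha_gate = alpha_gate, n_bins = n_bins,
       inputs = list())
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order.  When the `simulate` stage is
#' included its synthetic outputs feed the later stages; otherwise the
#' stages read the paths given in `config$inputs` (`cell_table`, `gmt`,
#' `dex`, `universe`, `expression`, `spines`).  Every stage output is
#' written under `config$output_dir`, and a `run_record.json` captures the
#' config, its hash, the derived seeds and the branch decisions, so a rerun
#' with an identical config reproduces the outputs byte for byte.  A stage
#' failure halts the run after writing the partial run record.
#'
#' @param config a [pipeline_config()] list or the path of a YAML file with
#'   the same fields.
#' @return the run record, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  record <- list(
    package_version = as.character(utils::packageVersion("laminapipe")),
    config = config,
    config_hash = config_hash(config),
    stages = list()
  )
  seed <- as.integer(config$seed)
  finish <- function() {
    write_result_json(record, file.path(out_dir, "run_record.json"))
  }
  paths <- config$inputs

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      record$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
      finish()
      stop("stage '", name, "' failed: ", conditionMessage(res), call. = FALSE)
    }
    record$stages[[name]] <<- c(list(status = "ok"), res)
  }

  run_stage("simulate", function() {
    cells <- gen_columns(column_sim_config(seed = seed + 1L))
    write_cell_table(cells, file.path(out_dir, "cell_table.csv"))
    gu <- gen_gene_universe(enrichment_sim_config(seed = seed + 2L, fold = 3))
    writeLines(gu$universe, file.path(out_dir, "universe.txt"))
    write_gmt(list(gu$disease_set), file.path(out_dir, "sets.gmt"))
    writeLines(c("gene", gu$dex_set$members), file.path(out_dir, "dex.tsv"))
    expr <- gen_expression(expression_sim_config(seed = seed + 3L))
    write_expression(expr, file.path(out_dir, "expression.tsv"))
    spines <- gen_spines(seed = seed + 4L)
    write_spines(spines, file.path(out_dir, "spines.csv"))
    paths <<- list(cell_table = file.path(out_dir, "cell_table.csv"),
                   universe = file.path(out_dir, "universe.txt"),
                   gmt = file.path(out_dir, "sets.gmt"),
                   dex = file.path(out_dir, "dex.tsv"),
                   expression = file.path(out_dir, "expression.tsv"),
                   spines = file.path(out_dir, "spines.csv"))
    list(seed = seed + 1L)
  })

  run_stage("laminar", function() {
    cells <- read_cell_table(paths$cell_table)
    profiles <- bin_profiles(cells, n_bins = config$n_bins)
    write_bin_profiles(profiles, file.path(out_dir, "bin_profiles.tsv"))
    paths$profiles <<- file.path(out_dir, "bin_profiles.tsv")
    gts <- unique(cells$genotype)
    res <- list(
      mean_position = lapply(stats::setNames(gts, gts), function(g) {
        mean_laminar_position(cells[cells$genotype == g, ])
      })
    )
    if (length(gts) == 2L) {
      mt <- median_position_test(cells$depth_fraction[cells$genotype == gts[1]],
                                 cells$depth_fraction[cells$genotype == gts[2]],
                                 n_perm = config$n_perm, seed = seed + 5L)
      ad <- ad_k_sample_test(split(cells$depth_fraction, cells$genotype))
      res$median_test <- list(statistic = mt$statistic, p_value = mt$p_value,
                              n_permutations = mt$n_permutations)
      res$anderson_darling <- list(statistic = ad$statistic, p_value = ad$p_value)
    }
    write_result_json(res, file.path(out_dir, "laminar_results.json"))
    list(seed = seed + 5L, n_slices = nrow(profiles))
  })

  run_stage("spatial_anova", function() {
    profiles <- read_bin_profiles(paths$profiles)
    res <- adjusted_anova(profiles, alpha_gate = config$alpha_gate,
                          n_perm = config$n_perm,
                          moran_n_perm = config$moran_n_perm,
                          seed = seed + 6L)
    write_result_json(
      list(gates = res$gates, branch = res$branch, rho = res$rho,
           table = res$table, posthoc = res$posthoc, df_res = res$df_res,
           compositional = res$compositional, seed = seed + 6L),
      file.path(out_dir, "spatial_anova.json")
    )
    list(seed = seed + 6L, branch = res$branch)
  })

  run_stage("enrich", function() {
    universe <- readLines(paths$universe, warn = FALSE)
    sets <- read_gmt(paths$gmt)
    dex <- read_dex_list(paths$dex)
    rep <- enrich_report(dex, sets, universe, R = config$resamples,
                         seed = seed + 7L)
    utils::write.table(rep, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_result_json(rep, file.path(out_dir, "enrichment.json"))
    list(seed = seed + 7L, n_sets = nrow(rep))
  })

  run_stage("network", function() {
    expr <- read_expression(paths$expression)
    net <- pearson_network(log_transform(expr), threshold = 0.7)
    deg <- degree_and_neighbors(net)
    utils::write.table(deg[c("gene", "degree")],
                       file.path(out_dir, "degree_centrality.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    edges <- edge_weight_scaling(net, w_min_r = 0.5)
    utils::write.table(edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(n_genes = length(net$genes), n_edges = nrow(edges),
         n_dropped = length(net$dropped))
  })

  run_stage("turnover", function() {
    spines <- read_spines(paths$spines)
    gt <- group_turnover(spines)
    write_result_json(
      list(animal_means = gt$animal_means, comparisons = gt$comparisons),
      file.path(out_dir, "turnover.json")
    )
    list(n_animals = nrow(gt$animal_means))
  })

  finish()
  invisible(record)
}
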