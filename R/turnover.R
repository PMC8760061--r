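# Dendritic-spine turnover rates from longitudinal two-photon counts.

#' Spine formation, elimination and net-addition rates
#'
#' Per-interval percentages relative to the baseline (day-0) spine count of
#' each identified dendritic segment: `formation = 100 * gained / n_day0`,
#' `elimination = 100 * lost / n_day0`, and net addition is their
#' difference — an identity that holds exactly for every survey because all
#' three share the same denominator.
#'
#' @param surveys a `spine_survey` data frame (columns `segment_id`,
#'   `animal_id`, `genotype`, `n_day0`, `n_gained`, `n_lost`,
#'   `interval_days`), e.g. from [gen_spines()] or [read_spines()].
#' @return the input with columns `formation_pct`, `elimination_pct`,
#'   `net_addition_pct` appended.
#' @examples
#' s <- data.frame(segment_id = "s1", animal_id = "a1", genotype = "WT",
#'                 n_day0 = 40, n_gained = 8, n_lost = 4, interval_days = 3)
#' turnover_rates(s)[, c("formation_pct", "elimination_pct", "net_addition_pct")]
#' @export
turnover_rates <- function(surveys) {
  need <- c("segment_id", "animal_id", "genotype", "n_day0", "n_gained", "n_lost")
  miss <- setdiff(need, names(surveys))
  if (length(miss)) stop("surveys is missing column(s): ", paste(miss, collapse = ", "))
  if (any(surveys$n_day0 <= 0)) {
    stop("n_day0 must be > 0 for every segment (offending: ",
         paste(surveys$segment_id[surveys$n_day0 <= 0], collapse = ", "), ")")
  }
  if (any(surveys$n_gained < 0 | surveys$n_lost < 0)) stop("counts must be >= 0")
  if (any(surveys$n_lost > surveys$n_day0)) {
    stop("n_lost cannot exceed n_day0 (offending: ",
         paste(surveys$segment_id[surveys$n_lost > surveys$n_day0], collapse = ", "), ")")
  }
  surveys$formation_pct <- 100 * surveys$n_gained / surveys$n_day0
  surveys$elimination_pct <- 100 * surveys$n_lost / surveys$n_day0
  surveys$net_addition_pct <- surveys$formation_pct - surveys$elimination_pct
  surveys
}

#' Animal-level turnover comparison between genotypes
#'
#' Aggregates segment rates to per-animal means (animals, not segments, are
#' the replicate unit) and compares the two genotypes for each rate with a
#' two-tailed t test, or a Mann-Whitney test when a Shapiro-Wilk gate
#' rejects normality in either group at `alpha_gate`.
#'
#' @param surveys a `spine_survey` data frame.
#' @param by grouping column (default `"genotype"`).
#' @param alpha_gate significance level of the normality gate.
#' @return list with `animal_means` (one row per animal) and `comparisons`
#'   (one row per rate: `measure`, `method`, `statistic`, `p_value`, group
#'   means).
#' @export
group_turnover <- function(surveys, by = "genotype", alpha_gate = 0.05) {
  rates <- turnover_rates(surveys)
  measures <- c("formation_pct", "elimination_pct", "net_addition_pct")
  animal_means <- stats::aggregate(
    rates[measures],
    by = list(animal_id = rates$animal_id, group = rates[[by]]),
    FUN = mean
  )
  groups <- unique(animal_means$group)
  if (length(groups) != 2L) stop("group_turnover compares exactly two groups")
  if (any(table(animal_means$group) < 2L)) {
    stop("need at least 2 animals per group")
  }
  cmp <- lapply(measures, function(m) {
    a <- animal_means[animal_means$group == groups[1], m]
    b <- animal_means[animal_means$group == groups[2], m]
    normal <- length(a) >= 3 && length(b) >= 3 &&
      stats::sd(a) > 0 && stats::sd(b) > 0 &&
      stats::shapiro.test(a)$p.value >= alpha_gate &&
      stats::shapiro.test(b)$p.value >= alpha_gate
    ht <- if (normal) stats::t.test(a, b) else stats::wilcox.test(a, b, exact = FALSE)
    data.frame(
      measure = m,
      method = if (normal) "t" else "mann_whitney",
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      mean_group1 = mean(a), mean_group2 = mean(b),
      stringsAsFactors = FALSE
    )
  })
  comparisons <- do.call(rbind, cmp)
  comparisons$group1 <- as.character(groups[1])
  comparisons$group2 <- as.character(groups[2])
  list(animal_means = animal_means, comparisons = comparisons)
}
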