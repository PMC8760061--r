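---
title: "Methods: laminar statistics, the spatially adjusted ANOVA, and the companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar statistics, the spatially adjusted ANOVA, and the companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminapipe)
```

## The scientific problem

In studies of cortical development, the phenotype of interest is often
*where* a class of cortical projection neurons settles within a cortical
column. A column imaged in a brain slice is cropped from the ventral
boundary (white matter side) to the pial surface, every labeled cell's
depth is expressed as a fraction of the cortical thickness
(0 = ventral, 1 = pia), and the column is divided into 20 equal bins so
that each slice yields a 20-vector of cell percentages. A genotype that
makes neurons over-migrate shifts these profiles toward the pia; the
statistical task is to decide whether the genotype changes the laminar
distribution, and in which bins.

`laminapipe` implements that quantification (bin profiles, mean laminar
positions, depth densities and cumulative distributions), the
distribution-comparison tests used alongside it (a permutation test for
medians and the k-sample Anderson–Darling test), and the centrepiece: a
**spatially adjusted two-way ANOVA** of bin profiles. It also carries the
molecular companions of such a study — gene-set overlap enrichment for a
differentially-expressed (DEX) gene list, a thresholded Pearson
co-expression network with degree centrality, and dendritic-spine
turnover rates — plus seeded synthetic-data generators so every stage is
testable without access to the original images or sequencing data.

## Laminar descriptive statistics

- **Bins** are half-open, `[(i-1)/20, i/20)`, indexed ventral → pial;
  depth exactly 1.0 is assigned to bin 20 rather than opening a 21st bin.
  With this orientation the two bins abutting the marginal zone are bins
  19–20. An empty slice is an error, not a zero profile: a bin
  distribution of nothing is undefined.
- **Mean laminar position** is `100 * mean(depth_fraction)` — on synthetic
  data with a planted shift `delta` the KO−WT difference recovers
  `100 * delta`.
- **Depth density** is a Gaussian kernel estimate with Silverman's
  bandwidth, corrected for the bounded support by sample reflection at 0
  and 1 so the estimate integrates to ≈ 1 on `[0, 1]`. The object exposes
  the mode (`argmax`) and its height (`max`) as fields, since bar-style
  summaries of the density maximum are a common figure element; no
  particular rendering is imposed. The numerically integrated density
  tracks the empirical CDF to within a few percent sup-norm at realistic
  sample sizes (this is a tested invariant).
- **The ECDF** is the right-continuous step function
  `P(depth <= x)`.

### Permutation test for medians

The statistic is `|median(A) - median(B)|`. When the number of
assignments `choose(nA + nB, nA)` is at most `n_perm`, all assignments
are enumerated and the p-value is the exact proportion at least as
extreme as the observed split; otherwise `n_perm` random reassignments
are drawn and the `+1`-corrected estimate is reported, so p is never
exactly zero. Whether cells or slices are the exchangeable unit is a
modelling choice the data do not decide for you; the function takes
plain numeric vectors, so cell-level permutation is what you get by
passing cell depths (the default reading) and a slice-level test is one
`tapply(..., mean)` away. With more than two genotypes, run the pairwise
tests and Bonferroni-correct by the number of pairs.

### k-sample Anderson–Darling test

The midrank (tie-aware) version of the Scholz–Stephens statistic,
standardized by its exact permutation variance. The p-value is
interpolated on the published critical-value surface, which covers
significance levels 0.25 down to 0.001; outside that range the p-value
is clamped to the nearest bound, which is ample for gate-style use. No
installed R package provides this test, so it is implemented here; the
test suite pins the statistic and p-value to an independent reference
implementation on fixed fixtures and cross-checks the p-value against a
permutation null of the same statistic.

## The spatially adjusted two-way ANOVA

The response is the stack of per-slice bin percentages with crossed
factors `genotype` and `bin`; each slice is one replicate profile.
Sums of squares are **type II**, because slice counts per genotype are
typically unbalanced. The pipeline:

1. **OLS factorial fit**, residuals kept for diagnostics.
2. **Assumption gates** (reported always, acted on at `alpha_gate`,
   default 0.05): Shapiro–Wilk on residuals for normality;
   Levene (Brown–Forsythe, median-centred — the robust default) across
   genotype×bin cells for homoscedasticity; and **Moran's I** of the
   residuals against **chain-contiguity weights** for independence.
   Adjacent bins of the same column are neighbours (1, else 0), blocks
   are assembled per slice — bins are spatially contiguous only within
   their own column — and rows are normalized to sum to 1. Moran
   significance uses permutation (default 999 draws, one-sided for
   positive autocorrelation) rather than the normal approximation,
   because the per-column chains are short; the exact enumeration takes
   over automatically when `n!` is small enough.
3. **Spatial filtering.** If the Moran gate fires, the spatial lag model
   `y = rho W y + X beta + eps` is fitted by maximum likelihood:
   `log|I - rho W|` comes from the eigenvalues of `W` (computed once per
   20×20 block, since `W` is block-diagonal with identical blocks), the
   concentrated RSS is an exact quadratic in `rho`, and `rho` is searched
   on `(1/min(lambda) + 1e-6, 1 - 1e-6)`. The analysis then proceeds on
   the filtered response `y - rho W y`, from which the autocorrelation has
   been removed — filtering rather than embedding `W y` as a regressor,
   so the factorial design and its F tests stay intact. At `rho = 0` the
   lag likelihood equals the OLS likelihood and the filtered response is
   `y`, so the branch degenerates cleanly.
4. **Permutation F tests.** If the Shapiro gate fires, F p-values come
   from permutation instead of the F distribution. The permutations are
   *restricted to the replicate hierarchy*: for the genotype and
   interaction terms, whole slice profiles are reassigned across
   genotypes; for the bin term, bins are shuffled within slices. The
   design was genuinely open here, and the obvious alternative —
   unrestricted permutation of all observations — was implemented first
   and measurably fails: bin percentages are multinomial, so per-bin
   variances differ by orders of magnitude between densely and sparsely
   populated bins, the interaction SS behaves like a weighted chi-square
   with far fewer effective degrees of freedom than `(G-1)(B-1)`, and an
   iid-homoscedastic permutation reference under-estimates its tail
   (measured type-I error ≈ 0.20 at nominal 0.05). Slice-level
   reassignment makes the genotype/interaction reference distribution
   exact under the null, because slices are the exchangeable unit
   whatever the within-profile variance structure.
5. **Post hoc:** per-bin genotype contrasts (Welch t by default,
   Wilcoxon optionally) on the analyzed response, Bonferroni-corrected by
   the number of bins (`p_adj = min(1, 20 * p_raw)` for 20 bins).

The branch actually taken — `classical`, `permutation`,
`spatial_filtered`, or `spatial_filtered_permutation` — is a
deterministic function of the gate p-values and is recorded in the
result, together with all gate p-values even when a branch is skipped.
When both gates fire, the response is filtered first and the filtered
response is permuted; this ordering is flagged in the output via the
branch label.

### Compositional degrees of freedom

Each slice's 20 percentages sum to exactly 100, so every slice-deviation
vector lies in a 19-dimensional subspace and the residual space has
dimension `(B-1)(S-G)`, not `B(S-G)`. Using the naive count inflates the
interaction F by a factor `B/(B-1)` and pushes the type-I error above
nominal. `adjusted_anova()` detects constant row sums and corrects the
residual degrees of freedom; the correction is exact for unfiltered
profiles and a very close approximation after spatial filtering. A
genotype *main* effect is structurally absent from compositional
profiles (every slice averages 5% per bin), which is why the interaction
is the scientifically informative term.

## Gene-set overlap enrichment

Identifiers are upper-cased and whitespace-stripped before matching;
both the DEX list and each annotation set are intersected with the
expressed-gene universe (out-of-universe members are counted and
reported, never silently used). For an overlap of `k` of the `n` DEX
genes with a set of `K` of the `N` universe genes:

- `p_binomial`: upper tail of `Binomial(n, K/N)` — enrichment is the
  only alternative of interest, so tests are one-sided;
- `p_hypergeometric`: the exact without-replacement tail;
- `p_permutation`: `R` random `n`-subsets of the universe (default
  1000), `+1`-corrected. This resampling null *is* the hypergeometric
  distribution, so the two agree as `R` grows — a tested invariant.
  Optionally the set can be redrawn too (`two_way = TRUE`); this second
  randomization is off by default since the annotation sets are fixed
  external references.

Benjamini–Hochberg adjustment is applied to the binomial p-values across
the sets of one report (the binomial test being the primary test, the
others its checks). `dex_tally()` carries the trivial but error-prone
bookkeeping of DEX-list totals (down + up, total − generic =
layer-enriched).

## Co-expression network

Pairwise Pearson correlation on `log2(RPKM + 1)`, with an edge wherever
the *signed* correlation reaches the threshold (default `r >= 0.7`) —
correlation windows like "0.7 to 1" imply positive co-expression, so
anti-correlated pairs never connect. Zero-variance (silent) genes are
dropped with a report rather than failing the run. Degree centrality is
the raw neighbour count (node sizes in figures scale with the count, so
no normalization), and edge display weights rescale `r` linearly from a
window `[w_min_r, 1]` (default 0.5) to `[0, 1]`. Columns of the
expression matrix are treated as exchangeable samples; any within-donor
averaging is upstream of this package.

## Spine turnover

Rates are per-interval percentages of the day-0 spine count of each
identified segment: this baseline denominator is the only convention
under which `net = formation − elimination` holds as an identity, which
the code enforces and the tests check exactly. Rates are not rescaled
per day; `interval_days` is carried so a caller can rescale. Group
comparisons aggregate to per-animal means first — animals, not
segments, are the replicate unit — then use a two-tailed t test, or
Mann–Whitney when a Shapiro–Wilk gate rejects normality in either group.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their config (including the seed);
reruns are bit-identical.

- **Cell positions** (`gen_columns()`): a truncated-Gaussian mixture
  over layers, sampled by rejection within `[0, 1]` — matching the
  unimodal per-layer bands of real immunostained columns without heavy
  tails. The genotype effect is an additive shift of all layer centers
  toward the pia (clipped to the support): the simplest encoding of
  superficial over-migration. Animal- and slice-level Gaussian
  intercepts on the shift emulate the replicate hierarchy. The defaults
  (one dominant band at depth 0.45, sd 0.08, weight 0.85 over a diffuse
  background; `WT = 0, KO = +0.05` shifts; 5 animals × 5 slices × 150
  cells; hierarchy sds 0.005/0.01) are one fixed, realistic
  configuration — per-layer spreads are free parameters of the config,
  not claims about any particular dataset.
- **Gene universe** (`gen_gene_universe()`): the DEX/set overlap count
  is drawn `Binomial(n, fold·K/N)` and members filled in accordingly, so
  the expected overlap is exactly `fold·n·K/N`; `fold = 1` is the
  random-sampling null, `fold = 0` forces disjointness.
- **Expression** (`gen_expression()`): a one-factor model per module on
  the log2 scale with loading `noise_sd * sqrt(r/(1-r))`, so the
  within-module correlation targets `r` exactly; gene means are drawn in
  `[2, 6]` so the nonnegativity floor is rarely active.
- **Spine surveys** (`gen_spines()`): animal-level net-addition rates
  (Gaussian, sd 2% by default) with Poisson baselines and binomial
  gained/lost counts per segment, so integer-count sampling noise rides
  on the planted animal effect.

What the generators do **not** emulate: imaging artefacts, segmentation
errors, the ectopic marginal-zone phenotype, read-level RNA-seq noise,
or donor structure in expression columns. Passing tests demonstrate that
the estimators recover what was planted under the stated statistical
structure; they do not validate image processing or upstream
quantification.

## Calibration experiments and problem sizes

The operating-characteristic experiments (`anova_rejection_rate()`,
`lag_recovery()`, `turnover_power()`) define the package's
parameter-recovery evidence:

- **Type-I error**: 500 simulated studies from `calibration_config()`
  with zero genotype shift and hierarchy sds set to 0 — the fully
  exchangeable null, which is the null hypothesis of the factorial F
  test. (With animal-level intercepts switched on, slices within an
  animal are dependent and the classical test targets a different null;
  that setting is available but is a mixed-model question outside this
  package's scope.) Measured rate ≈ 0.05–0.06, consistent with the
  attained level `24/500 ≈ 0.048` of a `+1`-corrected permutation test
  used at 499 draws.
- **Power**: 200 studies with a planted `+0.05` shift (one bin width) at
  25 slices per genotype — power ≈ 1, and the per-bin post hoc localizes
  the shift to the flanks of the band.
- **Spatial lag recovery**: 100 fits at `rho = 0.6` and at `rho = 0` on
  20 columns × 20 bins (n = 400).
- The experiments use 499 ANOVA / 199 Moran permutations per run —
  resolution to spare at the 0.05 decision point across hundreds of
  replicates — while single-analysis defaults stay at 5000/999.

## Numerical choices and degenerate inputs

- Permutation p-values use the `+1` correction except under exhaustive
  enumeration, where the exact proportion (observed assignment included)
  is reported; comparisons use a `1e-12` slack so ties in the statistic
  are counted as "as extreme".
- Constant responses, empty slices, empty design cells, zero-variance
  Moran inputs, and `n_day0 = 0` segments are errors with the offending
  unit named — silent zeros would propagate as fake certainty.
- Per-bin post hoc contrasts on two constant, equal groups return p = 1.
- `rho` estimates at the edge of the feasible interval raise a warning
  with the bracket, as boundary solutions usually mean a mis-ordered
  response vector.
- Readers validate eagerly (depths in range, counts consistent, columns
  present) and report offending line numbers.

## Known limitations

- The spatial model is the lag filter only — no spatial error model or
  CAR/SAR variants, and no mixed-effects alternative for animal-level
  dependence.
- The Anderson–Darling p-value is interpolated, hence clamped to
  `[0.001, 0.25]`; report the statistic when more resolution matters.
- Compositional df correction after spatial filtering is approximate
  (the filtered profiles' row sums are no longer exactly constant).
- Ortholog mapping, GO enrichment, module detection (WGCNA) and
  image-derived quantification are all upstream inputs, not package
  functionality.
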