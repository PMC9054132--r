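---
title: "Quantifying chromosomal instability: model, statistics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosomal instability: model, statistics and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinabc)
```

## The problem

The rate of chromosome mis-segregation — the operational measure of
chromosomal instability (CIN) — cannot be read directly from the karyotype
heterogeneity of a cell population. Selection removes (or favors) aneuploid
cells as fast as mis-segregation creates them, so two tumors with the same
observed diversity can have very different underlying rates. `cinabc`
treats the rate `P_misseg` and the selection strength `S` as parameters of
a generative model, simulates that model across a prior grid, and infers
both parameters jointly from an observed population by likelihood-free
(rejection ABC) inference, using summary statistics that retain information
about selection: phylogenetic topology alongside raw heterogeneity.

## The agent-based model

Each cell is an integer vector of 46 chromosome-arm copy numbers
(`1p … 22q, Xp, Xq`; chromosome Y is not modeled). The model's assumptions
are deliberately minimal:

* Division always yields two daughters; each chromosome copy of the parent
  mis-segregates independently with probability `P_misseg` per division,
  and no chromosome is more or less likely to mis-segregate than another.
* A mis-segregated copy transfers whole with probability `1 − P_break`, or
  breaks, transferring exactly one randomly chosen arm (a reciprocal
  arm-level alteration), with probability `P_break`. The gaining daughter
  is chosen equiprobably and independently per event. Arm-wise,
  `daughter_a + daughter_b = 2 × parent` always holds.
* A cell dies when any arm's copy number reaches 0 or exceeds 6 (both
  bounds configurable).

Because the state is arm-level but mis-segregation is a whole-chromosome
event, the number of Bernoulli trials for a chromosome is the maximum of
its two arm counts once breaks have made them diverge, and a transfer moves
only the arms that copy actually carries. This keeps the expected events
per division equal to `P_misseg ×` (total chromosome copies) — 46 trials
for a diploid, 92 for a tetraploid — which is the calculus used throughout:
`P_misseg = 0.05` is ≈2.3 events per diploid division, 0.001 is ≈0.046.

### Selection

Per-arm base scores are embedded (`load_arm_scores()`): gene-abundance
scores `f_c` (each arm's share of all genes; stabilizing selection) and
driver-density `TOE_c` scores (net tumor-suppressor / oncogene / essential
gene balance; directional selection, possibly negative). Each column sums
to 1, so a euploid cell at the population mean ploidy has fitness 1 under
every model; the embedded columns are renormalized at load to remove the
≤1e-6 residue of the printed 8-decimal precision, on which the euploid
invariant depends. Contextual per-arm scores are recomputed every step
against the *current* population mean ploidy `X̄_p` (not the founder
ploidy — the reference drifts as the population does):

* abundance: `CFS_c = f_c (1 − |n_c − X̄_p| / X̄_p)`
* driver: `CFS_c = n_c TOE_c / X̄_p`
* hybrid: the arm-wise mean of the two, so `F_hyb = (F_GA + F_TOE)/2`
* neutral: `F = 1` regardless of karyotype.

Selection strength enters as `F_M = F^S`, `S ∈ [0, 100]` in practice:
`S = 0` switches selection off, `S = 50` reduces a cell at `F = 0.954`
(an otherwise-diploid cell trisomic for both chromosome-1 arms in a
diploid-mean population) to `F_M ≈ 0.097`, a tenth of euploid fitness.
Driver and hybrid `F` can be negative for extreme karyotypes; since a real
exponent of a negative base is undefined, such cells are assigned
`F_M = 0` — they simply never divide. This is a package choice at a point
the model leaves open, and the conservative one.

### Population dynamics

Two regimes bound realistic growth behavior:

* **Exponential pseudo-Moran** (default): per step, fitness is evaluated,
  non-viable cells are culled, and once the census reaches the cap
  (default 3000 cells) a uniformly random half is deleted. Each surviving
  cell then divides iff `F_M > R ~ U[0, 2]`, so a euploid population
  divides at rate 0.5 per step and grows by ×1.5 until the cap regime;
  `F_M ≥ 2` divides every step. The `U[0, 2]` width is what makes the
  stated euploid division probability of 0.5 come out, and is used here
  even though a narrower draw appears in some descriptions of this rule.
* **Approximated Wright-Fisher** (constant size, default 4500): every cell
  divides every step; after viability culling, cells die with probability
  `min(1, 1/(F^S + 0.001))/5` (`R ~ U[0, 5]` rule), giving a ≈19.98%
  baseline at `F = 1`; the survivors' per-arm marginal copy-number
  distributions are stored and the next generation is drawn from them,
  arm-independently, at full size.

Extinction is a flagged terminal record, never an error, so parameter
sweeps don't abort. Exported censuses (snapshots, final population)
contain living cells only: daughters whose karyotype already violates the
viability bounds would be culled at the start of the next step and are
never observed alive. One seeded RNG drives each simulation with a fixed
draw order, so a seed plus parameters reproduces a trajectory exactly.

## Summary statistics

Given a cells × features matrix (46 arms or 23 chromosomes — the level is
tracked and never silently mixed):

* **aneuploidy** — sample variance within each cell's karyotype, averaged
  over cells;
* **MKV** — per-feature sample variance across cells, averaged over
  features, divided by mean ploidy (doubling every copy number therefore
  doubles MKV: variance ×4, ploidy ×2);
* **tree topology** — phylogenies are Euclidean-distance,
  complete-linkage dendrograms (`stats::hclust`, deterministic for a given
  input order, which is the tie-break rule for the zero-distance ties that
  clonal simulated populations produce). From the rooted binary tree we
  count cherries and pitchforks (normalized by tip count) and compute
  Colless imbalance normalized by its caterpillar maximum
  `(n−1)(n−2)/2` and Sackin by `n(n+1)/2 − 1`, so both sit in `[0, 1]`.
  Topology counts are validated in the test suite against brute-force
  enumeration of every binary shape with ≤6 tips.

All variances use the `n − 1` estimator (R's `var()`), chosen to match the
statistical environment the original analyses of this kind run in, and
applied identically to simulated and observed data so the two sides of the
ABC comparison always agree.

The default ABC feature set is `aneuploidy, mkv, colless, cherries`:
pitchforks carry little extra information and Sackin tracks Colless
closely, but both are computed and reported.

## Rejection ABC

`build_prior_library()` runs the simulator over a uniform parameter grid
(the defaults mirror the ranges `P_misseg ∈ [0, 0.001 … 0.05]`,
`S ∈ [0, 2 … 100]`, snapshot steps 40–80 used in practice), sampling a
configurable number of cells (200 by default) per snapshot.
`infer_cin()` standardizes each feature by its median absolute deviation
across the library (the behavior of the standard ABC tooling; a raw-scale
switch is provided), computes Euclidean distances to the observed feature
vector, and accepts the `T`-quantile nearest records (`T = 0.05` by
default; `ceiling(T × N)` records). The posterior point estimate is the
mean of accepted values with standard error `sd/√n`. `T = 1` recovers the
prior means exactly, and an observation identical to a library record
self-matches at distance 0 — both are frozen as tests.

`model_selection()` pools records across selection models, accepts the
same quantile, and reports each model's share of the accepted set (PP) and
its Bayes factor against neutral selection (`BF > 5` flagged substantial;
`PP(neutral) = 0` reports `Inf` rather than failing).
`sliding_window_inference()` repeats inference over 11-step windows of the
prior's time axis to locate where the posterior stabilizes, and
`sample_size_analysis()` reports percent accuracy
`100 (1 − |p̂ − p|/p)` — with the posterior mean as `p̂`, a definition the
package documents rather than inherits — across subsample sizes.

## The synthetic-data generator

`generate_fixture()` emulates the package's observed-data modalities so
every stage is testable without sequencing data:

* **acute_missegregation** — an acute perturbation experiment: `n` copies
  of a modal karyotype each undergo exactly one division at a high
  per-copy rate, one daughter is kept per division (the sequenced cell),
  and no selection or viability culling intervenes, matching a ~48-hour
  window that precedes selection. The bundled
  `modal_karyotype_44()` reference (a synthetic sub-diploid karyotype, 44
  chromosomes) stands in for a near-diploid cancer line. One modeling
  choice matters here: the gain/loss direction is drawn once per
  chromosome per division, so sister copies co-segregate — as they tend
  to on the multipolar spindles such perturbations induce — and the kept
  daughter's absolute deviation from the modal karyotype equals its event
  count. Under fully independent per-copy directions, two events on the
  same chromosome would cancel in the kept daughter about half the time
  and the population mean deviation would under-report the event rate by
  ~20% at high rates; the co-segregation rule keeps the generator
  consistent with the inversion `P_misseg = deviation / modal copies`
  (e.g. 18.5 observed mis-segregations over 44 chromosomes ↔
  `P_misseg ≈ 0.42`) that acute experiments are analyzed with. The
  steady-state simulator keeps fully independent per-event directions.
* **steady_state_population** — wraps `run_simulation()` and samples the
  final census (arm-level).
* **clonal** — identical rows; note a clonal population of a non-uniform
  modal karyotype has MKV 0 but nonzero aneuploidy (the within-cell
  variance of the karyotype itself).

What the generator does **not** emulate: sequencing noise and copy-number
calling error, doublets, clonal spatial structure, biased (non-random)
mis-segregation, and whole-genome doubling as an explicit event
(tetraploid founders are the supported route). Passing tests on these
fixtures therefore establishes the correctness of the machinery and the
internal consistency of the calculus, not the fidelity of any particular
biological dataset.

## Numerical choices and degenerate inputs

* The embedded score table's two X-arm rows are taken as Xp and Xq,
  giving the 46 distinct arms the score sums require.
* Score columns renormalized to sum exactly 1 (printed rounding ≤1e-6).
* `F ≤ 0 → F_M = 0`; `S = 0 → F_M = 1` for any `F > 0`.
* Breakage trial: the break decision is its own Bernoulli(`P_break`) draw
  after a mis-segregation, one arm chosen uniformly among those present.
* Random halving deletes `floor(n/2)` cells; the census surviving the cap
  check is therefore always below the cap, and under neutral growth the
  curve's effective ceiling sits just below it.
* Dendrogram ties (identical karyotypes) resolve by `hclust`'s
  deterministic candidate order; permuting input rows can permute tip
  labels of zero-height subtrees but changes no statistic away from ties.
* `collapse_to_chromosomes()` mean rule uses round-half-to-even (R's
  `round`), so arms `(2,3)` collapse to 2; `min` and `p-arm` rules are
  available, and cross-level ABC comparisons are refused rather than
  silently reconciled.
* Trees are rooted (the dendrogram root) for all statistics; statistics
  need ≥3 tips (topology) / ≥4 cells (full summary).
* MAD standardization falls back to SD, then to 1, for degenerate
  features.

## Problem sizes

The test suite and examples run at deliberately reduced scale so the whole
suite completes in well under a minute of simulation time: populations
capped at 300–1000 cells, 5–60 steps, prior grids of 12–25 points with 2
replicates, 200-cell samples, Monte-Carlo checks at 10⁴ divisions. These
sizes were chosen as the smallest at which the stochastic assertions have
comfortable margins (3 standard errors or better); the full-scale presets
(3000-cell cap, 4500-cell Wright-Fisher, 100-step runs, dense grids with
3–8 replicates) are the package defaults and run unchanged, just longer.

## Known limitations

* Inference quality is bounded by the prior library: a sparse grid
  quantizes the posterior (visible in the README example, where 3 accepted
  records carry the estimate). Dense grids and more replicates are the
  remedy, at linear cost.
* The fitness models are coarse approximations — arm-level, additive
  across arms, time-invariant — and `S` is a single global exponent.
* Wright-Fisher re-initiation resamples arms independently, discarding
  arm-arm linkage within cells between generations; it preserves each
  arm's marginal distribution (tested) but not joint structure.
* The per-chromosome ↔ per-division rate conversions assume one
  chromosome per observed error; `predicted_error_incidence()` and
  `approximate_rate_from_frequency()` make that assumption explicit.
* No SNV phylogenies, no bootstrap support, no spatial or
  microenvironmental structure.
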