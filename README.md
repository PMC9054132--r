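# cinabc

Quantifying chromosomal instability (CIN) from intratumoral karyotype
diversity.

Chromosome mis-segregation during mitosis produces cell-to-cell karyotype
heterogeneity, but the heterogeneity observed in a tumor is not a direct
readout of the mis-segregation rate: selection against (or for) particular
aneuploidies continually reshapes the population. `cinabc` is for
researchers who have single-cell copy-number profiles (low-coverage
scDNAseq-style integer calls per chromosome or chromosome arm) and want a
selection-corrected, quantitative estimate of CIN. It combines:

1. **An agent-based simulator** of karyotype evolution. Each cell carries an
   integer copy number for each of the 46 chromosome arms (1p…22q, Xp, Xq).
   At division, every chromosome copy mis-segregates independently with
   probability `P_misseg` (optionally breaking into a single-arm event with
   probability `P_break`); daughters are reciprocal, so material is
   conserved. Cells die when any arm reaches 0 or exceeds 6 copies.
   Selection acts through a cellular fitness
   `F = Σ_c CFS_c`, with per-arm contextual fitness scores under four
   models — gene abundance (stabilizing:
   `CFS_c = f_c (1 − |n_c − X̄_p| / X̄_p)`), driver density (directional:
   `CFS_c = n_c TOE_c / X̄_p`), their hybrid average, and neutral (`F = 1`)
   — scaled by a selection exponent: `F_M = F^S`. Population size is
   limited by exponential pseudo-Moran dynamics (random halving at a
   3000-cell cap; division iff `F_M > R ~ U[0,2]`) or constant-size
   approximated Wright-Fisher dynamics (4500 cells; fitness-dependent death
   `1/(F^S + 0.001) > R ~ U[0,5]`, ≈20% baseline).
2. **Summary statistics** of a cell population: aneuploidy (within-cell
   variance), MKV (mean karyotype variance across cells, normalized to mean
   ploidy), and the topology of the Euclidean/complete-linkage phylogeny —
   normalized Colless and Sackin imbalance, cherries and pitchforks.
3. **Rejection-sampling approximate Bayesian computation**: observed
   statistics are compared with a library of simulated ones; the 5% nearest
   parameter sets (standardized Euclidean distance) form the posterior for
   `(P_misseg, S)`. Model choice uses posterior model probabilities and
   Bayes factors against neutral selection; helpers tune the prior time-step
   window, check sample-size sufficiency, and convert between per-chromosome
   rates and observed error frequencies.

## Worked example

Simulate a population with moderate CIN under hybrid selection, summarize
it, and infer the rate back with ABC:

```r
library(cinabc)

sim <- run_simulation(sim_params(p_misseg = 0.02, S = 25,
  selection_model = "hybrid", n_steps = 60, pop_cap = 1000, seed = 11))
sim
#> Agent-based CIN simulation (pseudo_moran growth, hybrid selection)
#>   P_misseg = 0.02, P_break = 0, S = 25, founder ploidy 2
#>   60 step(s) run; final population 769 cell(s)

cells <- sample_cells(sim, 200)
summarize_population(cells)
#>   aneuploidy       mkv  colless     sackin cherries pitchforks mean_ploidy n_cells
#> 1   2.105739 0.3282306 0.024415 0.08383502    0.365       0.17     3.06913     200

grid <- expand.grid(p_misseg = c(0.005, 0.01, 0.02, 0.04), S = c(0, 25, 50))
lib <- build_prior_library(grid, replicates = 2, snapshot_steps = 60L,
  base_params = sim_params(selection_model = "hybrid", pop_cap = 1000L),
  n_cells = 200, seed = 99)
infer_cin(cells, lib, tolerance = 0.1)
#> Rejection-ABC inference of chromosomal instability
#>   library: 24 records; tolerance 0.1 -> 3 accepted
#>   P_misseg = 0.03333 (SE 0.00667)
#>   S        = 33.33 (SE 8.33)
```

The population, simulated at `P_misseg = 0.02` (about one mis-segregation
per diploid division) under substantial selection, has drifted toward a
near-triploid mean ploidy with high inter- and intra-karyotype variance;
the posterior mean recovers the mis-segregation rate to well within a
factor of two of the truth even from this deliberately small prior library,
and the selection estimate brackets the true `S = 25`. Larger grids and
replicate counts tighten both.

Observed data enter the same way: `read_copy_number_matrix()` loads a
delimited cells × features table (arm-level `1p,1q,…` or chromosome-level
`1..22,X` headers), and `infer_cin(matrix, library)` refuses mismatched
feature levels (collapse arm-level simulations with
`collapse_to_chromosomes()`). A thin command-line wrapper
(`inst/cli/cin.R`) exposes `simulate`, `stats`, `tree`, `fixture`, `infer`,
`model-select`, `window-scan` and `subsample-analysis` subcommands.

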