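---
title: "Methods: many-objective tag SNP selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: many-objective tag SNP selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagsnp)
```

## The model

A haplotype block is an `m × n` binary matrix: `m` distinct haplotype
patterns (allele classes) over `n` biallelic SNPs. A candidate tag set is
a binary chromosome `c` of length `n`. For every unordered pattern pair
`(i, j)` the *pairwise distinguish count* `D_ij(c)` is the number of
selected SNPs at which the two patterns differ; because alleles are
binary, `D_ij` coincides entrywise with the pairwise Hamming distance
restricted to the selected SNPs (the package computes both through
independent code paths and asserts the identity in its tests).

Four objectives are evaluated from one pass over the `C(m,2)` counts:

* **f1, compactness** (min): `sum(c)` — genotyping cost.
* **f2, tolerance** (max): `min_ij D_ij`. A value `v ≥ 1` means the set
  distinguishes every pair and still works after any `v − 1` genotypes go
  missing. `f2 = 0` flags a selection that fails to separate some pair;
  it is a legal objective value, not a constraint violation — dominance
  pressure removes such solutions naturally, and keeping them makes the
  search space closed under mutation (the empty selection evaluates to
  `(0, 0, 0, 0)`).
* **f3, dissimilarity** (max): mean of the pairwise distances.
* **f4, balance** (min): variance of the pairwise distances, with divisor
  `C(m,2)` (population variance) exactly as the defining formula is
  printed, not `C(m,2) − 1`.

Useful bounds, all property-tested: `0 ≤ f2 ≤ f1 ≤ n`, `f3 ≤ f1`,
`f4 ≥ 0`, and adding a SNP never decreases any `D_ij`.

## Search strategies

All four optimizers share one run contract (`run_ga()`): binary encoding,
maximization objectives negated internally, results reported on the
original scales, and full determinism for a fixed `(block, config, seed)`
triple — one RNG stream per run, with sub-seeds drawn for initialization
and search, so either stage is independently reproducible.

* **NSGA-II** — fast nondominated sorting plus crowding-distance
  truncation of the combined parent/offspring population.
* **SPEA2** — strength/raw fitness with k-nearest-neighbor density, a
  fixed-size archive, and lexicographic nearest-neighbor truncation. Two
  implementation notes: exact duplicates in objective space sit at
  distance zero and are removed first by the canonical truncation rule,
  so the implementation collapses them directly before running the
  distance-based loop (a large constant-factor saving in plain R); and
  sorted distance vectors are only materialized for candidates tied on
  their first nearest neighbor.
* **NSGA-III** — nondominated sorting with reference-direction niching.
  Reference directions are a Das–Dennis simplex lattice on the four
  objectives with the smallest partition count whose size reaches the
  population size (e.g. p = 9, 220 directions, for population 200).
  Normalization uses the ideal point and achievement-scalarizing extreme
  points, falling back to the first front's nadir when the extreme-point
  hyperplane is degenerate.
* **MOEA/D** — Tchebycheff decomposition over the same weight lattice
  (thinned deterministically, evenly spaced in lattice order, to exactly
  the population size), neighborhood size 15, both parents drawn from the
  neighborhood, steady-state updates with the canonical replace-on-ties
  rule `g(y) ≤ g(x_j)`, and an adaptively updated ideal point. One
  "generation" is defined as `pop_size` single-offspring updates so
  evaluation budgets match the generational strategies; there is no
  external archive — the final front is extracted from the final
  population.

Variation for the three generational strategies: binary tournament
(Pareto dominance first; rank-sum fitness — the sum over objectives of a
solution's competition rank, ties sharing the minimum rank — as the
secondary key; a seeded coin for full ties), uniform crossover with
`p_c = 0.7`, and bit-flip mutation with `p_m = 1/n`. The rank-sum score
is exposed as `rank_sum_fitness()` and used *only* inside tournaments; it
never replaces Pareto dominance in survival selection, which follows each
strategy's canonical publication.

Defaults mirror the published experimental protocol: population 200,
offspring 200, 500 generations, 5 runs per algorithm × initialization
cell (40 experiments).

## Initialization

Random initialization draws every gene i.i.d. Bernoulli(0.5). Greedy
initialization builds one chromosome per *coverage* target `c`: SNPs are
visited in decreasing distinguishability order (`z(m − z)` for a column
with `z` zeros; ties broken by ascending index) and added only when they
raise some pattern pair whose current count of selected distinguishing
SNPs is below `c` — true greedy set-cover behavior. The sorted-selection
rule could also be read as "add every visited SNP until covered"; both
behaviors are implemented (`skip_noncontributing`), with skipping the
default because it yields strictly more compact covers. Coverage runs
from 1 to `c_max`, the tolerance of the all-ones chromosome (beyond which
saturation is flagged, not errored); remaining population slots are
filled with bit-flip-mutated copies (rate `1/n`) of the coverage
chromosomes, cycled in order, preserving the structured spread that is
the point of the scheme. A block in which some pair is indistinguishable
even by all SNPs cannot be tagged at all; greedy initialization reports
the offending pair and stops.

## Synthetic blocks

Real haplotype blocks have strong column correlation (linkage
disequilibrium), which is exactly what makes distinguishability-sorted
greedy selection informative; i.i.d. Bernoulli columns would not exercise
it. `generate_block()` therefore uses a founder/recombination scheme:
`n_founders` random binary founders (default 3), each pattern a founder
mosaic that switches founder with probability `recomb_rate` per SNP
(default 0.01) and then flips each allele with probability `noise_rate`
(default 0.01). The defaults are the shape used throughout the tests
(tens of patterns, hundreds of SNPs, `c_max` around 20 for
`m = 20, n = 200`) and emulate the scale of the real 1000+-SNP blocks the
method targets. Duplicate rows are resampled under a bounded retry
budget; constant columns are re-randomized when forbidden (the default).
What the generator does *not* emulate: allele-frequency spectra,
recombination hotspots, genotyping error patterns, or population
structure — so a green test on synthetic blocks establishes algorithmic
correctness, not biological performance on any real dataset.

## Front quality measures

Range (summed per-objective spread), SumMin (sum of per-objective
minima) and MinSum (minimum solution-wise sum) operate on objectives
converted to minimization sense (f2 and f3 negated — the only reading
that yields a consistent all-minimization space, since f4 is already a
minimization objective) and min–max normalized to `[0, 1]` with bounds
pooled over *all* fronts under comparison; per-front bounds would make
values incomparable across algorithms, and per-generation traces reuse
the pooled final bounds for the same reason. A degenerate objective
(pooled max = min) maps to 0. `summin ≤ minsum` always, since the
per-objective minima may come from different solutions.

Tolerance rates (`f2/f1`, guarded at `f1 = 0`) and the average-Hamming
measure use raw objective values, where ratios and means keep their
units.

Hypervolume uses the common reference point 1.1 per normalized axis
(configurable). For fronts of at most 14 nondominated points it is exact
by inclusion–exclusion over the `2^k − 1` box intersections; above that a
Monte Carlo estimate with reported standard error takes over, and the
independent Monte Carlo path doubles as a cross-check of the exact one
(agreement within 3 standard errors is asserted in the tests).

## Numerical and design choices

* Duplicate patterns in a block are a hard validation error — allele
  classes are distinct by definition — and duplicate chromosomes are
  allowed inside populations but deduplicated in reported fronts.
* The worked 4×5 example block is used exactly as printed; the prose
  accompanying it elsewhere claims its column 3 equals column 1, which is
  false on the printed matrix (they are complements). The matrix wins.
* Front comparisons in the tests are made in objective space (the set of
  unique objective vectors), the standard meaning of "Pareto front";
  chromosome-level equality is unattainable in principle for MOEA/D,
  whose final population holds one solution per weight vector.
* Rank ties in the rank-sum fitness use competition ranking (ties share
  the minimum rank) — deterministic and order-independent.
* The flat `key: value` configuration format is a deliberate YAML subset
  so no YAML dependency is needed.

## Known limitations

The oracle-equivalence check on small enumerable blocks exposes a real
property of population-bounded evolutionary search: a point that is
nondominated *within the final population or archive* need not be
globally Pareto-optimal. On 6-pattern × 10-SNP blocks, NSGA-II reliably
returns subsets of the enumerated Pareto set, but SPEA2, NSGA-III and
MOEA/D each retain a few locally-nondominated, globally dominated points
on some seeds at every budget tried (population 200, up to 300
generations): instrumentation shows the archive plateauing with a couple
of dominating front vectors simply never produced by variation. The
corresponding acceptance check is asserted as specified and left failing
for those cells rather than weakened; the extreme-point and
worked-example equality checks pass for all four algorithms. At the
published protocol scale (1000+ SNPs) no such oracle exists and fronts
are compared only through the quality measures above.

Runtime scaling in the test suite: oracle comparisons keep the protocol's
population of 200 but run 300 generations instead of 500; the worked 4×5
example uses population 20 / 50 generations. Both scalings are fixed in
the tests and documented here, not tuned per outcome.
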