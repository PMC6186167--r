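---
title: "Models and methods behind mycodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mycodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycodiv)
```

This vignette is the package's own account of its science: the models and
procedures, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions that were genuinely open.

## 1. Trait-based pool selection

**Problem.** A mycorrhizal-type treatment is only interpretable if the AMF
and EMF species pools do not differ systematically in other functional
traits; otherwise any "mycorrhizal type" effect is confounded with growth
strategy.

**Model.** Mixed-type traits (leaf-out date, specific leaf area, maximum
height, wood density, leaf C:N, seed mass are the canonical set; the
package takes any columns) enter a Gower dissimilarity: numeric traits as
range-normalized absolute differences, categorical traits as 0/1
mismatches, averaged over traits observed in both species (pairwise
deletion). Numeric traits with zero range carry no information and are
dropped with a warning; a species missing *all* traits is rejected.
Functional diversity of a pool is Rao's quadratic entropy
$Q = \sum_i \sum_j d_{ij} p_i p_j$ (full double sum, $d_{ii} = 0$), with
equal abundances $p_i = 1/S$ as the default.

**Open choices made here.** The selection objective was open: "most
similar between the groups" could mean minimizing the difference in pool-level
Q, or minimizing raw between-pool trait distance. We minimize the **mean
between-pool pairwise Gower dissimilarity** — it targets the confounding
directly (AMF species should have EMF counterparts with similar traits) —
and report each pool's Q as a diagnostic. With ≤ 12 candidates per type all
$\binom{n_A}{k}\binom{n_E}{k}$ pool pairs are enumerated; beyond that a
seeded random-restart single-swap descent is used (tests confirm it attains
the exhaustive optimum on enumerable instances). Ties break by
lexicographic species labels, so selection is reproducible.

## 2. Design generation

Treatments are the 8 valid cells of richness {1, 2, 4} × mycorrhizal level
{AMF, EMF, Both} — a monoculture has one mycorrhizal type, so (1, Both)
does not exist. Replication rules (all configurable in code, fixed by
default):

| cell | compositions | replicates | plots |
|---|---|---|---|
| 1 × AMF/EMF | each of 10 species | 2 | 20 |
| 2 × AMF, 2 × EMF | all $\binom{5}{2} = 10$ each | 1 | 20 |
| 2 × Both | 10 of the $5 \times 5 = 25$ | 1 | 10 |
| 4 × AMF, 4 × EMF | all $\binom{5}{4} = 5$ each | 2 | 20 |
| 4 × Both | 10 of the $\binom{5}{2}^2 = 100$ | 1 | 10 |

Mixed ("Both") compositions are constrained to an **equal split** across
types (1+1, 2+2): only that split yields 25 and 100 possible mixed
combinations, and it keeps the type contrast orthogonal to richness.
The "10 out of 25 / 100" subsets are found by seeded randomized
backtracking so that **every species occurs exactly** $k \cdot r / S$
times in the cell (2 and 4 here); infeasible targets are rejected up
front.

**Spatial randomization.** The 80 plots split evenly over two blocks
(balanced within treatment), and within each block are placed on a 5 × 8
grid — the grid dimensions were unspecified in the source design, 5 × 8 is
the default and configurable; paths between plots are not modeled — under
two constraints, both read on the 8-cell Moore neighborhood:

* **c1** — no two same-treatment plots are adjacent (orthogonal or
  diagonal contact), "treatment" meaning the richness × mycorrhizal cell;
* **c2** — around any focal plot, no treatment appears more than twice.

Placement is greedy restart sampling: cells are visited in random order
and a feasible treatment (or an empty slot) is drawn uniformly at each;
dead ends trigger a restart. Constraint density at 8 treatments × 5 plots
per block is low, so restarts converge in milliseconds; a standalone
checker (`check_layout()`) re-validates every generated layout and is
itself tested against hand-built violations and an exhaustive brute-force
feasibility oracle. Monoculture replicates of the same species share a
treatment cell, so c1 applies to them too.

Note one corner the oracle settles: on a *full* 3 × 3 grid, three
treatments × three plots are provably infeasible under c1 — the center
cell touches all eight others — so the generator's error path, not its
success path, is the correct behavior there.

**Planting pattern.** Within a plot, 140 trees on a 14 × 10 grid at 1 m
spacing (the only near-square integer grid with 140 cells containing an
8 × 8 core; the central 64 positions are the measurement core). Cells are
walked in boustrophedon order with species assigned cyclically: this gives
exact per-species counts (140 / richness) and — because consecutive walk
indices of orthogonal neighbors differ by an odd number — no orthogonally
adjacent conspecifics at richness 2 or 4. The true planting geometry of
the field experiment is not recoverable from its description; this
convention is a documented stand-in.

## 3. The resource-niche simulator

**What it emulates.** The conceptual model behind the experiment: species
occupy partially overlapping regions of a resource space; mixtures of
species with *different* mycorrhizal types cover more of that space with
less overlap, and resource-use complementarity translates into
overyielding. The simulator makes that testable: every species is a disk
(center, radius) in the unit box, a community captures the union of its
disks, and cells covered by $k$ members are split $1/k$ each — the
simplest symmetric competition rule consistent with "overlap = competition
for the same resources".

Capture is computed by grid quadrature (midpoint rule, default 200 cells
per axis, error $O(1/R)$); an analytic circle/lens oracle validates it in
the tests. Conservation (captures sum to the union area) holds exactly at
any resolution by construction.

**Growth law.** Per-capita share is capture divided by planted density
($140/\text{richness}$ trees), and each living tree grows
$\Delta d = \text{rate} \cdot \text{share} \cdot e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$, cm per year. Noise is multiplicative
lognormal because diameters are positive and increment distributions are
right-skewed. Growth responds to *per-capita* share so density effects
appear: plots hold 140 trees regardless of richness.

**Scenarios and default knobs.** The source framework quantifies nothing
about niche geometry, so all scenario parameters are free knobs, chosen
once to be ecologically plausible and not revisited:

| parameter | default | why |
|---|---|---|
| disk radius | 0.10 | ≈ 3% of the resource box per species; 5 within-type disks fit their region with moderate overlap |
| AMF / EMF center regions | x ∈ [0.05, 0.40] / [0.60, 0.95] | separated by 2 × radius, so between-type disks are disjoint under complementarity |
| base rate | 2500 cm per unit per-capita capture · yr | gives ≈ 0.6 cm/yr monoculture increments, realistic for young temperate broadleaves |
| dominant advantage (selection) | 8 × rate, radius 0.35 | makes the dominant's monoculture yield exceed the rest combined, the regime where selection outweighs complementarity |
| growth noise σ | 0.1 | ≈ 10% CV of annual increment |
| mortality | 0.02 / yr | few-percent establishment losses |
| planting diameter | median 1.0 cm, lognormal σ 0.1 | nursery sapling at 5 cm stem height |

*Scenario signatures* (derivable from the capture rule, and verified by the
acceptance suite): with disjoint niches and equal rates a species keeps its
monoculture capture while its density drops, so relative yields approach 1
and CE > 0 with SE ≈ 0; with nested niches and one dominant species the
dominant keeps its exclusive annulus while subordinates shrink
proportionally, so |SE| exceeds |CE| on average; with identical niches
mixtures replicate monocultures and all effects vanish.

**What it does not emulate** — and hence what a green test does *not*
establish about real forests: no mycorrhizal colonization dynamics or
hyphal networks (only direct nutrient supply), no plant–soil feedbacks, no
light competition or size asymmetry, no spatial interaction between
neighboring trees (capture is a plot-level quantity), no temporal niche
dynamics, and mortality is independent of competition. Green scenario
tests establish that the *pipeline* recovers known ground truth, not that
real tree communities behave this way.

## 4. Productivity and additive partitioning

Productivity is the annualized basal-area increment between two inventory
years: per tree $BA = \pi (d/200)^2$ m² (diameter in cm), summed over core
trees alive at the later year; trees dead by then contribute zero — plot
productivity is the estimand, so losses count against it rather than being
dropped. Fractional years are supported because real measurement windows
(e.g. 20 months) rarely align with calendar years. Negative increments of
living trees are kept with a warning (measurement noise does that in real
inventories).

The monoculture reference $M_i$ is the mean over the species' two
monoculture plots (block-specific references were considered and rejected
for simplicity — they halve the reference sample). The partition follows
the classical additive decomposition with the **population covariance**
(divide by $N$), which is what makes $NE = CE + SE$ an identity rather
than an approximation; the tests enforce it at $10^{-12}$ relative on
10,000 random tables. Only mixtures are partitioned; a mixture whose
species lacks a positive monoculture reference is excluded with a message.

## 5. Inference

* **Bootstrap.** Percentile intervals from resampling plots within
  treatment groups (plot = experimental unit; tree-level resampling would
  fake replication). Size-1 groups get `NA` intervals, flagged. Percentile
  intervals undercover slightly at n ≈ 10–30; the coverage test budgets
  for that.
* **Mixed model.** `y ~ log2(richness) + myco_level + (1 | composition)`,
  REML via lme4. Richness enters numerically (one numerator df), log2 by
  default since doubling richness is the natural step in a 1–2–4 design;
  raw scale is a switch. Wald z tests are reported; Satterthwaite or
  Kenward–Roger denominator-df corrections are deliberately out of scope,
  and the acceptance suite instead verifies calibration empirically
  (coverage of 95% Wald intervals within [90%, 99%] across a
  σ_α × group-count grid — measured on 400 simulated datasets per cell so
  the Monte-Carlo SE of observed coverage is ≈ 1 point). Singular fits
  (zero random-intercept variance) are returned with a warning flag, and
  in that limit the fixed estimates provably collapse to OLS.
* **R².** Marginal $\sigma^2_f / (\sigma^2_f + \sigma^2_\alpha +
  \sigma^2_\varepsilon)$ and conditional $(\sigma^2_f + \sigma^2_\alpha) /
  (\sigma^2_f + \sigma^2_\alpha + \sigma^2_\varepsilon)$, with
  $\sigma^2_f$ the (population) variance of the fixed-effect linear
  predictor.

## 6. Determinism and seeds

One master seed fans out to per-stage child seeds (`split_seed()`; order:
pools, design, layout, niche, simulation, analysis), so any stage replays
in isolation and two runs of the same config are byte-identical — the
test suite hashes the output files to enforce this. All internal RNG use
restores the caller's random state.

## 7. Known limitations

* The heuristic pool search is a local swap descent; global optimality is
  only guaranteed on instances small enough to enumerate.
* Greedy layout placement can exhaust its restart budget on pathologically
  tight grids (it reports the tightest constraint); it is not a
  completeness proof, the brute-force oracle in the tests is.
* Quadrature resolution trades accuracy for time ($O(1/R)$ bias); the
  default 200 keeps single-disk errors well under 1%.
* The bundled trait table carries synthetic values — it demonstrates the
  machinery and must not be used for science.
* Wald inference ignores denominator-df corrections; for small designs
  the bootstrap summaries are the safer readout.
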