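# mycodiv

Tools for planning and analysing **tree diversity experiments that cross
species richness with mycorrhizal association type** — communities of trees
that associate with arbuscular mycorrhizal fungi (AMF), with ectomycorrhizal
fungi (EMF), or with a mixture of both.

The package is aimed at biodiversity–ecosystem functioning (BEF)
researchers who need the whole life cycle of such an experiment in one
reproducible pipeline:

1. **Species-pool selection.** From a candidate trait table, select one
   five-species pool per mycorrhizal type so that the pools are maximally
   similar in functional traits *other than* mycorrhizal type, using mixed
   Gower dissimilarity, `d_ij ∈ [0, 1]`, and Rao's quadratic entropy
   `Q = Σᵢ Σⱼ d_ij p_i p_j` as the functional-diversity diagnostic. This
   keeps trait differences from confounding the mycorrhizal contrast.
2. **Design generation.** Treatments cross richness {1, 2, 4} with
   mycorrhizal level {AMF, EMF, Both} (8 valid cells). The generator
   produces 80 plots — 20 monocultures (10 species × 2), 30 two-species and
   30 four-species plots, with balanced "ten out of 25" / "ten out of 100"
   subsets of the mixed-type combinations so every species occurs equally
   often — and randomizes them onto two 5 × 8 block grids under the
   constraints that same-treatment plots are never adjacent (8-neighborhood)
   and no treatment occurs more than twice around any focal plot. Each plot
   gets a 14 × 10 planting grid (140 trees, 1 m spacing) with maximally
   interleaved species and a 64-tree core area.
3. **Synthetic growth data.** A resource-niche simulator stands in for
   field data: each species occupies a disk in a 2-D unit resource space,
   overlapping disk regions are shared equally, and per-capita captured
   resource drives lognormally noisy diameter growth with annual mortality.
   Scenarios: *complementarity* (disjoint niches, equal rates), *selection*
   (nested niches, one dominant species), *neutral* (identical niches).
4. **Additive partitioning.** Plot productivity is the annualized
   basal-area increment `ΔBA = π (d/200)²` summed over core trees. Mixture
   overyielding is partitioned as

   `NE = ΣY_O,i − ΣRY_E,i·M_i`, `CE = N·mean(ΔRY)·mean(M)`,
   `SE = N·cov(ΔRY, M)`

   (population covariance, so `NE = CE + SE` holds exactly), separating
   resource-partitioning signals (CE) from dominance of productive species
   (SE).
5. **Inference.** Percentile-bootstrap group summaries (plot-level
   resampling), random-intercept linear mixed models with community
   composition as the random factor, and marginal / conditional R²
   (fixed-effects vs fixed-plus-random variance explained).

## Worked example

```r
library(mycodiv)

tt     <- read_trait_table(system.file("extdata", "example_traits_synthetic.csv",
                                       package = "mycodiv"))
pools  <- select_pools(tt)
design <- randomize_layout(assemble_design(pools, seed = 1), seed = 1)
niche  <- sample_niche_config(pools, "complementarity", seed = 1)
inv    <- simulate_inventory(design, niche, seed = 1)
part   <- partition_effects(build_yield_table(basal_area_increment(inv, 1, 2), design))
print(group_summary(part, "NE", n_boot = 1000, seed = 1), digits = 3)
```

```
  richness myco_level  n   mean  lower  upper excludes_zero
1        2        AMF 10 0.0177 0.0145 0.0199          TRUE
2        2       Both 10 0.0189 0.0180 0.0197          TRUE
3        2        EMF 10 0.0181 0.0167 0.0193          TRUE
4        4        AMF 10 0.0657 0.0605 0.0712          TRUE
5        4       Both 10 0.0820 0.0787 0.0856          TRUE
6        4        EMF 10 0.0740 0.0709 0.0770          TRUE
```

Under the complementarity scenario every treatment group shows a positive
net biodiversity effect (m² basal-area increment per plot and year) whose
95% bootstrap interval excludes zero, and the effect grows with richness —
disjoint niches mean each species keeps its full resource capture while its
planted density halves or quarters. A mixed model on the same plots:

```r
part$composition <- design$composition[match(part$plot_id, design$plot_id)]
fit_mixed_model(part, "NE")
```

```
Random-intercept mixed model for NE
   .y ~ .rich + myco_level + (1 | composition)
            term  estimate       se       z          p
1    (Intercept) -0.041904 0.002825 -14.831  9.289e-50
2          .rich  0.056530 0.001746  32.380 5.329e-230
3 myco_levelBoth  0.007545 0.002071   3.643  2.694e-04
4  myco_levelEMF  0.003260 0.002181   1.495  1.350e-01
  var(fixed) 0.0008085, var(composition) 2.989e-05, var(resid) 7.047e-06
  R2 marginal 0.956, conditional 0.992
```

`NE` rises by ≈ 0.057 m² per log₂ richness step, and accounting for the
community composition random intercept raises explained variation from the
marginal to the conditional R². Re-running either chunk reproduces the
output byte for byte — the pipeline is deterministic for a fixed seed.

## Command line

```sh
Rscript inst/cli/mycodiv run-all --seed 1 --out results/
Rscript inst/cli/mycodiv validate-design --design results/design.csv
```

Subcommands: `select-pools`, `design`, `simulate`, `partition`, `analyze`,
`run-all`, `validate-design`. Configs are JSON or YAML
(see `default_config()`); every run writes a `manifest.json` with the
config, seed and output hashes for exact replay.

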