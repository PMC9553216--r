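# coexhist

Quantitative analysis of **coexistence-history experiments** in intercropped
annual crop communities: do plants whose parents grew in the same community
type for the previous generations interact differently — compete less,
facilitate more — than plants whose parents grew elsewhere?

The package is aimed at plant community ecologists and agronomists analysing
(or power-testing) diversity–adaptation experiments in which six crop
species from four phylogenetic groups are grown as isolated singles,
monocultures, 13 two-species and 4 four-species mixtures, under two
fertilization levels, with seed sources from singles, monocultures or
mixtures ("same" vs "different" coexistence history).

## What it computes

* **Relative interaction index.** Per marked individual,
  `RII = (y_comm − y_single)/(y_comm + y_single)`, with the single-plant
  reference averaged per species × fertilization × history stratum; species
  means and the plot-level net index `RII_net = Σ RII_i r_i` with
  `r_i = 1/S`. Negative = competition, positive = facilitation, bounded in
  [−1, 1]. A companion contrast (`rii_coexistence()`) applies the same index
  to reference performance across seed histories.
* **Biodiversity-effect partition.** Net effect `NE = Yo − Σ r_i M_i`
  against history-matched monocrop references, split exactly into
  complementarity `CE = N·mean(ΔRY)·mean(M)` and selection
  `SE = N·cov(ΔRY, M)` (population covariance, so `NE = CE + SE` is an
  identity).
* **Trait structure.** SLA and LDMC from raw leaf measurements,
  community-weighted means (biomass weights), species- and community-level
  CVs, and convex-hull functional richness in standardized trait space
  (exact d-dimensional hull volume, with principal-axis reduction for
  degenerate plots).
* **Mixed-model inference.**
  `y ~ fertilization * history * (monomix + monomix:nspecies) + (1|comb) +
  (1|bed) + (1|column)` via lme4/lmerTest (type III, Satterthwaite),
  marginal means and Tukey contrasts via emmeans, percent effect sizes with
  a magnitude denominator, Shapiro–Wilk/Levene diagnostics, and an FPAR
  model with a day-of-year random term. `rii_history_test()` adds a
  reference-aware species-level test for the history effect (see the
  methods vignette for why the plot-level test alone is anticonservative).
* **Synthetic data.** `simulate_experiment()` generates the full experiment
  (individuals, plot yields, traits, weekly canopy light) under a
  multiplicative competition model with known ground truth, calibrated so
  the implied marginal-mean contrasts on net RII are +50% (history) and
  +64% (fertilization).

## Worked example

The `analysis/` directory is a numbered workflow (design → simulate →
interactions → partition → traits → inference) writing its tables under
`results/`. Running it end to end:

```sh
Rscript analysis/01_design.R
Rscript analysis/02_simulate.R
Rscript analysis/03_interactions.R
```

prints, among other things:

```
Plots: 420 | community: 276 | mixtures: 204 | singles: 144

Mean net RII by history and fertilization:
          fertilized unfertilized
different     -0.375       -0.122
same          -0.150       -0.065
```

All cells are negative — communities compete — but competition is weaker
under a common coexistence history and without fertilization, the two
directions the pipeline is built to quantify. `04_partition.R` verifies the
partition identity on every plot (`max |NE − (CE + SE)| ≈ 1e-13 g`),
`05_traits.R` shows the built-in character convergence (community LDMC CV
about 10–15% lower under a common history), and `06_inference.R` fits the
mixed models:

```
Percent effect sizes (marginal means):
      history fertilization
        57.73         65.15

Reference-aware history test: F = 57.37 (den. df 21.5), p = 1.65e-07
```

i.e. this particular simulated dataset recovers the generator's implied
+50%/+64% contrasts to within sampling error, and the history effect is
significant under the reference-aware test.

The same machinery runs on external field tables: `read_bundle()` reads the
four-table CSV schema (design, plots, individuals, light), translating
foreign column headers through an adapter mapping, and `run_pipeline()`
executes every stage with validation and a run log.

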