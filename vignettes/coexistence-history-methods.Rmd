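---
title: "Methods: quantifying coexistence-history effects in crop communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying coexistence-history effects in crop communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexhist)
```

## The question and the experimental structure

Intercropping experiments that resow harvested seed over successive
generations can ask whether crops *adapt to their neighbourhood*: do plants
whose parents grew in the same community type (a common "coexistence
history") interact differently from plants whose parents grew elsewhere?
`coexhist` implements the complete quantitative analysis of such a
three-generation experiment with six annual crops — wheat and oat
(monocots), coriander (superasterid), lentil (legume), flax and camelina
(non-legume superrosids) — grown as isolated singles, monocultures, all 13
two-species mixtures spanning two phylogenetic groups, and all 4
four-species mixtures with one species per group, under fertilized and
unfertilized conditions. In the analysed (third-year) snapshot every
community exists in three seed-source versions: from singles, from
monocultures, and from mixtures; a plot has the *same* coexistence history
when community type and seed source coincide (for mixtures, the identical
species combination), and a *different* history otherwise. With 23
community compositions x 2 fertilization levels x 3 sources x 2 replicates
the design holds 276 community plots, 204 of them mixtures; singles are
replicated 4 times in separate beds. Monocultures and singles sown "from
mixture" use a pooled four-species-mixture seed lot, represented by the
`pooled-4mix` source token.

## Interaction, biodiversity-effect and trait metrics

**Relative interaction index.** For each marked individual,
\(\mathrm{RII} = (y_{\mathrm{comm}} - y_{\mathrm{single}})/(y_{\mathrm{comm}} +
y_{\mathrm{single}})\), where \(y_{\mathrm{single}}\) is the mean grain
yield of the four single-plant replicates of the same species,
fertilization *and history class*, so that history effects on interactions
are separated from baseline performance shifts. Species RIIs are the means
over the (up to three) marked individuals — averaging individuals before
species is the default because the net index sums one term per species;
with balanced plots the alternative (pooling all individuals) coincides and
both are implemented. The plot-level net index is
\(\mathrm{RII}_{net} = \sum_i \mathrm{RII}_i r_i\) with \(r_i = 1/S\).
Missing reference strata propagate as `NA` — a zero would fabricate "no
interaction". A companion contrast, `rii_coexistence()`, applies the same
index shape to reference performance itself (singles under community-derived
vs single-derived seed; monocultures under non-monoculture vs monoculture
seed).

**Biodiversity effects.** For each mixture,
\(\mathrm{NE} = Y_o - \sum_i r_i M_i\) with monocrop references \(M_i\)
averaged over the two monoculture replicates matched on fertilization and
history class. The additive partition uses \(\Delta RY_i = Y_{o,i}/M_i -
r_i\): \(\mathrm{CE} = N\,\overline{\Delta RY}\,\overline{M}\) and
\(\mathrm{SE} = N\,\mathrm{cov}(\Delta RY, M)\) with the *population*
covariance, which makes \(\mathrm{NE} = \mathrm{CE} + \mathrm{SE}\) an
algebraic identity rather than an approximation. Proportions are
\(r_i = 1/N\) throughout: the design is substitutive (each species occupies
\(1/N\) of the rows at its monoculture density); sown-density weighting is
exposed as an option but not used. Where both different-history sources
exist they are pooled within the history class.

**Traits.** SLA is leaf area over dry mass; LDMC is dry over water-saturated
leaf mass. Community-weighted means weight species trait means by the
species' share of plot aboveground biomass. The community-level CV pools
all marked individuals of a plot. Functional richness is the convex-hull
volume of a plot's individuals in trait space *standardized to zero mean and
unit variance across the whole dataset* — raw-unit hulls would multiply
centimetres by g/g. Plots with too few individuals to span the trait space
(e.g. three marked plants of a monoculture in five-trait space) are
projected onto their leading principal axes — `min(points - 1, rank)`
dimensions — and the reduced dimension is reported next to the volume;
configurations still degenerate after reduction give `NA`. The hull volume
itself is computed by exact recursive supporting-hyperplane enumeration
(suited to the \(\le 12\) points of a plot) and is verified in the test
suite against an independent shoelace-formula oracle in 2-D and analytic
simplex volumes in higher dimension.

## Mixed-model inference

Each per-plot response (net RII, NE, CE, SE, total yield, FPAR, CWMs, CVs,
FRic) is analysed with

```
y ~ fertilization * history * (monomix + monomix:nspecies)
    + (1|comb) + (1|bed) + (1|column)
```

where `history` contrasts same vs different (the two different-history
sources are pooled by default; a three-level option exists), and crop
species number (2 vs 4) is nested within the monoculture/mixture contrast —
its monoculture cell is aliased and dropped automatically. F tests use type
III sums of squares with Satterthwaite denominator degrees of freedom (the
method is reported alongside every table, since printed F values depend on
it). Marginal means come from `emmeans`, pairwise comparisons are
Tukey-adjusted within the probed interaction, and percent effect sizes are
\(100\,(m_{\mathrm{focal}} - m_{\mathrm{ref}})/|m_{\mathrm{ref}}|\) — the
magnitude denominator makes a less-negative interaction index read as a
positive percent change. Residuals are checked with Shapiro–Wilk and
Levene tests; `log`/`sqrt` transformations are available and marginal means
are back-transformed. The FPAR model averages the three weekly readings per
plot and adds a day-of-year random intercept (dropped, with a warning, when
only one week is present).

**Propagating reference uncertainty.** Every plot of a species x
fertilization x history stratum is compared against the *same* estimated
single-plant mean (four replicates). A plot-level model treats that shared
estimation error as if it were treatment signal, and simulation under a
null history effect shows the history F test rejecting at far above its
nominal size (the test suite demonstrates this inflation directly).
`rii_history_test()` therefore re-fits the model at the
species-RII level with random intercepts for species and for the reference
stratum `species:fertilization:history`; the history contrast is then tested
against between-stratum variance with denominator degrees of freedom of the
order of the number of reference strata, and simulation shows its size close
to nominal (slightly conservative). The package's convention: effect sizes
and marginal means from the plot-level model, the history p-value from the
reference-aware test. The same caveat applies in principle to NE/CE/SE
(monocrop references from two replicates); only the RII test is given the
reference-aware form because that is where the contrast of interest lives.

## The synthetic-data generator

The generator emulates the experiment's statistical structure with known
ground truth; it is not a plant-growth model. Per-plant yield is

\[
y = \mathrm{baseline}_s \times \mathrm{fert}^{\,f} \times c_{\mathrm{eff}}
    \times \varepsilon,\qquad
\varepsilon \sim \mathrm{lognormal}(-\sigma^2/2, \sigma),
\]

so noise has unit mean and yields stay positive. Competition is
multiplicative — the minimal mechanism consistent with the ratio form of
RII — and the treatments relax it on the \((1-c)\) scale:
\(1 - c_{\mathrm{eff}} = (1 - c)(1 - \gamma)^{\mathrm{unfert}}
(1 - \delta)^{\mathrm{same}}\). Plot-level species yield is the per-plant
mean of the marked individuals times the sown count (monoculture density
scaled by \(1/S\) in mixtures), which keeps the individual and plot tables
mutually consistent and makes the whole dataset deterministic at
\(\sigma = 0\). Single plants are simulated under all three seed histories
so reference stratification is exercised, but carry no neighbours and hence
no history effect on yield. Intra- and inter-specific multipliers are
separate parameters so monocultures and mixtures can diverge; both default
to 0.5.

Default calibration, fixed once at design time:

* \(c = 0.5\): fertilized different-history communities sit at net RII
  \(-1/3\), a competitive but not collapse-level interaction strength.
* \(\delta = 0.439853\), \(\gamma = 0.582526\): solved jointly (Newton
  iteration on the noiseless cell means) so the implied marginal-mean
  contrasts are exactly +50% (same vs different history) and +64%
  (unfertilized vs fertilized) — `implied_effects()` returns these closed
  forms, and the recovery studies compare pipeline estimates against them.
* \(\sigma = 0.2\): a 20% individual yield CV, typical of garden-scale
  yield data.
* Fertilization multiplies baseline yield by 1.5.
* Trait convergence under a common history: +5% height, −3% LDMC mean
  shifts, and a dispersion shrink factor 0.85 applied both to within-species
  SDs and (in mixtures) to the spread of species means around the community
  mean — so community trait CVs drop by roughly 15% under a common history.
* Canopy light: logistic closure over day of year (midpoint day 160, time
  constant 12 d, asymptote 85% for communities, 20% for singles), a +3
  percentage-point increment under a common history, reading noise SD 3.

What the generator does *not* emulate: generations 1–2 as explicit
selection (history enters only through \(\delta\)), bed/column spatial
gradients (those random effects are exercised but their true variances are
zero), species-specific competition asymmetries, and any yield–trait
covariance. Passing recovery tests therefore show that the pipeline
measures what the model puts in — not that the field data satisfy the
model.

## Numerical and design choices

* Population (1/N) covariance in the partition — the identity
  NE = CE + SE is checked to \(10^{-9}\) relative tolerance on every plot.
* RII requires a positive denominator; two zero yields raise an explicit
  undefined-RII error rather than returning 0.
* Hull degeneracy: affine rank is determined at tolerance \(10^{-8}\);
  coplanar facet point sets are merged before recursion so grids and boxes
  are handled exactly.
* Bed assignment randomizes plots into beds of 28 within fertilization
  level (fertilizer is applied at bed level), singles in separate beds;
  `column` is the within-bed position. A single integer seed reproduces the
  layout, and `.Random.seed` is restored after every seeded operation.
* Problem sizes for the simulation studies: 100 seeds for effect-size
  recovery and 200 datasets for the null-size study, each on the full
  276-community-plot design — enough for Monte-Carlo standard errors of
  about 1 percentage point on the recovered effect and 1.5 points on the
  rejection rate.
* The deposited field data of the motivating experiment are not bundled;
  `read_bundle()` accepts external tables through an adapter mapping of
  column headers, and the reproduction check in the acceptance suite runs
  only when the deposit is placed under `data-raw/`.

## Known limitations

* The reference-aware history test runs slightly conservative in the
  null-size simulation; with only 24 reference strata this is the expected
  price of the Satterthwaite approximation at small denominator df.
* NE/CE/SE inference reuses the plot-level model and thus inherits the
  shared-reference caveat discussed above.
* FRic volumes are comparable only within one standardization, i.e. within
  one dataset run.
* The pipeline analyses a single-season snapshot; lineage dynamics across
  generations are outside its scope.
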