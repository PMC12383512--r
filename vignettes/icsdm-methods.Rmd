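---
title: "Coupled habitat-suitability models from fishery logbooks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled habitat-suitability models from fishery logbooks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small pelagic fish such as Japanese sardine (*Sardinops melanostictus*) and
chub mackerel (*Scomber japonicus*) share fishing grounds in the Northwest
Pacific, and their habitat dynamics are not independent: where one species
aggregates, the other's distribution shifts too. Classical single-species
distribution models (ssSDM) map environmental covariates to a habitat
suitability index (HSI) one species at a time and ignore this coupling.
`icSDM` implements a coupled workflow: fit each species' single-species
model, predict its suitability over the whole region, then inject that
predicted surface into the *other* species' model as an additional biotic
covariate — an interspecific-competition SDM (icSDM) — and quantify what
the coupling buys in explanatory power, habitat-class structure and
inter-species habitat correlation.

The workflow runs on a 0.25° grid over 34–45° N, 144–163° E, June–November,
with four training years and one prediction year. (The study window is
sometimes quoted from 144° E and sometimes from 145° E in the source
material; the western bound is configurable and defaults to 144° E.)

## Pipeline stages

1. **Gridding.** Logbook records (date, position, catch in tons, hauls,
   effort days, vessel id) are binned to 0.25° cells, half-open in both
   axes with the north/east boundary joining the last cell. Catch, effort
   and hauls are summed within (species, cell, year, month); CPUE is the
   ratio of sums (tons per effort day), never the mean of per-record
   ratios.
2. **Empirical HSI.** The model's training target is min–max normalized
   CPUE within each (species, month) stratum, pooled across training
   years, so the best cell of a month scores 1 and the worst 0. CPUE was
   chosen over raw catch or effort because it is the standard unit-free
   abundance proxy in fisheries HSI work; catch- and effort-based targets
   remain available. A stratum with no CPUE contrast is degenerate and is
   assigned 0.5 with a warning rather than dividing by zero.
3. **ssSDM.** A bagged regression-tree ensemble (random forest) with 1000
   trees, 4 candidate covariates per split and minimum leaf size 5 maps
   the 13 environmental covariates (temperature at 0/50/100/150/200 m,
   SSH, SSS, chlorophyll-a, U, V, EKE, SSTA, ONI) to the empirical HSI.
   The ensemble is the `ranger` implementation run single-threaded with a
   fixed seed, which makes every fit bit-reproducible. Predictions are
   means of a [0,1] response and cannot leave the training range; the
   explicit clip to [0,1] is a formal guard asserted in tests.
4. **Coupling.** The fitted ssSDM of species B is evaluated at every cell
   of every training layer ("regional" prediction); its value at species
   A's sample rows becomes the covariate `hsi_other` of A's icSDM (and
   symmetrically for B). The coupling is one-pass by design: icSDMs
   consume single-species surfaces only, never other icSDM output, so no
   feedback loop can arise, and the role tag on every surface
   (`regional_ss` vs `ic`) is checked at injection time. `mtry` stays at 4
   after the covariate count grows to 14; the ensemble configuration is
   treated as one fixed setting across stages.
5. **Validation.** Repeated random 80/20 holdout, 100 iterations per
   month, refitting on each training part and scoring R² = 1 − SSE/SST on
   the test part. The split of iteration *i* is derived from (seed, *i*)
   alone, so the ssSDM and icSDM see identical splits and their R² values
   are paired. The gain is summarized as the mean paired difference with
   a two-sided Wilcoxon signed-rank p-value and conventional significance
   stars. Because the holdout replicates share training data, these
   p-values are descriptive, and the reports label them as such. The
   "100 iterations of leave-one-out cross-validation over an 80/20 split"
   phrasing in the source material is self-contradictory; 100 repeated
   random holdouts at 80/20 is the only reading consistent with both
   numbers and is what is implemented.
6. **Habitat analysis.** Surfaces are classified into five fixed classes
   (boundaries 0, 0.2, 0.4, 0.6, 0.8, 1; all bins half-open except the
   last, which is closed at 1, so an HSI of exactly 0.8 or 1.0 is class
   5). Cells with HSI ≥ 0.6 are optimal habitat. Cohabitation surfaces
   combine the two species' icSDM fields cellwise — geometric mean by
   default (symmetric, [0,1]-preserving, zero iff either species finds
   the cell unsuitable), with `min` and `product` as alternatives; the
   rule is recorded in the output's species tag. An asymmetric
   construction (weighting one species more) would also be defensible —
   the symmetric default is this package's choice, documented rather than
   claimed. Monthly Pearson correlations between and within species use
   jointly unmasked cells only, with no imputation.

## The synthetic fishery

Real purse-seine logbooks are proprietary, so the package ships a
generator that emulates both inputs with known ground truth.

**Environment.** Each monthly layer combines a southward-warming
latitudinal gradient (0.8 °C per degree), a seasonal cycle peaking in
August, a mean temperature decrease of 0.045 °C per metre of depth, and
smooth spatial noise built by bilinear interpolation of coarse white
noise. EKE is computed from the U, V anomalies about each layer's spatial
mean as ½(u′² + v′²) — the standard definition, adopted because the name
alone does not fix a formula. SSTA and ONI are genuinely basin-scale
monthly indices, so they are generated as per-month scalars broadcast to
all cells.

**Species.** Each species' base suitability is the weight-normalized
geometric mean of unimodal Gaussian responses to its active covariates.
The interspecific coupling multiplies species B's base by
(1 + γ<sub>B</sub> · suitability<sub>A</sub>), renormalizes the layer so
its maximum equals the base field's maximum, and clips to [0,1]. The
renormalization matters: without it a positive coupling deflates the
coupled species' entire dynamic range wherever the two niches barely
overlap, which would starve the observation model; being a positive
per-layer scaling it leaves Pearson correlations between surfaces
untouched, and at γ = 0 the coupled surface reduces exactly to the base
surface. A multiplicative form was chosen because the analysis treats the
competitor's HSI as a single added covariate and needs a monotone
dependence to recover; an additive form is available.

**Observation process.** Expected effort per cell is proportional to
truth<sup>k</sup> above a detection floor; the monthly effort budget is
integerized by a single multinomial draw, which conserves the budget
exactly (a Poisson alternative would not, and exact conservation is what
makes the allocation testable). Cell effort is split into vessel trips,
catch per record is q · effort · truth · mean-one lognormal noise, and
positions are uniform within the cell. Hauls are effort-days × 2 and
vessel length is generated but unused — both kept purely for format
fidelity.

**Default study conditions.** The defaults were calibrated once to the
study design and then frozen: an 80-vessel fleet with 150 effort-days per
species-month, k = 2, catchability 1.5 t/day, noise σ = 0.1 and floor
0.05 yields roughly 130–150 fished cells per species-month and ≈3300
training rows per species over four years — the scale of the real
logbook data. Species A has a diffuse six-covariate niche (surface and
100 m temperature, chlorophyll, SSH, SSS, EKE); species B has a broad
thermal niche centred 2.5 °C colder at 50 m plus a mild chlorophyll
preference, and a coupling of γ<sub>B</sub> = 0.8 to species A.

## What the synthetic data can and cannot show

The generator's truth surfaces are *deterministic functions of the 13
covariates the models see*. This has a consequence worth stating plainly:
the injected biotic covariate — the competitor's predicted surface — is
itself a function of those covariates, so it carries no information the
single-species feature set does not already contain. Any icSDM gain on
this synthetic data is therefore a finite-sample, representation-transfer
effect: the competitor's model distils its cross-month training data into
one high-quality composite feature that the focal month's small fit could
not rebuild from raw covariates. That effect is real and consistently
positive here (mean ΔR² of roughly +0.005, Wilcoxon p < 0.05 in most
replicates, against a γ = 0 baseline of about −0.005 caused by mtry
dilution from the extra covariate), but it is an order of magnitude
smaller than gains reported on real fisheries data, where the competitor's
realized distribution reflects shared drivers — prey fields, schooling,
fleet behaviour — that are *not* in the covariate set. Passing the
synthetic power checks shows the machinery recovers the coupling
direction and ordering; it does not certify effect sizes on real data,
and conversely the small synthetic effect sizes say nothing against
larger real-world gains.

Other simplifications: no ocean dynamics (no advection, no coherent
eddies), no vessel economics, exactly two species, no spatial
autocorrelation in catch noise, and no covariate measurement error.

## Numerical and design choices

- **Determinism.** All randomness flows from one root seed through named
  substreams (`generator`, `fishery`, `splits`, per-model tree seeds), so
  any stage can be re-run independently and the full pipeline is
  bit-reproducible; manifests record md5 hashes of every output.
- **Holdout reproducibility.** Iteration *i*'s split seed is
  `(seed · 10007 + i) mod (2³¹ − 1)`, below the 32-bit limit.
- **Degenerate inputs.** Constant training response: refused unless
  explicitly overridden. Zero test variance in a holdout iteration: that
  iteration is NA and counted. All-zero coupled surface (possible when
  γ < −1): an error, never silently renormalized. Points on the grid
  boundary: assigned to the last cell, never clamped from outside.
- **Problem sizes.** Validation experiments in the test-suite use
  25-tree ensembles and surface experiments 60–200 trees; the package
  default stays at 1000 trees, and the reduced ensembles are an
  experiment-size choice that leaves the design (grid, years, row counts,
  100 iterations, ten seed replicates) untouched.
- **Interfaces.** Gridded data travel as long-format CSV dialects
  (`year,month,lat,lon,var,value` for environment;
  `year,month,lat,lon,species,role,hsi` for surfaces) plus the logbook
  CSV; models serialize to RDS with a JSON provenance sidecar.

## Known limitations

- The per-month empirical-HSI normalization makes HSI comparable within a
  month but not across months; cross-month comparisons ride on the
  models' covariate responses.
- p-values from split-matched holdout replicates overstate evidence if
  read as independent-sample tests; they are reported for comparability
  with the conventional presentation and labelled descriptive.
- The biotic covariate is injected at fished cells at their predicted
  values; no smoothing or neighbourhood aggregation is attempted, as
  nothing in the method's description licenses one.
- SSTA and ONI are included as model covariates by default although they
  are month-constants; with few distinct months they can act as month
  indicators for the ensemble. They are removable via the model spec.
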