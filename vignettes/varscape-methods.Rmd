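---
title: "Methods: predicting urban bird diversity from vegetation rasters and vocal activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting urban bird diversity from vegetation rasters and vocal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

City-wide bird monitoring is expensive: field surveys and even passive
acoustic monitoring cover tens of sites, not a whole city. If site-level
diversity can be predicted from remote-sensing vegetation metrics —
quantities available wall-to-wall — a modest monitoring campaign can be
extrapolated into a city-wide diversity map for planning and conservation.
`varscape` implements that workflow end to end: it turns automated acoustic
detections into diversity metrics, extracts vegetation statistics around
monitoring sites at several spatial scales, finds the scale at which
vegetation best explains diversity, compares competing vegetation
predictors, ordinates the community, and produces evaluated prediction
maps. A synthetic-data generator with analytic ground truth makes every
stage testable.

## From detections to diversity: the vocal activity rate

The acoustic input is a table of classifier detections (site, start time,
species, confidence), as produced by BirdNET-style analysers. Three
screening steps run in a fixed order:

1. **Confidence filter** — keep detections with confidence ≥ 0.8
   (inclusive; `filter_confidence()`).
2. **Singleton removal** — a species detected exactly once at a site is
   treated as incidental there and removed; pairs with two or more
   detections are kept even if the species is a singleton at another site
   (`remove_singletons()`).
3. **Rare-species review** — species with ten or fewer detections overall
   are flagged for manual identity checking; confirmed misidentifications
   are removed by name (`rare_species_review()`). The review itself is a
   human step; the software only represents its outcome.

The order matters and is regression-tested: the confidence filter can turn
a pair into a singleton, and singleton removal changes the totals the rare
review sees.

The abundance proxy is the **vocal activity rate**:

$$\mathrm{VAR} = \frac{n_{\text{15-minute periods with} \ge 1
\text{ detection}}}{\text{days recorded}}$$

Multiple vocalisations within one 15-minute period count once, which damps
the over-representation of incessant singers. Periods are 900-second bins
anchored at each site's recording start (not wall-clock quarter hours), so
VAR does not depend on the deployment minute; a detection belongs to the
bin containing its start time (classifier windows are ~3 s, so boundary
spans are negligible). `days recorded` is the actual fractional recording
duration. A full day has 96 periods, so VAR is bounded by 96 when effort
equals elapsed time.

Site-level metrics (`site_diversity()`): richness is the number of species
with positive VAR; total VAR is their sum; Shannon diversity is
$-\sum p_i \ln p_i$ with $p_i$ the VAR shares (natural log). A site with no
species has undefined Shannon diversity and is reported as 0 with a
warning.

## Vegetation rasters and buffer statistics

Rasters are simple planar-metric grids (`raster_layer`), exchanged as
plain-text ESRI ASCII grids. NDVI is $(NIR-Red)/(NIR+Red)$, bounded in
$[-1, 1]$; EVI is $2.5(NIR-Red)/(NIR+6Red-7.5Blue+1)$; vegetation volume is
canopy height × cell area on vegetated cells (nodata elsewhere), with
negative heights clipped to zero under a warning.

Buffer statistics (`site_buffer_table()`) are computed at radii 25, 50,
100, 200, 400 and 800 m:

- a cell belongs to a buffer iff its **centre** lies within the radius
  (all-or-nothing, the common raster-extraction default);
- mean NDVI excludes nodata cells;
- vegetation-volume **density** (m³/m²) sums volume with nodata treated as
  zero and divides by the number of in-buffer cells × cell area — the
  denominator uses the same discretisation as the numerator rather than
  $\pi r^2$;
- the volume predictor enters models as the natural log of density. A
  density of exactly zero (possible on synthetic landscapes, not observed
  in real cities with vegetated buffers) is logged as
  $\log(\text{density} + \varepsilon)$ with $\varepsilon$ = smallest
  positive observed density × 10⁻³, under a warning.

Block aggregation (`aggregate_raster()`) requires an integer resolution
ratio, ignores nodata for means, treats all-nodata blocks as nodata, and
conserves totals under `sum`.

## Stratified site selection

`stratified_select()` reproduces a two-way stratified design: five 3-km
distance rings around the city centre crossed with five equal-width NDVI
bins on a 100 m selection raster (mean-aggregated, then negative values
zeroed — aggregation happens first). Up to two cells per (ring, bin)
stratum are drawn uniformly without replacement among eligible cells: at
least 75% of the cell inside the city boundary (measured on a 10×10
subgrid of points per cell) and at least 300 m from every already-selected
cell. Separation is enforced greedily against the full growing set across
strata; strata that cannot be filled are reported, never fabricated. Values
exactly on an interior bin edge belong to the upper bin; the last bin is
right-closed. The field step of snapping a site to the nearest streetlamp
is replaced by using the cell centre.

## Linear models, scale optimisation and predictor comparison

For each diversity metric, vegetation predictor and buffer radius, the
model is

$$\text{metric} \sim \text{week} + \text{distance}_{km} + x_{b}$$

with recording week a dummy-coded factor (first level reference), distance
to the city centre linear in km, and $x_b$ the buffer predictor (mean NDVI,
or log vegetation-volume density; NDVI is additionally log-transformed in
Shannon models when all buffer values are positive, falling back to the
identity otherwise). Fits are ordinary least squares (`stats::lm`).

- **Partial R²** of a single-column term is $t^2/(t^2 + df_{res})$; the
  multi-column week factor uses the nested-model form
  $(R^2_{full} - R^2_{red})/(1 - R^2_{red})$. Both forms agree to numerical
  precision for single columns (property-tested).
- **Collinearity** is screened by `vif_step()`: iteratively drop the column
  with the largest variance inflation factor $1/(1-R^2_j)$ while any VIF
  ≥ 5.
- **Buffer selection** records, per metric × predictor, the radius with the
  highest partial R², then picks the modal radius across combinations;
  ties go to the radius with the highest mean partial R².
- **Predictor comparison** ranks predictors by model R² per metric and
  reports the mean-R² relative gain under both conventions
  $(a-b)/b$ and $(a-b)/a$, since a headline "x% more variance" figure is
  ambiguous between them.
- **Residual spatial autocorrelation** uses Moran's I with raw
  inverse-distance weights $w_{ij} = 1/d_{ij}$ and a two-sided permutation
  p-value with the $(r+1)/(n_{perm}+1)$ estimator (nonzero by
  construction). The null expectation is $-1/(n-1)$. Note that
  `ape::Moran.I` row-standardises its weights, so it matches this
  statistic only under that convention; the test suite checks both
  formulations against a double-loop oracle.

Model assumption diagnostics never gate execution; the pipeline reports
statistics and leaves judgement to the analyst.

## Community ordination

The community matrix holds site × species VAR values. Dissimilarities are
Bray–Curtis after an explicit $\log(1+x)$ transformation (damping highly
vocal species), and Jaccard on presence–absence. No automatic
transformation happens inside the NMDS: vegan's `metaMDS` is driven with
`autotransform = FALSE` so every transformation is an explicit pipeline
step.

NMDS minimises Kruskal stress-1 over 20 random starts (isotonic regression
with primary tie treatment), keeping the lowest-stress solution; scores are
centred and principal-axis rotated. One subtlety of primary ties: a
dissimilarity matrix in which *all* entries are equal (e.g. four exactly
equidistant points) imposes no rank constraints, so any configuration
attains stress 0 — non-embeddability tests therefore need distinct
dissimilarity ranks. Stress is non-increasing in the iteration budget
within a start (`nmds_stress_path()` exposes this for testing).

For interpretation, the 2-d ordination is rigidly rotated so the fitted
direction of NDVI coincides with axis 1 (`rotate_to_variable()`; stress
and inter-point distances unchanged). `env_fit()` projects environmental
variables (NDVI, log volume, distance, week as a factor by default) onto
the scores with permutation significance; constant variables get r² = 0,
p = 1 with a warning. Species are placed at VAR-weighted averages of site
scores. Habitat-preference annotation collapses raw trait labels: rock and
coastal → human-modified, riverine and wetland → aquatic, grassland and
shrubland → open; forest and woodland pass through.

Concordance between the VAR-based and presence-based views uses Procrustes
superimposition with the PROTEST permutation test ($m^2$ residual,
$t = \sqrt{1-m^2}$) and the Mantel correlation between the two distance
matrices (lower-triangle Pearson r, one-sided permutation p).

## Prediction mapping

An 80/20 uniform random split (ceiling rule: 86 sites → 69 train, 17 test;
unstratified, as nothing in the design requires stratification) feeds
training-set models per metric. Predictions are evaluated on the held-out
sites (RMSE, MAE) and with standardised major-axis model II regression —
the symmetric line for observed-vs-predicted comparisons:
slope $= \mathrm{sign}(r)\, s_y/s_x$, with the 95% CI
$\text{slope}\,(\sqrt{B+1} \pm \sqrt{B})$,
$B = (1-r^2)F_{0.95;1,n-2}/(n-2)$.

The city-wide map evaluates the fitted model on a 100 m NDVI grid,
averaging the linear predictor over the week levels (equivalent to
averaging the dummy effects) with each cell's distance to the centre as
covariate. Cells whose NDVI falls outside the training range still receive
predictions but are flagged as extrapolation rather than clipped — maps
legitimately extend beyond sampled conditions, and the flag keeps that
visible.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure the analysis
assumes, with analytic ground truth for recovery tests.

**Landscape.** NDVI = clip(base + radial slope × distance + Gaussian random
field, −1, 1). The field is white noise circularly convolved (FFT) with a
Gaussian kernel — cheap, stationary, and sufficient for testing. Defaults,
chosen once as a plausible compact city: 6 km extent at 10 m resolution,
base 0.20 at the centre, +0.12 NDVI per km (greenness rising outward),
field sd 0.12 with a 60 m correlation length. The vegetated mask is
NDVI > 0.25; canopy height is a logistic link of NDVI saturating at 35 m
(centre 0.5, scale 0.12), plus a *spatially correlated* height field (sd
3 m, correlation length 120 m). Structured rather than iid height
variation is essential: at equal greenness, a stand of trees and a lawn
differ over whole patches, so canopy error must survive buffer averaging —
with iid cell noise the volume predictor would collapse into a
deterministic transform of NDVI at the 100 m scale.

**Sites and effort.** 86 sites with ≥ 300 m pairwise separation, placed by
rejection sampling inside an edge margin equal to the largest buffer
radius; four recording weeks assigned cyclically; days recorded ~
N(6.49, 1.11) truncated to [3, 7].

**Community.** Each species has a Gaussian niche on the NDVI axis
(stratified-uniform centres over [0, 1], widths 0.12–0.30, peak activity
0.15–0.80); habitat classes are monotone in the niche centre
(human-modified → open → woodland → forest). Occupancy is Bernoulli with
the niche response as probability; given occupancy, each 15-minute period
independently contains a vocalisation with probability
q = max_activity × niche response, and occupied periods get 1 + Poisson
extra detections at uniform times. Confidences mix Beta(8, 2) ("true") and
Beta(2, 4) ("noise") components so the 0.8 filter is exercised in both
directions, and injected single-detection pairs exercise the singleton
filter. `expected_metrics()` gives the closed-form expectations
(richness = Σ occupancy, total VAR = Σ occupancy · 96 · q, Shannon from
expected VAR shares) used as oracles.

**What it does not emulate.** No audio, no detection-distance decay (site
exposure is tied to buffer NDVI only), no weather or seasonal phenology
beyond the week label, no species interactions, and no land-cover
composition shifts — which is why the NDVI/log-volume correlation in the
synthetic city *increases* with buffer radius (the shared radial trend
dominates large buffers) instead of declining as in real cities. Because
the community model is nonlinear in NDVI (Gaussian niches, saturating
VAR), emergent study-level quantities — e.g. which buffer radius or
predictor wins on a fully simulated community — need not match the
metric-level recovery experiments, which generate metrics linearly from a
known scale and slope. Passing tests therefore demonstrate that the
estimators recover known structure under the stated conditions, not that
real cities behave like the generator.

## Problem sizes and numerical choices in the test suite

The recovery and calibration experiments use: 500 replicates of 86 sites
for CI coverage of the generating NDVI slope (target band 0.93–0.97); 100
replicates for buffer-scale recovery over the full radius set on 4 km
landscapes (noise levels set so model R² ≈ 0.5, matching typical field
values); 100 replicates for predictor ranking; 200 null simulations per
permutation test (Moran's I, Mantel, environmental fit) at 199
permutations each, with acceptance band 0.02–0.09 around the nominal 5%
level; 1000 random detection streams against the brute-force VAR oracle;
and 100 random rasters against the all-pixel buffer oracle. Permutation
defaults in production use are 999 with the $(r+1)/(n_{perm}+1)$
estimator. All stochastic steps take explicit integer seeds; equal seeds
give bit-identical outputs.

## Known limitations

- Planar metric coordinates are assumed throughout; geographic data must
  be projected upstream.
- Rasters are held in memory as dense matrices; city-scale sub-metre
  imagery should be aggregated before use.
- The manual rare-species review and any external species-list
  cross-checks are represented only by their outcome (a removal list).
- Bray–Curtis is a semimetric; triangle-inequality violations are
  expected and only boundedness in [0, 1] is enforced.
- The ordination reports Kruskal stress-1; any single "R²" summary of an
  NMDS is estimator-dependent and is deliberately not conflated with
  stress.
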