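# varscape

Predicting urban bird diversity from remote-sensing vegetation metrics and
passive acoustic monitoring.

City planners need to know where bird diversity is high without surveying
every block. `varscape` implements the full workflow for building such
predictions: automated acoustic detections from a modest network of
recorders are turned into site-level diversity metrics, vegetation rasters
are summarised around each site at several spatial scales, linear models
identify the scale and the vegetation predictor that best explain
diversity, community composition is ordinated against the vegetation
gradient, and the chosen model is projected into a city-wide,
quantitatively evaluated diversity map. A synthetic-data generator with
analytic ground truth makes every stage testable. It is aimed at urban
ecologists and monitoring programmes working with BirdNET-style detection
tables and NDVI / canopy-height products.

## The statistics at the core

**Vocal activity rate (VAR)** — the acoustic abundance proxy. For species
*s* at a site,

    VAR_s = (number of 15-minute periods with >= 1 detection of s) / (days recorded)

Multiple vocalisations in one period count once (damping incessant
singers); a full day has 96 periods. Site metrics are richness (species
count), total VAR (sum over species), and Shannon diversity
−Σ pᵢ ln pᵢ with pᵢ the VAR shares. Detections are first screened at
confidence ≥ 0.8, per-site singletons removed, and rare species (≤ 10
detections overall) reviewed.

**Scale optimisation** — for each diversity metric *y*, vegetation
predictor *x* (mean NDVI or log vegetation-volume density, m³/m²) and
buffer radius *b* ∈ {25, 50, 100, 200, 400, 800} m:

    y ~ week + distance_km + x_b        (OLS)

The partial R² of *x_b* (t²/(t² + df)) is compared across radii; the
buffer chosen most often across metric × predictor combinations wins, with
ties broken by mean partial R². Predictors are then compared by model R²
at the chosen scale, with residual spatial autocorrelation checked by a
permutation Moran's I (inverse-distance weights).

**Community composition** — NMDS (Kruskal stress-1, multiple random
starts) of log1p Bray–Curtis dissimilarities of the site × species VAR
matrix, rotated so NDVI aligns with axis 1; environmental vectors fitted
by permutation; concordance with a presence–absence / Jaccard ordination
assessed by Procrustes (PROTEST) and Mantel tests.

**Prediction** — an 80/20 train/test split, city-wide prediction on a
100 m NDVI grid averaging over recording weeks, and evaluation by RMSE,
MAE and standardised major-axis (model II) regression of observed vs
predicted.

See `vignettes/varscape-methods.Rmd` for the full model description,
parameter defaults, and the synthetic generator's assumptions.

## Worked example

A complete synthetic study — landscape, sites, species pool, detection
streams — analysed end to end:

```r
library(varscape)

study <- simulate_study(n_sites = 40, n_species = 25, seed = 11,
                        landscape = landscape_config(grid_size_m = 3000, seed = 11),
                        min_separation_m = 200, margin_m = 450)
vol <- veg_volume_layer(study$landscape$ndsm, study$landscape$veg_mask)
cfg <- pipeline_config(radii = c(25, 50, 100, 200, 400), n_perm = 499,
                       nmds_starts = 10, seed = 11)
res <- run_pipeline(study$detections, study$sites, study$landscape$ndvi, vol,
                    centre = c(1500, 1500), traits = study$traits, cfg = cfg)
```

The pipeline logs its stages (`[metrics] ... [predict]`) and reports,
among other things:

```
            mean    min    max
richness   11.55   8.00  16.00
var_total 194.21 149.49 257.57
shannon     2.28   1.96   2.58
best buffer (m): 200
mean R2 by predictor:
log_veg_volume      mean_ndvi
         0.289          0.402
NMDS stress: 0.131 | Mantel r (BC vs Jaccard): 0.953 | PROTEST t: 0.962
Moran p (richness residuals): 0.152
held-out RMSE richness: 1.43 | SMA slope: 0.64
```

Reading the output: each simulated site hosted 8–16 species with total
vocal activity of 149–258 periods/day. Mean NDVI explained more variance
in the diversity metrics than log vegetation volume (mean R² 0.40 vs
0.29), the ordination found a usable 2-d representation (stress 0.13) in
which the VAR-based and presence-based community views agree strongly
(Mantel r 0.95, PROTEST t 0.96), model residuals showed no spatial
autocorrelation (p 0.15), and held-out richness was predicted to within
about 1.4 species RMSE. With `out_dir =` set, all tables, prediction
grids (ASCII rasters) and a checksum manifest are written to disk;
`inst/scripts/run_pipeline.R` wraps the same pipeline for shell use.

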