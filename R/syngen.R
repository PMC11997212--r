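#' Configuration of a synthetic urban vegetation landscape
#'
#' Defines the generating model for a synthetic city: NDVI is a radial
#' gradient from the city centre plus a spatially autocorrelated Gaussian
#' random field, clipped to \[-1, 1\]; the vegetated mask is an NDVI
#' threshold; canopy height follows a logistic link of NDVI on vegetated
#' cells. Defaults describe a compact city of 6 km extent whose greenness
#' rises away from the centre, with fine-scale vegetation texture at a 60 m
#' correlation length and canopies up to 35 m.
#'
#' @param grid_size_m landscape edge length (m); must be a multiple of
#'   `resolution_m` and at least 4 correlation lengths.
#' @param resolution_m cell size (m).
#' @param centre_xy city-centre coordinate; default is the grid midpoint.
#' @param ndvi_base NDVI at the city centre before noise.
#' @param ndvi_radial_slope NDVI increase per km of distance from the centre.
#' @param noise_sd marginal standard deviation of the random field.
#' @param correlation_length_m Gaussian kernel width of the field (m).
#' @param veg_mask_threshold cells with NDVI above this are vegetated.
#' @param canopy_hmax_m asymptotic maximum canopy height (m).
#' @param canopy_centre,canopy_scale location and scale of the logistic
#'   NDVI-to-height link.
#' @param canopy_noise_sd standard deviation of canopy height variation
#'   around the logistic link (m). This variation is spatially structured
#'   (its own Gaussian field at `canopy_noise_corr_m`): at equal greenness a
#'   stand of trees and a lawn differ in height over whole patches, not cell
#'   by cell, so canopy-height error must survive buffer averaging for
#'   vegetation volume to be a realistically imperfect proxy.
#' @param canopy_noise_corr_m correlation length of the canopy variation
#'   field (m).
#' @param seed integer seed; equal seeds give bit-identical landscapes.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(grid_size_m = 6000, resolution_m = 10,
                             centre_xy = c(grid_size_m / 2, grid_size_m / 2),
                             ndvi_base = 0.20, ndvi_radial_slope = 0.12,
                             noise_sd = 0.12, correlation_length_m = 60,
                             veg_mask_threshold = 0.25, canopy_hmax_m = 35,
                             canopy_centre = 0.5, canopy_scale = 0.12,
                             canopy_noise_sd = 3, canopy_noise_corr_m = 120,
                             seed = 1L) {
  if (resolution_m <= 0) stop("resolution_m must be positive")
  if (correlation_length_m <= 0) stop("correlation_length_m must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (grid_size_m < 4 * correlation_length_m)
    stop("grid_size_m must be at least 4 correlation lengths")
  if (abs(grid_size_m / resolution_m - round(grid_size_m / resolution_m)) > 1e-8)
    stop("resolution_m must divide grid_size_m")
  if (veg_mask_threshold < -1 || veg_mask_threshold > 1)
    stop("veg_mask_threshold must lie in [-1, 1]")
  if (canopy_hmax_m <= 0) stop("canopy_hmax_m must be positive")
  structure(list(
    grid_size_m = grid_size_m, resolution_m = resolution_m,
    centre_xy = centre_xy, ndvi_base = ndvi_base,
    ndvi_radial_slope = ndvi_radial_slope, noise_sd = noise_sd,
    correlation_length_m = correlation_length_m,
    veg_mask_threshold = veg_mask_threshold, canopy_hmax_m = canopy_hmax_m,
    canopy_centre = canopy_centre, canopy_scale = canopy_scale,
    canopy_noise_sd = canopy_noise_sd,
    canopy_noise_corr_m = canopy_noise_corr_m, seed = as.integer(seed)
  ), class = "landscape_config")
}

## stationary Gaussian random field: white noise convolved (circularly, via
## FFT) with a Gaussian kernel of width `corr_len`, rescaled to sd `sd_target`
gaussian_field <- function(nr, nc, res, corr_len, sd_target) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sd_target == 0) return(matrix(0, nr, nc))
  dx <- res * pmin(0:(nc - 1), nc - (0:(nc - 1)))
  dy <- res * pmin(0:(nr - 1), nr - (0:(nr - 1)))
  k <- exp(-outer(dy^2, dx^2, "+") / (2 * corr_len^2))
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  f * (sd_target / stats::sd(as.vector(f)))
}

#' Generate a synthetic NDVI / canopy landscape
#'
#' Realises the generating model of [landscape_config()]: NDVI =
#' clip(base + slope x distance_km + field, -1, 1); the vegetated mask is
#' NDVI > threshold; canopy height (nDSM) is
#' `hmax * logistic((ndvi - centre)/scale)` plus noise, clipped at 0, on
#' vegetated cells and nodata elsewhere.
#'
#' @param cfg a [landscape_config()].
#' @return list with `raster_layer` elements `ndvi`, `ndsm`, `veg_mask`
#'   (mask values 1/0) and the `cfg` used.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  set.seed(cfg$seed)
  n <- as.integer(round(cfg$grid_size_m / cfg$resolution_m))
  res <- cfg$resolution_m
  template <- raster_layer(matrix(0, n, n), xmin = 0, ymax = cfg$grid_size_m,
                           res = res)
  xs <- cell_xs(template); ys <- cell_ys(template)
  dist_km <- sqrt(outer((ys - cfg$centre_xy[2])^2, (xs - cfg$centre_xy[1])^2,
                        "+")) / 1000
  field <- gaussian_field(n, n, res, cfg$correlation_length_m, cfg$noise_sd)
  ndvi <- matrix(pmin(1, pmax(-1, cfg$ndvi_base +
                                cfg$ndvi_radial_slope * dist_km + field)),
                 n, n)
  mask <- (ndvi > cfg$veg_mask_threshold) + 0
  h <- cfg$canopy_hmax_m *
    stats::plogis((ndvi - cfg$canopy_centre) / cfg$canopy_scale)
  if (cfg$canopy_noise_sd > 0)
    h <- h + gaussian_field(n, n, res, cfg$canopy_noise_corr_m,
                            cfg$canopy_noise_sd)
  h <- matrix(pmax(h, 0), n, n)
  h[mask == 0] <- NA
  list(
    ndvi = raster_layer(ndvi, 0, cfg$grid_size_m, res),
    ndsm = raster_layer(h, 0, cfg$grid_size_m, res),
    veg_mask = raster_layer(mask, 0, cfg$grid_size_m, res),
    cfg = cfg
  )
}

#' Generate a niche-structured species pool
#'
#' Species occupy Gaussian niches along the NDVI axis. Niche centres are a
#' stratified-uniform spread over \[0, 1\] (one species per 1/n slice), so the
#' pool always spans the gradient; habitat classes are assigned by niche
#' centre (low NDVI: human-modified, then open, woodland, and forest at the
#' top), giving classes that are monotone in the niche centre.
#'
#' @param n_species number of species (>= 2).
#' @param seed integer seed.
#' @return data frame with columns `species_id`, `niche_centre`,
#'   `niche_width`, `max_activity`, `habitat_class`.
#' @export
generate_species_pool <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("n_species must be at least 2")
  set.seed(as.integer(seed))
  centres <- (seq_len(n_species) - stats::runif(n_species)) / n_species
  cls <- cut(centres, c(-Inf, 0.25, 0.5, 0.75, Inf),
             labels = c("human-modified", "open", "woodland", "forest"))
  data.frame(
    species_id = sprintf("sp%03d", seq_len(n_species)),
    niche_centre = centres,
    niche_width = stats::runif(n_species, 0.12, 0.30),
    max_activity = stats::runif(n_species, 0.15, 0.80),
    habitat_class = as.character(cls),
    stringsAsFactors = FALSE
  )
}

## Gaussian niche response in [0, 1]
niche_response <- function(ndvi, centre, width) {
  exp(-(ndvi - centre)^2 / (2 * width^2))
}

#' Simulate timestamped acoustic detections for a set of sites
#'
#' For every site x species pair, occupancy is Bernoulli with the Gaussian
#' niche response as probability; if occupied, each 15-minute period of the
#' recording independently contains at least one vocalisation with
#' probability `q = max_activity * niche_response`. Occupied periods receive
#' `1 + Poisson` detections placed uniformly within the period. Detection
#' confidences are a Beta(8, 2) / Beta(2, 4) mixture so that a configurable
#' fraction of rows falls below the 0.8 screening threshold; a configurable
#' number of single-detection noise species-site pairs is injected to
#' exercise the singleton filter.
#'
#' @param sites data frame with columns `site_id` and `days_recorded`
#'   (fractional days; if absent, `days` is used for every site).
#' @param ndvi_at_sites numeric NDVI exposure per site (same order as
#'   `sites`).
#' @param pool species pool from [generate_species_pool()].
#' @param days default recording length in days (> 0).
#' @param seed integer seed.
#' @param low_conf_frac fraction of detections drawn from the low-confidence
#'   Beta(2, 4) component.
#' @param n_noise_singletons number of injected single-detection pairs.
#' @param extra_per_period mean of the Poisson for extra detections within an
#'   occupied period.
#' @return a detection table: `site_id`, `start_s`, `end_s`, `species`,
#'   `confidence`.
#' @export
simulate_detections <- function(sites, ndvi_at_sites, pool, days = 7,
                                seed = 1L, low_conf_frac = 0.1,
                                n_noise_singletons = 0,
                                extra_per_period = 0.4) {
  if (days <= 0) stop("days must be positive")
  if (length(ndvi_at_sites) != nrow(sites))
    stop("ndvi_at_sites must have one value per site")
  set.seed(as.integer(seed))
  days_site <- if ("days_recorded" %in% names(sites)) sites$days_recorded else
    rep(days, nrow(sites))
  rows <- vector("list", nrow(sites) * nrow(pool))
  ri <- 0L
  for (i in seq_len(nrow(sites))) {
    P <- floor(96 * days_site[i])
    for (s in seq_len(nrow(pool))) {
      g <- niche_response(ndvi_at_sites[i], pool$niche_centre[s],
                          pool$niche_width[s])
      if (stats::rbinom(1, 1, g) == 0) next
      q <- pool$max_activity[s] * g
      npds <- stats::rbinom(1, P, q)
      if (npds == 0) next
      bins <- sample.int(P, npds) - 1L
      counts <- 1L + stats::rpois(npds, extra_per_period)
      bin_rep <- rep(bins, counts)
      start <- bin_rep * 900 + stats::runif(length(bin_rep)) * 897
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        site_id = sites$site_id[i], start_s = start, end_s = start + 3,
        species = pool$species_id[s], stringsAsFactors = FALSE)
    }
  }
  det <- if (ri > 0) do.call(rbind, rows[seq_len(ri)]) else
    data.frame(site_id = character(), start_s = numeric(),
               end_s = numeric(), species = character(),
               stringsAsFactors = FALSE)
  if (n_noise_singletons > 0 && nrow(sites) > 0) {
    idx <- sample.int(nrow(sites), n_noise_singletons, replace = TRUE)
    d <- days_site[idx]
    start <- stats::runif(n_noise_singletons) * d * 86400 - 3
    noise <- data.frame(
      site_id = sites$site_id[idx], start_s = pmax(start, 0),
      end_s = pmax(start, 0) + 3,
      species = sprintf("noise%03d", seq_len(n_noise_singletons)),
      stringsAsFactors = FALSE)
    det <- rbind(det, noise)
  }
  n <- nrow(det)
  if (n > 0) {
    low <- stats::runif(n) < low_conf_frac
    conf <- numeric(n)
    conf[low] <- stats::rbeta(sum(low), 2, 4)
    conf[!low] <- stats::rbeta(sum(!low), 8, 2)
    det$confidence <- conf
    det <- det[order(det$site_id, det$start_s), , drop = FALSE]
    rownames(det) <- NULL
  } else det$confidence <- numeric(0)
  det
}

#' Analytic expected site metrics under the generating niche model
#'
#' Closed-form expectations used as oracles in recovery tests: expected
#' richness is the sum of occupancy probabilities; expected total VAR is
#' `sum(occupancy * 96 * q)` per day; Shannon diversity is computed from the
#' expected VAR shares.
#'
#' @param pool species pool from [generate_species_pool()].
#' @param ndvi scalar NDVI exposure.
#' @return list with `richness`, `var_total`, `shannon`.
#' @export
expected_metrics <- function(pool, ndvi) {
  g <- niche_response(ndvi, pool$niche_centre, pool$niche_width)
  occ <- g
  q <- pool$max_activity * g
  ev <- occ * 96 * q
  vt <- sum(ev)
  p <- ev[ev > 0] / vt
  list(richness = sum(occ), var_total = vt,
       shannon = if (length(p) <= 1) 0 else -sum(p * log(p)))
}

#' Place monitoring sites with a minimum separation
#'
#' Uniform rejection sampling inside the landscape minus an edge margin,
#' enforcing a pairwise minimum distance; mirrors a field design in which
#' sites must be far enough apart to be treated as independent.
#'
#' @param n_sites number of sites.
#' @param grid_size_m landscape edge length (m).
#' @param min_separation_m pairwise minimum distance (m).
#' @param margin_m keep-out margin from the landscape edge (m), e.g. the
#'   largest buffer radius that must stay inside the raster.
#' @param weeks vector of recording-week labels to assign cyclically.
#' @param mean_days,sd_days,max_days recording effort distribution: days
#'   recorded per site are Normal(mean, sd) truncated to \[3, max_days\].
#' @param seed integer seed.
#' @return data frame `site_id`, `x`, `y`, `week`, `days_recorded`.
#' @export
place_sites <- function(n_sites, grid_size_m, min_separation_m = 300,
                        margin_m = 800, weeks = c(14, 27, 29, 31),
                        mean_days = 6.49, sd_days = 1.11, max_days = 7,
                        seed = 1L) {
  set.seed(as.integer(seed))
  lo <- margin_m; hi <- grid_size_m - margin_m
  if (hi <= lo) stop("margin too large for the landscape")
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L; cap <- 2000L * n_sites
  while (length(xs) < n_sites && tries < cap) {
    tries <- tries + 1L
    px <- stats::runif(1, lo, hi); py <- stats::runif(1, lo, hi)
    if (length(xs) == 0 ||
        min((xs - px)^2 + (ys - py)^2) >= min_separation_m^2) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  if (length(xs) < n_sites)
    stop("could not place ", n_sites, " sites at ", min_separation_m,
         " m separation; enlarge the landscape or reduce n_sites")
  d <- pmin(pmax(stats::rnorm(n_sites, mean_days, sd_days), 3), max_days)
  data.frame(
    site_id = sprintf("site%03d", seq_len(n_sites)),
    x = xs, y = ys, week = rep(weeks, length.out = n_sites),
    days_recorded = d, stringsAsFactors = FALSE)
}

#' Species trait table with raw habitat labels
#'
#' Emits an AVONET-style trait table for a species pool, translating the
#' pool's generating habitat class into raw database labels (including the
#' labels that the habitat-reassignment rules collapse, such as Rock,
#' Coastal, Grassland, Shrubland), so that downstream habitat annotation is
#' exercised end to end.
#'
#' @param pool species pool from [generate_species_pool()].
#' @param seed integer seed.
#' @return data frame `species`, `habitat`.
#' @export
species_traits <- function(pool, seed = 1L) {
  set.seed(as.integer(seed))
  raw <- vapply(pool$habitat_class, function(cl) {
    switch(cl,
           "human-modified" = sample(c("Human Modified", "Rock", "Coastal"),
                                     1, prob = c(0.6, 0.2, 0.2)),
           "open" = sample(c("Grassland", "Shrubland"), 1),
           "woodland" = "Woodland",
           "forest" = "Forest",
           "aquatic" = sample(c("Riverine", "Wetland"), 1),
           stop("unknown habitat class: ", cl))
  }, "")
  data.frame(species = pool$species_id, habitat = unname(raw),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic acoustic-monitoring study
#'
#' Generates a landscape, places sites, simulates a species pool and its
#' detection streams (site NDVI exposure is the buffer mean at the generating
#' radius), and returns everything together with the ground truth needed for
#' parameter-recovery tests. Optionally writes all artefacts as plain-text
#' files (ASCII grids, CSVs, a JSON ground truth).
#'
#' @param n_sites,n_species study dimensions.
#' @param landscape a [landscape_config()].
#' @param exposure_radius_m the generating buffer radius: site NDVI exposure
#'   is the NDVI buffer mean at this radius (m).
#' @param min_separation_m pairwise minimum site distance (m).
#' @param margin_m site keep-out margin from the landscape edge (m).
#' @param seed master seed; stage seeds are derived from it.
#' @param low_conf_frac,n_noise_singletons passed to
#'   [simulate_detections()].
#' @param out_dir if non-`NULL`, write landscape/sites/detections/traits and
#'   the ground truth under this directory.
#' @return list with `landscape` (ndvi/ndsm/veg_mask rasters), `sites`,
#'   `pool`, `detections`, `traits`, `truth`.
#' @export
simulate_study <- function(n_sites = 86, n_species = 40,
                           landscape = landscape_config(seed = seed),
                           exposure_radius_m = 100, min_separation_m = 300,
                           margin_m = 800, seed = 1L, low_conf_frac = 0.1,
                           n_noise_singletons = 10, out_dir = NULL) {
  seed <- as.integer(seed)
  land <- generate_landscape(landscape)
  sites <- place_sites(n_sites, landscape$grid_size_m,
                       min_separation_m = min_separation_m,
                       margin_m = margin_m, seed = seed + 1L)
  ndvi_exp <- vapply(seq_len(n_sites), function(i)
    buffer_mean(land$ndvi, c(sites$x[i], sites$y[i]), exposure_radius_m,
                warn_partial = FALSE), 0)
  pool <- generate_species_pool(n_species, seed = seed + 2L)
  det <- simulate_detections(sites, ndvi_exp, pool, seed = seed + 3L,
                             low_conf_frac = low_conf_frac,
                             n_noise_singletons = n_noise_singletons)
  traits <- species_traits(pool, seed = seed + 4L)
  truth <- list(exposure_radius_m = exposure_radius_m,
                landscape = unclass(landscape), pool = pool,
                ndvi_at_sites = ndvi_exp)
  out <- list(landscape = land, sites = sites, pool = pool, detections = det,
              traits = traits, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ascii_grid(land$ndvi, file.path(out_dir, "ndvi.asc"))
    write_ascii_grid(land$ndsm, file.path(out_dir, "ndsm.asc"))
    write_ascii_grid(land$veg_mask, file.path(out_dir, "veg_mask.asc"))
    utils::write.csv(sites, file.path(out_dir, "sites.csv"),
                     row.names = FALSE)
    utils::write.csv(det, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth[c("exposure_radius_m", "landscape",
                                 "ndvi_at_sites")],
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Generate site diversity metrics linearly from a vegetation predictor
#'
#' Ground-truth generator for model-recovery experiments: a metric is
#' `intercept + slope * predictor + week effects + dist_effect * distance_km
#' + Gaussian noise`. Used to test slope recovery, buffer-scale recovery and
#' predictor ranking, where the generating scale and slope are known.
#'
#' @param predictor numeric vector (e.g. 100 m-buffer NDVI per site).
#' @param week factor or vector of week labels per site.
#' @param distance_km distance to the city centre per site (km).
#' @param slope,intercept generating coefficients.
#' @param week_effects named or positional effects added per week level
#'   (recycled over `levels(factor(week))`; first level is the reference 0 if
#'   fewer effects than levels are given).
#' @param dist_effect linear distance effect per km.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return numeric vector of generated metric values.
#' @export
generate_linear_metric <- function(predictor, week, distance_km, slope,
                                   intercept = 0,
                                   week_effects = NULL, dist_effect = 0,
                                   noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  wf <- factor(week)
  we <- if (is.null(week_effects)) rep(0, nlevels(wf)) else
    rep(week_effects, length.out = nlevels(wf))
  intercept + slope * predictor + we[as.integer(wf)] +
    dist_effect * distance_km +
    stats::rnorm(length(predictor), sd = noise_sd)
}
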