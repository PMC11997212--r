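#' Pipeline configuration
#'
#' All thresholds, radii, permutation counts and stage seeds of the
#' end-to-end analysis, as one round-trippable list. Every source of
#' randomness is an explicit named seed; no stage consumes hidden global RNG
#' state.
#'
#' @param min_conf detection confidence threshold.
#' @param rare_max_total rare-species review flag threshold.
#' @param removals species removed after manual review.
#' @param radii buffer radii (m).
#' @param prediction_res prediction grid resolution (m).
#' @param train_fraction train share of the train/test split.
#' @param n_perm permutation count for Moran's I, envfit, Mantel, PROTEST.
#' @param nmds_starts random starts for each NMDS.
#' @param seed master seed; per-stage seeds derive from it.
#' @param shannon_ndvi_log log-transform NDVI in the Shannon models
#'   (requires positive buffer NDVI).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_conf = 0.8, rare_max_total = 10,
                            removals = character(),
                            radii = c(25, 50, 100, 200, 400, 800),
                            prediction_res = 100, train_fraction = 0.8,
                            n_perm = 999, nmds_starts = 20, seed = 1L,
                            shannon_ndvi_log = TRUE) {
  structure(list(min_conf = min_conf, rare_max_total = rare_max_total,
                 removals = removals, radii = radii,
                 prediction_res = prediction_res,
                 train_fraction = train_fraction, n_perm = n_perm,
                 nmds_starts = nmds_starts, seed = as.integer(seed),
                 shannon_ndvi_log = shannon_ndvi_log),
            class = "pipeline_config")
}

#' Read and write a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config` equal to the one
#'   written.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$removals <- as.character(raw$removals %||% character())
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full diversity-prediction pipeline
#'
#' Orchestrates every stage on in-memory inputs: acoustic filtering and VAR
#' metrics; buffer extraction at all radii; per-buffer linear models with
#' partial R-squared and buffer-scale selection; NDVI vs vegetation-volume
#' comparison and residual Moran's I at the chosen scale; community
#' ordination (log1p Bray-Curtis NMDS rotated to NDVI, environmental fit,
#' habitat annotation, presence-absence Jaccard NMDS, Procrustes and Mantel
#' concordance); and train/test predictive mapping with RMSE, MAE and SMA
#' evaluation. When `out_dir` is given, all tables are written as CSV/JSON
#' together with a manifest of seeds, versions and input checksums.
#'
#' @param detections detection table (see [read_detections()]).
#' @param sites data frame `site_id`, `x`, `y`, `week`, `days_recorded`.
#' @param ndvi,volume `raster_layer`s of NDVI and per-cell vegetation
#'   volume.
#' @param centre city-centre coordinate `c(x, y)` (m).
#' @param traits optional species trait table for habitat annotation.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of stage results: `metrics`, `buffers`, `partial_r2_table`,
#'   `buffer_choice`, `predictor_comparison`, `best_fits`, `morans`,
#'   `ordination`, `prediction`.
#' @export
run_pipeline <- function(detections, sites, ndvi, volume, centre,
                         traits = NULL, cfg = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  need <- c("site_id", "x", "y", "week", "days_recorded")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("stage metrics: sites table lacks columns ",
         paste(miss, collapse = ", "))

  ## -- acoustic metrics ------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ac <- tryCatch(
    acoustic_pipeline(detections, sites, min_conf = cfg$min_conf,
                      rare_max_total = cfg$rare_max_total,
                      removals = cfg$removals),
    error = function(e) stop("stage metrics: ", conditionMessage(e),
                             call. = FALSE))
  metrics <- site_diversity(ac$var_table, site_ids = sites$site_id)
  stage_msg("metrics", t0)

  ## -- buffers ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  buffers <- tryCatch(
    site_buffer_table(sites, ndvi, volume, radii = cfg$radii,
                      warn_partial = FALSE),
    error = function(e) stop("stage buffers: ", conditionMessage(e),
                             call. = FALSE))
  stage_msg("buffers", t0)

  ## model frame: metrics + buffer columns per radius
  dist_km <- distance_to_centre(sites[c("x", "y")], centre) / 1000
  base <- merge(metrics, sites[c("site_id", "week")], by = "site_id")
  base$distance_km <- dist_km[match(base$site_id, sites$site_id)]

  model_frame <- function(radius) {
    b <- buffers[buffers$radius_m == radius,
                 c("site_id", "mean_ndvi", "log_veg_volume")]
    merge(base, b, by = "site_id")
  }
  responses <- c("richness", "var_total", "shannon")
  predictors <- c("mean_ndvi", "log_veg_volume")
  ## the Shannon-model NDVI log transform needs positive buffer NDVI
  ## everywhere; fall back to the identity otherwise
  ndvi_all_pos <- all(buffers$mean_ndvi > 0)
  if (cfg$shannon_ndvi_log && !ndvi_all_pos)
    warning("non-positive buffer NDVI encountered; Shannon models use ",
            "untransformed NDVI")
  transform_for <- function(resp, pred) {
    if (resp == "shannon" && pred == "mean_ndvi" && cfg$shannon_ndvi_log &&
        ndvi_all_pos) "log" else "none"
  }

  ## -- fits over all radii + buffer selection ---------------------------
  t0 <- as.numeric(Sys.time())
  pr2 <- expand.grid(metric = responses, predictor = predictors,
                     buffer_m = cfg$radii, stringsAsFactors = FALSE)
  pr2$partial_r2 <- NA_real_
  pr2$r2 <- NA_real_
  for (i in seq_len(nrow(pr2))) {
    df <- model_frame(pr2$buffer_m[i])
    fit <- fit_diversity_model(df, pr2$metric[i], pr2$predictor[i],
                               buffer_m = pr2$buffer_m[i],
                               transform = transform_for(pr2$metric[i],
                                                         pr2$predictor[i]))
    pr2$partial_r2[i] <- partial_r2(fit, "predictor")
    pr2$r2[i] <- fit$r2
  }
  choice <- buffer_selection(pr2)
  best_radius <- choice$best_buffer
  stage_msg("fit", t0)

  ## -- best-buffer models, comparison, Moran's I ------------------------
  t0 <- as.numeric(Sys.time())
  best_df <- model_frame(best_radius)
  best_fits <- list()
  for (resp in responses) for (pred in predictors)
    best_fits[[paste(resp, pred, sep = ".")]] <-
      fit_diversity_model(best_df, resp, pred, buffer_m = best_radius,
                          transform = transform_for(resp, pred))
  r2tab <- data.frame(
    metric = rep(responses, each = length(predictors)),
    predictor = rep(predictors, times = length(responses)),
    r2 = vapply(best_fits[paste(rep(responses, each = length(predictors)),
                                rep(predictors, times = length(responses)),
                                sep = ".")], function(f) f$r2, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  comparison <- compare_predictors(r2tab)
  xy <- sites[match(best_df$site_id, sites$site_id), c("x", "y")]
  morans <- lapply(stats::setNames(responses, responses), function(resp) {
    f <- best_fits[[paste(resp, comparison$best_predictor, sep = ".")]]
    morans_i_test(stats::residuals(f$lm), xy, n_perm = cfg$n_perm,
                  seed = cfg$seed + 11L)
  })
  stage_msg("compare", t0)

  ## -- ordination --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  comm <- community_matrix(ac$var_table)
  ord_df <- best_df[best_df$site_id %in% rownames(comm), , drop = FALSE]
  comm <- comm[match(ord_df$site_id, rownames(comm)), , drop = FALSE]
  Dbc <- bray_curtis(comm, log1p = TRUE)
  ordv <- nmds(Dbc, k = 2, n_starts = cfg$nmds_starts,
               seed = cfg$seed + 21L)
  ordv <- rotate_to_variable(ordv, ord_df$mean_ndvi)
  envdf <- data.frame(mean_ndvi = ord_df$mean_ndvi,
                      log_veg_volume = ord_df$log_veg_volume,
                      distance_km = ord_df$distance_km,
                      week = factor(ord_df$week))
  ef <- env_fit(ordv, envdf, n_perm = cfg$n_perm, seed = cfg$seed + 22L)
  habitat <- if (!is.null(traits))
    assign_habitat(traits, community_species = colnames(comm)) else NULL
  sp_scores <- species_scores(ordv, comm)
  Xpa <- to_presence_absence(comm)
  Dj <- jaccard_distance(Xpa)
  ordp <- nmds(Dj, k = 2, n_starts = cfg$nmds_starts,
               seed = cfg$seed + 23L)
  conc <- procrustes_protest(ordv$points, ordp$points, n_perm = cfg$n_perm,
                             seed = cfg$seed + 24L)
  mant <- mantel_test(Dbc, Dj, n_perm = cfg$n_perm, seed = cfg$seed + 25L)
  ordination <- list(var_nmds = ordv, pa_nmds = ordp, envfit = ef,
                     species_scores = sp_scores, habitat = habitat,
                     procrustes = conc, mantel = mant)
  stage_msg("ordinate", t0)

  ## -- prediction --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sp <- split_data(best_df, cfg$train_fraction, seed = cfg$seed + 31L)
  ndvi_pred <- aggregate_raster(ndvi, cfg$prediction_res, "mean")
  prediction <- list(split_n = c(train = nrow(sp$train),
                                 test = nrow(sp$test)))
  for (resp in responses) {
    f <- fit_diversity_model(sp$train, resp, "mean_ndvi",
                             buffer_m = best_radius,
                             transform = transform_for(resp, "mean_ndvi"))
    grid <- predict_grid(f, ndvi_pred, centre)
    nd <- sp$test
    px <- nd$mean_ndvi
    if (f$transform == "log") px <- log(px)
    ## held-out prediction uses the site's actual week, as in evaluation
    pred_obs <- stats::predict(
      f$lm, newdata = data.frame(week = factor(nd$week,
                                               levels = f$week_levels),
                                 distance_km = nd$distance_km, .pred = px))
    ev <- evaluate_predictions(pred_obs, nd[[resp]])
    sma <- sma_regression(nd[[resp]], pred_obs)
    prediction[[resp]] <- list(fit = f, grid = grid, rmse = ev$rmse,
                               mae = ev$mae, sma = sma)
  }
  stage_msg("predict", t0)

  res <- list(metrics = metrics, var_table = ac$var_table,
              buffers = buffers, partial_r2_table = pr2,
              buffer_choice = choice, predictor_comparison = comparison,
              best_fits = best_fits, morans = morans,
              ordination = ordination, prediction = prediction,
              config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, sites, out_dir)
  invisible(res)
}

## write stage outputs + manifest; plain-text formats only
write_pipeline_outputs <- function(res, sites, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(res$metrics, "site_metrics.csv")
  wcsv(res$var_table, "var_table.csv")
  wcsv(res$buffers, "buffer_table.csv")
  wcsv(res$partial_r2_table, "partial_r2_table.csv")
  scores <- data.frame(site_id = sites$site_id[
    match(rownames(res$ordination$var_nmds$points), sites$site_id)],
    res$ordination$var_nmds$points)
  wcsv(scores, "nmds_site_scores.csv")
  report <- list(
    best_buffer_m = res$buffer_choice$best_buffer,
    predictor_comparison = res$predictor_comparison[
      c("mean_r2", "best_predictor", "relative_gain",
        "gain_share_of_best")],
    morans = res$morans,
    ordination = list(
      stress_var = res$ordination$var_nmds$stress,
      stress_pa = res$ordination$pa_nmds$stress,
      envfit_vectors = res$ordination$envfit$vectors,
      procrustes = res$ordination$procrustes,
      mantel = res$ordination$mantel),
    prediction = lapply(
      res$prediction[setdiff(names(res$prediction), "split_n")],
      function(p) list(rmse = p$rmse, mae = p$mae,
                       sma_slope = p$sma$slope,
                       sma_intercept = p$sma$intercept, r = p$sma$r)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (resp in setdiff(names(res$prediction), "split_n"))
    write_ascii_grid(res$prediction[[resp]]$grid$grid,
                     file.path(out_dir, paste0("prediction_", resp, ".asc")))
  outs <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(
    file = basename(outs), md5 = as.character(tools::md5sum(outs)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("varscape")),
         r_version = R.version.string, seed = res$config$seed,
         files = manifest),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
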