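#' Random train/test split of a site table
#'
#' Uniform random partition without stratification: `ceiling(f * n)` rows go
#' to the training set, the remainder to the test set.
#'
#' @param sites data frame of sites.
#' @param train_fraction fraction in (0, 1) (default 0.8).
#' @param seed optional integer seed.
#' @return list with data frames `train` and `test`.
#' @export
split_data <- function(sites, train_fraction = 0.8, seed = NULL) {
  n <- nrow(sites)
  if (n < 5) stop("need at least 5 sites to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_train <- ceiling(train_fraction * n)
  if (n_train >= n) n_train <- n - 1L
  idx <- sample.int(n, n_train)
  list(train = sites[idx, , drop = FALSE],
       test = sites[-idx, , drop = FALSE])
}

#' City-wide prediction grid from a fitted diversity model
#'
#' Evaluates a fitted `metric ~ week + distance_km + NDVI` model on every
#' cell of a 100 m NDVI grid, averaging the linear predictor over the
#' recording-week levels (equivalent to averaging the dummy effects), with
#' the cell's distance to the city centre as the spatial covariate. Cells
#' whose NDVI is nodata are nodata; cells whose NDVI falls outside the
#' model's training range still receive a prediction but are flagged as
#' extrapolation.
#'
#' @param fit a `div_model` whose predictor is the grid's NDVI.
#' @param ndvi100 `raster_layer` of NDVI at the prediction resolution.
#' @param centre city-centre coordinate `c(x, y)` in metres.
#' @param week_levels week levels to average over (default: the model's).
#' @return list with `grid` (`raster_layer` of predictions), `extrapolated`
#'   (`raster_layer`, 1 where NDVI is outside the training range), `metric`.
#' @export
predict_grid <- function(fit, ndvi100, centre, week_levels = NULL) {
  stopifnot(inherits(fit, "div_model"))
  if (is.null(week_levels)) week_levels <- fit$week_levels
  v <- as.vector(ndvi100$values)
  px <- v
  if (fit$transform == "log") {
    px[!is.na(px) & px <= 0] <- NA
    px <- log(px)
  }
  xs <- cell_xs(ndvi100); ys <- cell_ys(ndvi100)
  cx <- rep(xs, each = nrow(ndvi100$values))
  cy <- rep(ys, times = ncol(ndvi100$values))
  dist_km <- as.vector(sqrt((cx - centre[1])^2 + (cy - centre[2])^2)) / 1000
  ok <- !is.na(px)
  acc <- numeric(sum(ok))
  for (w in week_levels) {
    nd <- data.frame(week = factor(w, levels = fit$week_levels),
                     distance_km = dist_km[ok], .pred = px[ok])
    acc <- acc + stats::predict(fit$lm, newdata = nd)
  }
  pred <- rep(NA_real_, length(v))
  pred[ok] <- acc / length(week_levels)
  extr <- rep(NA_real_, length(v))
  extr[!is.na(v)] <- (v[!is.na(v)] < fit$predictor_range[1] |
                        v[!is.na(v)] > fit$predictor_range[2]) + 0
  nr <- nrow(ndvi100$values)
  list(
    grid = raster_layer(matrix(pred, nr), ndvi100$xmin, ndvi100$ymax,
                        ndvi100$res, ndvi100$crs),
    extrapolated = raster_layer(matrix(extr, nr), ndvi100$xmin,
                                ndvi100$ymax, ndvi100$res, ndvi100$crs),
    metric = fit$response
  )
}

#' Prediction error: RMSE and MAE
#'
#' @param pred,obs numeric vectors of equal, positive length.
#' @return list with `rmse = sqrt(mean((pred - obs)^2))` and
#'   `mae = mean(abs(pred - obs))`.
#' @export
evaluate_predictions <- function(pred, obs) {
  if (length(pred) == 0 || length(pred) != length(obs))
    stop("pred and obs must be non-empty and of equal length")
  e <- pred - obs
  list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Standardised major-axis (model II) regression
#'
#' Symmetric line fitting for observed-vs-predicted comparisons where both
#' axes carry error: `slope = sign(r) * s_y / s_x`,
#' `intercept = mean(y) - slope * mean(x)`. The 95% confidence interval for
#' the slope is `slope * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = (1 - r^2) * F(0.95; 1, n - 2) / (n - 2)`.
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @return list with `slope`, `intercept`, `r`, `ci_slope` (length 2), `n`.
#' @export
sma_regression <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  B <- (1 - r^2) * stats::qf(0.95, 1, n - 2) / (n - 2)
  ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  list(slope = slope, intercept = intercept, r = r, ci_slope = ci, n = n)
}
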