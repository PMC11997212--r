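#' Fit a diversity ~ vegetation linear model
#'
#' Ordinary least squares of a site diversity metric on a vegetation
#' predictor at one buffer radius, with recording week (categorical,
#' dummy-coded against the first level) and distance to the city centre (km,
#' linear) as covariates:
#' `metric ~ week + distance_km + predictor`.
#' The predictor can be log-transformed (used for NDVI in Shannon-diversity
#' models; vegetation volume enters as `log_veg_volume` upstream).
#'
#' @param data data frame containing the response column, the predictor
#'   column, `week` and `distance_km`; must be complete (no `NA`).
#' @param response name of the response column.
#' @param predictor name of the predictor column.
#' @param buffer_m buffer radius the predictor was extracted at (metadata).
#' @param transform `"none"` or `"log"` (natural log of the predictor;
#'   requires positive values).
#' @return object of class `div_model`: the `lm` fit plus `r2`, `adj_r2`,
#'   coefficient table, predictor metadata and training predictor range.
#' @export
fit_diversity_model <- function(data, response, predictor, buffer_m = NA,
                                transform = c("none", "log")) {
  transform <- match.arg(transform)
  need <- c(response, predictor, "week", "distance_km")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[need])) stop("model data contain missing values")
  px <- data[[predictor]]
  if (transform == "log") {
    if (any(px <= 0))
      stop("log transform requires a strictly positive predictor")
    px <- log(px)
  }
  d <- data.frame(.y = data[[response]], week = factor(data$week),
                  distance_km = data$distance_km, .pred = px)
  if (nrow(d) <= nlevels(d$week) + 2)
    stop("too few observations for the model's parameters")
  fit <- stats::lm(.y ~ week + distance_km + .pred, data = d)
  ali <- stats::alias(fit)$Complete
  if (!is.null(ali))
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(ali), collapse = ", "))
  sm <- summary(fit)
  structure(list(
    lm = fit, response = response, predictor = predictor,
    buffer_m = buffer_m, transform = transform,
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    coefficients = stats::coef(sm),
    residual_df = fit$df.residual,
    predictor_range = range(data[[predictor]]),
    week_levels = levels(d$week)
  ), class = "div_model")
}

#' @export
print.div_model <- function(x, ...) {
  cat("<div_model> ", x$response, " ~ week + distance_km + ", x$predictor,
      if (x$transform == "log") " (log)", " @ ", x$buffer_m, " m\n", sep = "")
  cat("  R2 = ", round(x$r2, 4), ", adj R2 = ", round(x$adj_r2, 4),
      ", residual df = ", x$residual_df, "\n", sep = "")
  invisible(x)
}

#' Partial R-squared of a model term
#'
#' For a single-column term, `t^2 / (t^2 + df_residual)` from the term's t
#' statistic. For a multi-column term (the `week` factor), the nested-model
#' form `(R2_full - R2_reduced) / (1 - R2_reduced)`, refitting without the
#' term. Both forms agree for single-column terms.
#'
#' @param fit a `div_model`.
#' @param term `"predictor"`, `"distance_km"` or `"week"`.
#' @return partial R-squared in \[0, 1\].
#' @export
partial_r2 <- function(fit, term = "predictor") {
  stopifnot(inherits(fit, "div_model"))
  internal <- switch(term,
                     predictor = ".pred",
                     distance_km = "distance_km",
                     week = "week",
                     stop("unknown term: ", term))
  if (internal == "week") {
    mf <- stats::model.frame(fit$lm)
    full <- summary(fit$lm)$r.squared
    red <- summary(stats::lm(.y ~ distance_km + .pred, data = mf))$r.squared
    return((full - red) / (1 - red))
  }
  ct <- fit$coefficients
  row <- match(internal, rownames(ct))
  if (is.na(row)) stop("term not in model: ", term)
  t2 <- ct[row, "t value"]^2
  t2 / (t2 + fit$residual_df)
}

#' Stepwise variance-inflation-factor screening
#'
#' Iteratively removes the column with the largest variance inflation factor
#' while any VIF is at or above the threshold. `VIF_j = 1 / (1 - R2_j)` where
#' `R2_j` comes from regressing column j on the remaining columns. Constant
#' columns have infinite VIF and are dropped first, with a warning.
#'
#' @param X data frame or matrix of candidate continuous predictors (at
#'   least two columns).
#' @param threshold VIF threshold (default 5).
#' @return list with `kept` (character), `dropped` (data frame `column`,
#'   `vif` in removal order) and `vifs` (final VIFs of kept columns).
#' @export
vif_step <- function(X, threshold = 5) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least two columns")
  dropped <- data.frame(column = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  vif_of <- function(d) {
    vapply(seq_along(d), function(j) {
      if (stats::var(d[[j]]) == 0) return(Inf)
      dd <- d[-j]
      dd$.resp <- d[[j]]
      r2 <- summary(stats::lm(.resp ~ ., data = dd))$r.squared
      1 / (1 - r2)
    }, 0)
  }
  repeat {
    if (ncol(X) == 1) break
    v <- vif_of(X)
    if (any(is.infinite(v)))
      warning("constant (or aliased) column has infinite VIF: ",
              names(X)[which.max(v)])
    if (max(v) < threshold) break
    j <- which.max(v)
    dropped <- rbind(dropped, data.frame(column = names(X)[j], vif = v[j]))
    X <- X[-j]
  }
  final <- if (ncol(X) >= 2) vif_of(X) else
    stats::setNames(1, names(X))
  list(kept = names(X), dropped = dropped,
       vifs = stats::setNames(as.numeric(final), names(X)))
}

#' Select the optimal buffer radius from a partial R-squared table
#'
#' For every (metric, predictor) combination the buffer with the highest
#' partial R-squared is recorded; the chosen buffer is the modal argmax
#' across combinations. Ties between equally frequent buffers are broken in
#' favour of the buffer with the highest mean partial R-squared across all
#' combinations.
#'
#' @param tab data frame with columns `metric`, `predictor`, `buffer_m`,
#'   `partial_r2`, covering every metric x predictor x buffer cell.
#' @return list with `best_buffer`, `per_combination` (argmax per metric x
#'   predictor) and `counts` (argmax frequency per buffer).
#' @export
buffer_selection <- function(tab) {
  need <- c("metric", "predictor", "buffer_m", "partial_r2")
  stopifnot(all(need %in% names(tab)))
  full <- expand.grid(metric = unique(tab$metric),
                      predictor = unique(tab$predictor),
                      buffer_m = unique(tab$buffer_m),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$metric, d$predictor, d$buffer_m, sep = "\r")
  missing <- full[!(key(full) %in% key(tab)), , drop = FALSE]
  if (nrow(missing))
    stop("partial R2 table is incomplete; missing cells: ",
         paste(apply(missing, 1, paste, collapse = "/"), collapse = "; "))
  combos <- unique(tab[c("metric", "predictor")])
  argmax <- vapply(seq_len(nrow(combos)), function(i) {
    sub <- tab[tab$metric == combos$metric[i] &
                 tab$predictor == combos$predictor[i], ]
    sub$buffer_m[which.max(sub$partial_r2)]
  }, 0)
  combos$best_buffer_m <- argmax
  counts <- table(argmax)
  top <- as.numeric(names(counts)[counts == max(counts)])
  if (length(top) > 1) {
    means <- vapply(top, function(b) mean(tab$partial_r2[tab$buffer_m == b]),
                    0)
    top <- top[which.max(means)]
  }
  list(best_buffer = top, per_combination = combos,
       counts = as.data.frame(counts, responseName = "n_combinations"))
}

#' Compare vegetation predictors by model R-squared
#'
#' Per metric, the predictor whose model has the larger R-squared wins. The
#' summary reports the mean R-squared per predictor and the relative gain of
#' the better predictor under two conventions: `(a - b) / b` (gain relative
#' to the weaker model) and `(a - b) / a` (share of the stronger model's
#' variance explained).
#'
#' @param tab data frame with columns `metric`, `predictor`, `r2`.
#' @return list with `winners` (per metric), `mean_r2` (per predictor),
#'   `relative_gain` and `gain_share_of_best`.
#' @export
compare_predictors <- function(tab) {
  stopifnot(all(c("metric", "predictor", "r2") %in% names(tab)))
  metrics <- unique(tab$metric)
  winners <- data.frame(metric = metrics, winner = NA_character_,
                        r2_winner = NA_real_, r2_other = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(metrics)) {
    sub <- tab[tab$metric == metrics[i], ]
    j <- which.max(sub$r2)
    winners$winner[i] <- sub$predictor[j]
    winners$r2_winner[i] <- sub$r2[j]
    winners$r2_other[i] <- if (nrow(sub) > 1) max(sub$r2[-j]) else NA_real_
  }
  means <- tapply(tab$r2, tab$predictor, mean)
  ord <- order(means, decreasing = TRUE)
  a <- means[ord[1]]; b <- if (length(means) > 1) means[ord[2]] else NA
  list(winners = winners,
       mean_r2 = stats::setNames(as.numeric(means), names(means)),
       best_predictor = names(means)[ord[1]],
       relative_gain = as.numeric((a - b) / b),
       gain_share_of_best = as.numeric((a - b) / a))
}

#' Moran's I test with inverse-distance weights and permutation p-value
#'
#' Global spatial autocorrelation of values at point locations, with weights
#' `w_ij = 1 / d_ij` (zero diagonal):
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' The expected value under the null is `-1 / (n - 1)`; the two-sided p-value
#' comes from random permutations of the values over the locations, using
#' the `(r + 1) / (n_perm + 1)` estimator.
#'
#' @param x numeric values (e.g. model residuals).
#' @param coords two-column matrix/data frame of planar coordinates (m).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `I`, `expected`, `p`.
#' @export
morans_i_test <- function(x, coords, n_perm = 999, seed = NULL) {
  coords <- as.matrix(coords)
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  if (nrow(coords) != n) stop("coords must match x in length")
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate coordinates give infinite weights; jitter the points")
  W <- 1 / d
  diag(W) <- 0
  S0 <- sum(W)
  istat <- function(z) {
    zc <- z - mean(z)
    n * as.numeric(crossprod(zc, W %*% zc)) / (S0 * sum(zc^2))
  }
  obs <- istat(x)
  expected <- -1 / (n - 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) istat(x[sample.int(n)]), 0)
  r <- sum(abs(perm - expected) >= abs(obs - expected))
  list(I = obs, expected = expected, p = (r + 1) / (n_perm + 1))
}
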