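# Independent brute-force oracles and tiny fixture builders.

make_raster <- function(values, res = 1, xmin = 0, ymax = nrow(values) * res) {
  raster_layer(values, xmin = xmin, ymax = ymax, res = res)
}

# all-pixel scan: mean of values whose centres lie within radius (NA dropped)
oracle_buffer_mean <- function(r, point, radius) {
  acc <- c()
  for (i in seq_len(nrow(r$values))) for (j in seq_len(ncol(r$values))) {
    xc <- r$xmin + (j - 0.5) * r$res
    yc <- r$ymax - (i - 0.5) * r$res
    if ((xc - point[1])^2 + (yc - point[2])^2 <= radius^2)
      acc <- c(acc, r$values[i, j])
  }
  mean(acc, na.rm = TRUE)
}

oracle_buffer_density <- function(r, point, radius) {
  acc <- 0; n <- 0
  for (i in seq_len(nrow(r$values))) for (j in seq_len(ncol(r$values))) {
    xc <- r$xmin + (j - 0.5) * r$res
    yc <- r$ymax - (i - 0.5) * r$res
    if ((xc - point[1])^2 + (yc - point[2])^2 <= radius^2) {
      n <- n + 1
      if (!is.na(r$values[i, j])) acc <- acc + r$values[i, j]
    }
  }
  acc / (n * r$res^2)
}

# distinct 15-minute bin count per site x species, by explicit grouping
oracle_var_table <- function(dets, effort, period_s = 900) {
  groups <- split(seq_len(nrow(dets)),
                  paste(dets$site_id, dets$species, sep = "|"))
  out <- do.call(rbind, lapply(groups, function(ix) {
    np <- length(unique(floor(dets$start_s[ix] / period_s)))
    sid <- dets$site_id[ix[1]]
    d <- effort$days_recorded[effort$site_id == sid]
    data.frame(site_id = sid, species = dets$species[ix[1]],
               n_periods = np, var = np / d, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$site_id, out$species), ]
  rownames(out) <- NULL
  out
}

make_detections <- function(site_id, species, start_s, confidence = 0.9) {
  data.frame(site_id = site_id, start_s = start_s, end_s = start_s + 3,
             species = species, confidence = confidence,
             stringsAsFactors = FALSE)
}

# small complete site table for model tests
make_model_frame <- function(n = 86, seed = 1) {
  set.seed(seed)
  data.frame(
    site_id = sprintf("s%03d", seq_len(n)),
    week = rep(c(14, 27, 29, 31), length.out = n),
    distance_km = runif(n, 0, 12),
    mean_ndvi = runif(n, 0.1, 0.8))
}
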