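#' Georeferenced raster grid
#'
#' Lightweight container for a single-band raster on a planar metric
#' coordinate system: a numeric matrix plus the coordinate of the upper-left
#' corner and the (square) cell size. Row 1 of the matrix is the northernmost
#' row. Missing data are represented by `NA`; `NA` cells are never silently
#' treated as zero by the statistics in this package unless an operation's
#' semantics demand it (and then it is documented, as for buffer volume
#' density).
#'
#' @param values numeric matrix of cell values (row 1 = top).
#' @param xmin x coordinate of the left edge (m).
#' @param ymax y coordinate of the top edge (m).
#' @param res cell size in metres (cells are square).
#' @param crs free-text label of the planar CRS; geographic coordinates must
#'   be projected before use.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(values, xmin = 0, ymax = nrow(values) * res, res = 1,
                         crs = "local-metric") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(res) || length(res) != 1 || !is.finite(res) || res <= 0)
    stop("`res` must be a single positive number")
  structure(
    list(values = values, xmin = xmin, ymax = ymax, res = res, crs = crs),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values
  cat("<raster_layer> ", nrow(v), "x", ncol(v), " cells @ ", x$res, " m\n",
      sep = "")
  cat("  extent: x [", x$xmin, ", ", x$xmin + ncol(v) * x$res, "]  y [",
      x$ymax - nrow(v) * x$res, ", ", x$ymax, "]\n", sep = "")
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat("  values: [", signif(rng[1], 4), ", ", signif(rng[2], 4), "], ",
      sum(is.na(v)), " nodata cells\n", sep = "")
  invisible(x)
}

#' @rdname raster_layer
#' @param x a `raster_layer`.
#' @export
is_raster_layer <- function(x) inherits(x, "raster_layer")

## cell-centre coordinate vectors (columns left->right, rows top->bottom)
cell_xs <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$res
cell_ys <- function(r) r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$res

check_same_grid <- function(...) {
  rs <- list(...)
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!identical(dim(r$values), dim(ref$values)))
      stop("raster grids differ in shape: ", paste(dim(ref$values), collapse = "x"),
           " vs ", paste(dim(r$values), collapse = "x"))
    if (abs(r$res - ref$res) > 1e-9 || abs(r$xmin - ref$xmin) > 1e-6 ||
        abs(r$ymax - ref$ymax) > 1e-6)
      stop("rasters are not co-registered (origin/resolution mismatch)")
  }
  invisible(TRUE)
}

#' Normalised Difference Vegetation Index from red and near-infrared bands
#'
#' NDVI = (NIR - Red) / (NIR + Red) per cell; bounded in \[-1, 1\]. Cells
#' where the denominator is zero, or where either band is nodata, are nodata.
#'
#' @param red,nir co-registered `raster_layer` reflectance bands.
#' @return a `raster_layer` of NDVI values.
#' @export
ndvi_from_bands <- function(red, nir) {
  check_same_grid(red, nir)
  den <- nir$values + red$values
  out <- (nir$values - red$values) / den
  out[!is.na(den) & den == 0] <- NA
  raster_layer(out, red$xmin, red$ymax, red$res, red$crs)
}

#' Enhanced Vegetation Index from blue, red and near-infrared bands
#'
#' EVI = 2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1) per cell; nodata on a
#' zero denominator or wherever any band is nodata.
#'
#' @param blue,red,nir co-registered `raster_layer` reflectance bands.
#' @return a `raster_layer` of EVI values.
#' @export
evi_from_bands <- function(blue, red, nir) {
  check_same_grid(blue, red, nir)
  den <- nir$values + 6 * red$values - 7.5 * blue$values + 1
  out <- 2.5 * (nir$values - red$values) / den
  out[!is.na(den) & den == 0] <- NA
  raster_layer(out, red$xmin, red$ymax, red$res, red$crs)
}

#' Per-cell vegetation volume below a canopy surface model
#'
#' On vegetated cells, volume = canopy height x cell area (m^3); non-vegetated
#' cells are nodata. Negative heights are clipped to zero with a warning.
#'
#' @param ndsm `raster_layer` of normalised surface heights in metres.
#' @param veg_mask co-registered `raster_layer`; cells with value > 0 are
#'   treated as vegetated.
#' @return a `raster_layer` of volumes in cubic metres.
#' @export
veg_volume_layer <- function(ndsm, veg_mask) {
  check_same_grid(ndsm, veg_mask)
  h <- ndsm$values
  neg <- !is.na(h) & h < 0
  if (any(neg)) {
    warning(sum(neg), " negative canopy heights clipped to 0")
    h[neg] <- 0
  }
  vol <- h * ndsm$res^2
  vol[is.na(veg_mask$values) | veg_mask$values <= 0] <- NA
  raster_layer(vol, ndsm$xmin, ndsm$ymax, ndsm$res, ndsm$crs)
}

#' Block-aggregate a raster to a coarser resolution
#'
#' Aggregates non-overlapping blocks of cells with `mean` (nodata ignored) or
#' `sum` (nodata treated as absent; blocks that are entirely nodata are
#' nodata). The target resolution must be an integer multiple of the source
#' resolution; trailing rows/columns that do not fill a block are padded with
#' nodata.
#'
#' @param r a `raster_layer`.
#' @param target_res target cell size in metres (>= source resolution).
#' @param stat `"mean"` or `"sum"`.
#' @return a `raster_layer` at the target resolution.
#' @export
aggregate_raster <- function(r, target_res, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  f <- target_res / r$res
  if (target_res < r$res)
    stop("target resolution must be >= source resolution")
  if (abs(f - round(f)) > 1e-8)
    stop("target resolution (", target_res, ") is not an integer multiple of ",
         "the source resolution (", r$res, ")")
  f <- as.integer(round(f))
  m <- r$values
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / f); nc2 <- ceiling(nc / f)
  if (nr2 * f > nr || nc2 * f > nc) {
    pad <- matrix(NA_real_, nr2 * f, nc2 * f)
    pad[seq_len(nr), seq_len(nc)] <- m
    m <- pad
  }
  gr <- rep(seq_len(nr2), each = f)
  gc <- rep(seq_len(nc2), each = f)
  m0 <- m; m0[is.na(m0)] <- 0
  cnt <- (!is.na(m)) + 0
  S <- t(rowsum(t(rowsum(m0, gr)), gc))
  N <- t(rowsum(t(rowsum(cnt, gr)), gc))
  out <- if (stat == "mean") S / N else S
  out[N == 0] <- NA
  raster_layer(out, r$xmin, r$ymax, target_res, r$crs)
}

## indices and values of cells whose centres fall within `radius` of (x, y);
## a cell is in or out as a whole (all-or-nothing on its centre)
buffer_cells <- function(r, x, y, radius) {
  xs <- cell_xs(r); ys <- cell_ys(r)
  jc <- which(abs(xs - x) <= radius)
  ir <- which(abs(ys - y) <= radius)
  clipped <- (x - radius < r$xmin) || (x + radius > r$xmin + ncol(r$values) * r$res) ||
    (y + radius > r$ymax) || (y - radius < r$ymax - nrow(r$values) * r$res)
  if (length(jc) == 0 || length(ir) == 0)
    return(list(values = numeric(0), n = 0L, clipped = clipped))
  d2 <- outer((ys[ir] - y)^2, (xs[jc] - x)^2, "+")
  sel <- d2 <= radius^2
  list(values = r$values[ir, jc, drop = FALSE][sel], n = sum(sel),
       clipped = clipped)
}

#' Mean raster value within a circular buffer
#'
#' Averages the cells whose centres lie within Euclidean distance `radius_m`
#' of `point`; nodata cells are excluded from the mean. A buffer containing no
#' cell centres is an error; a buffer that extends beyond the raster extent is
#' computed from the available cells with a coverage warning.
#'
#' @param r a `raster_layer`.
#' @param point numeric length-2 vector `c(x, y)` in metres.
#' @param radius_m buffer radius in metres.
#' @param warn_partial emit the partial-coverage warning (default `TRUE`).
#' @return the buffer mean (scalar).
#' @export
buffer_mean <- function(r, point, radius_m, warn_partial = TRUE) {
  bc <- buffer_cells(r, point[1], point[2], radius_m)
  if (bc$n == 0)
    stop("no cell centres fall inside the ", radius_m, " m buffer at (",
         point[1], ", ", point[2], ")")
  if (bc$clipped && warn_partial)
    warning("buffer at (", point[1], ", ", point[2], "), radius ", radius_m,
            " m extends beyond the raster extent; mean computed from the ",
            "available cells")
  vals <- bc$values[!is.na(bc$values)]
  if (length(vals) == 0) {
    warning("all cells in buffer are nodata; returning NA")
    return(NA_real_)
  }
  mean(vals)
}

#' Vegetation-volume density within a circular buffer
#'
#' Sums a volume layer over the cells whose centres fall inside the buffer,
#' treating nodata (non-vegetated) cells as zero volume, and divides by the
#' buffer area. The area denominator is the number of in-buffer cells times
#' the cell area, keeping numerator and denominator on the same
#' discretisation.
#'
#' @inheritParams buffer_mean
#' @param volume a `raster_layer` of per-cell volumes (m^3).
#' @return density in m^3/m^2 (scalar, >= 0).
#' @export
buffer_volume_density <- function(volume, point, radius_m, warn_partial = TRUE) {
  bc <- buffer_cells(volume, point[1], point[2], radius_m)
  if (bc$n == 0)
    stop("no cell centres fall inside the ", radius_m, " m buffer at (",
         point[1], ", ", point[2], ")")
  if (bc$clipped && warn_partial)
    warning("buffer at (", point[1], ", ", point[2], "), radius ", radius_m,
            " m extends beyond the raster extent; density computed from the ",
            "available cells")
  sum(bc$values, na.rm = TRUE) / (bc$n * volume$res^2)
}

#' Buffer statistics for every site at every radius
#'
#' For each site and each buffer radius, computes the mean NDVI, the
#' vegetation-volume density (m^3/m^2) and its natural log. Sites with a
#' density of zero get `log(density + eps)` where `eps` is the smallest
#' positive density observed in the table times 1e-3, with a warning.
#'
#' @param sites data frame with columns `site_id`, `x`, `y`.
#' @param ndvi `raster_layer` of NDVI.
#' @param volume `raster_layer` of per-cell vegetation volume (m^3).
#' @param radii numeric vector of buffer radii in metres.
#' @param warn_partial passed to the buffer extractors.
#' @return data frame with columns `site_id`, `radius_m`, `mean_ndvi`,
#'   `veg_volume_density`, `log_veg_volume`.
#' @export
site_buffer_table <- function(sites, ndvi, volume,
                              radii = c(25, 50, 100, 200, 400, 800),
                              warn_partial = TRUE) {
  stopifnot(all(c("site_id", "x", "y") %in% names(sites)))
  grid <- expand.grid(i = seq_len(nrow(sites)), radius_m = radii)
  n <- nrow(grid)
  mnd <- numeric(n); den <- numeric(n)
  for (k in seq_len(n)) {
    s <- sites[grid$i[k], ]
    pt <- c(s$x, s$y)
    mnd[k] <- tryCatch(
      buffer_mean(ndvi, pt, grid$radius_m[k], warn_partial = warn_partial),
      error = function(e) stop("site ", s$site_id, ", radius ",
                               grid$radius_m[k], " m: ", conditionMessage(e)))
    den[k] <- tryCatch(
      buffer_volume_density(volume, pt, grid$radius_m[k],
                            warn_partial = warn_partial),
      error = function(e) stop("site ", s$site_id, ", radius ",
                               grid$radius_m[k], " m: ", conditionMessage(e)))
  }
  logv <- rep(NA_real_, n)
  pos <- den > 0
  if (any(!pos)) {
    eps <- if (any(pos)) min(den[pos]) * 1e-3 else 1e-6
    warning(sum(!pos), " site-radius combinations have zero vegetation ",
            "volume density; using log(density + ", signif(eps, 3), ")")
    logv[!pos] <- log(den[!pos] + eps)
  }
  logv[pos] <- log(den[pos])
  data.frame(site_id = sites$site_id[grid$i], radius_m = grid$radius_m,
             mean_ndvi = mnd, veg_volume_density = den, log_veg_volume = logv,
             stringsAsFactors = FALSE)
}

#' Euclidean distance to the city centre
#'
#' @param xy two-column matrix or data frame of planar coordinates in metres
#'   (columns x, y).
#' @param centre numeric length-2 vector `c(x, y)`.
#' @return distances in metres.
#' @export
distance_to_centre <- function(xy, centre) {
  xy <- as.matrix(xy)
  sqrt((xy[, 1] - centre[1])^2 + (xy[, 2] - centre[2])^2)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`NCOLS`, `NROWS`,
#' `XLLCORNER`, `YLLCORNER`, `CELLSIZE`, `NODATA_VALUE`) followed by rows of
#' cell values from north to south.
#'
#' @param r a `raster_layer`.
#' @param path file path.
#' @param nodata sentinel written for `NA` cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `raster_layer`.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  ymin <- r$ymax - nrow(v) * r$res
  hdr <- c(
    paste("NCOLS", ncol(v)), paste("NROWS", nrow(v)),
    paste("XLLCORNER", format(r$xmin, scientific = FALSE)),
    paste("YLLCORNER", format(ymin, scientific = FALSE)),
    paste("CELLSIZE", format(r$res, scientific = FALSE)),
    paste("NODATA_VALUE", nodata)
  )
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- toupper(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE",
            "NODATA_VALUE")
  if (!all(need %in% key)) stop("not an ESRI ASCII grid: ", path)
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(as.integer(val["NROWS"]), as.integer(val["NCOLS"]))))
    stop("grid body does not match header dimensions in ", path)
  m[m == val["NODATA_VALUE"]] <- NA
  raster_layer(m, xmin = val[["XLLCORNER"]],
               ymax = val[["YLLCORNER"]] + val[["NROWS"]] * val[["CELLSIZE"]],
               res = val[["CELLSIZE"]])
}
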