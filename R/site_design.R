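#' Configuration for stratified site selection
#'
#' The selection stratifies a 100 m NDVI grid over concentric distance rings
#' around the city centre crossed with equal-width NDVI bins, and samples
#' cells per stratum subject to a pairwise minimum separation and a maximum
#' fraction of each cell outside the city boundary.
#'
#' @param n_rings number of 3 km distance rings.
#' @param ring_width_m ring width in metres.
#' @param n_bins number of equal-width NDVI bins.
#' @param sites_per_bin_per_ring cells sampled per (ring, bin) stratum.
#' @param min_separation_m pairwise minimum distance between selected cell
#'   centres (m).
#' @param max_outside_fraction maximum fraction of a cell allowed outside the
#'   boundary polygon.
#' @param seed integer seed.
#' @return a `selection_config` list.
#' @export
selection_config <- function(n_rings = 5, ring_width_m = 3000, n_bins = 5,
                             sites_per_bin_per_ring = 2,
                             min_separation_m = 300,
                             max_outside_fraction = 0.25, seed = 1L) {
  stopifnot(n_rings >= 1, ring_width_m > 0, n_bins >= 1,
            sites_per_bin_per_ring >= 1, min_separation_m >= 0,
            max_outside_fraction >= 0, max_outside_fraction <= 1)
  structure(list(n_rings = n_rings, ring_width_m = ring_width_m,
                 n_bins = n_bins,
                 sites_per_bin_per_ring = sites_per_bin_per_ring,
                 min_separation_m = min_separation_m,
                 max_outside_fraction = max_outside_fraction,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Prepare the NDVI raster used for site selection
#'
#' Mean-aggregates the NDVI layer to the selection resolution (100 m) and
#' then sets negative cell values to zero to compress the range of
#' non-vegetated cells. Aggregation happens before zeroing.
#'
#' @param ndvi a `raster_layer` of NDVI.
#' @param target_res selection resolution in metres.
#' @return a `raster_layer`.
#' @export
prepare_selection_raster <- function(ndvi, target_res = 100) {
  agg <- aggregate_raster(ndvi, target_res, "mean")
  agg$values <- pmax(agg$values, 0)
  agg
}

#' Equal-width bin edges over the range of values
#'
#' Splits `[min, max]` into `n_bins` equal-width intervals. Values equal to
#' an interior edge belong to the upper bin; the last bin is right-closed. A
#' zero range falls back to a single bin with a warning.
#'
#' @param values numeric vector (NA ignored).
#' @param n_bins number of bins.
#' @return numeric vector of `n_bins + 1` edges.
#' @export
bin_edges <- function(values, n_bins) {
  r <- range(values, na.rm = TRUE)
  if (diff(r) == 0) {
    warning("values have zero range; using a single bin")
    return(c(r[1], r[1] + 1e-9))
  }
  seq(r[1], r[2], length.out = n_bins + 1)
}

#' @rdname bin_edges
#' @param edges edges from `bin_edges`.
#' @return `assign_bins`: integer bin index per value (NA stays NA).
#' @export
assign_bins <- function(values, edges) {
  n <- length(edges) - 1
  w <- (edges[n + 1] - edges[1]) / n
  b <- floor((values - edges[1]) / w) + 1
  b <- pmin(pmax(b, 1L), n)
  b[is.na(values)] <- NA_integer_
  as.integer(b)
}

## fraction of each cell inside the boundary polygon, by a sub x sub point
## grid per cell (bounds discretisation error at 1/sub^2)
cell_inside_fraction <- function(xs, ys, res, boundary, sub = 10) {
  off <- ((seq_len(sub) - 0.5) / sub - 0.5) * res
  n <- length(xs)
  px <- rep(xs, each = sub * sub) + rep(rep(off, times = sub), times = n)
  py <- rep(ys, each = sub * sub) + rep(rep(off, each = sub), times = n)
  inside <- mgcv::in.out(as.matrix(boundary), cbind(px, py))
  colMeans(matrix(inside, nrow = sub * sub))
}

#' Stratified random selection of monitoring cells
#'
#' Samples raster cells stratified by distance ring x NDVI bin: up to
#' `sites_per_bin_per_ring` cells per stratum, uniformly without replacement
#' among eligible cells. A cell is eligible when at least
#' `1 - max_outside_fraction` of it lies inside the boundary polygon and its
#' centre is at least `min_separation_m` from every already-selected cell
#' (separation is enforced greedily against the full growing set, across all
#' strata). Strata that cannot be filled are reported in the `unfilled`
#' attribute, never fabricated.
#'
#' @param ndvi100 selection raster from [prepare_selection_raster()].
#' @param centre city-centre coordinate `c(x, y)`.
#' @param boundary two-column matrix/data frame of polygon vertices, or
#'   `NULL` for no boundary constraint.
#' @param cfg a [selection_config()].
#' @return data frame `site_id`, `x`, `y`, `ring`, `bin`, `ndvi`; attribute
#'   `unfilled` lists strata with deficits.
#' @export
stratified_select <- function(ndvi100, centre, boundary = NULL,
                              cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  set.seed(cfg$seed)
  v <- ndvi100$values
  xs <- cell_xs(ndvi100); ys <- cell_ys(ndvi100)
  cx <- rep(xs, each = nrow(v))   # column-major order matches as.vector(v)
  cy <- rep(ys, times = ncol(v))
  val <- as.vector(v)
  dist <- sqrt((cx - centre[1])^2 + (cy - centre[2])^2)
  ring <- floor(dist / cfg$ring_width_m) + 1L
  ok <- !is.na(val) & ring <= cfg$n_rings
  edges <- bin_edges(val[ok], cfg$n_bins)
  bin <- assign_bins(val, edges)
  if (!is.null(boundary)) {
    frac <- rep(0, length(val))
    frac[ok] <- cell_inside_fraction(cx[ok], cy[ok], ndvi100$res, boundary)
    ok <- ok & frac >= 1 - cfg$max_outside_fraction
  }
  idx <- which(ok)
  if (length(idx) == 0) stop("no eligible cells: boundary and raster may not overlap")
  sel <- integer(0)
  unfilled <- list()
  strata <- expand.grid(ring = seq_len(cfg$n_rings), bin = seq_len(cfg$n_bins))
  strata <- strata[sample.int(nrow(strata)), , drop = FALSE]
  for (s in seq_len(nrow(strata))) {
    rg <- strata$ring[s]; bn <- strata$bin[s]
    cand <- idx[ring[idx] == rg & bin[idx] == bn]
    cand <- cand[sample.int(length(cand))]
    taken <- 0L
    for (cc in cand) {
      if (taken >= cfg$sites_per_bin_per_ring) break
      if (length(sel) == 0 ||
          min((cx[sel] - cx[cc])^2 + (cy[sel] - cy[cc])^2) >=
            cfg$min_separation_m^2) {
        sel <- c(sel, cc)
        taken <- taken + 1L
      }
    }
    if (taken < cfg$sites_per_bin_per_ring)
      unfilled[[length(unfilled) + 1]] <-
        data.frame(ring = rg, bin = bn,
                   deficit = cfg$sites_per_bin_per_ring - taken)
  }
  out <- data.frame(
    site_id = sprintf("cell%04d", seq_along(sel)),
    x = cx[sel], y = cy[sel], ring = ring[sel], bin = bin[sel],
    ndvi = val[sel], stringsAsFactors = FALSE)
  attr(out, "unfilled") <- if (length(unfilled)) do.call(rbind, unfilled) else
    data.frame(ring = integer(), bin = integer(), deficit = integer())
  out
}

#' Read a boundary polygon from GeoJSON
#'
#' Reads the first (outer) ring of the first Polygon/MultiPolygon feature.
#' Coordinates must already be in the planar metric CRS used by the rasters.
#'
#' @param path GeoJSON file path.
#' @return two-column matrix of vertex coordinates.
#' @export
read_boundary_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(g$features)) g$features$geometry else g
  coords <- if (is.data.frame(geom)) geom$coordinates[[1]] else g$coordinates
  while (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3) coords <- coords[1, , ]
  m <- matrix(as.numeric(coords), ncol = 2)
  colnames(m) <- c("x", "y")
  m
}
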