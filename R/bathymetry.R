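#' Construct a bathymetry grid
#'
#' A regular longitude/latitude raster of sea-floor depth. Depth is positive
#' metres below sea level; values <= 0 encode land. Nodes sit at cell centres,
#' and the resolution must divide one degree evenly so that 1-degree analysis
#' cells align with whole blocks of nodes.
#'
#' @param depth numeric matrix `[n_lat, n_lon]` of node depths (m, positive down).
#' @param lat_min,lon_min southern/western edge of the grid domain (degrees).
#' @param res node spacing in degrees; must divide 1 evenly.
#' @return object of class `bathy_grid` with node coordinate vectors
#'   `lat`, `lon`, the `depth` matrix and `res`.
#' @export
bathy_grid <- function(depth, lat_min, lon_min, res) {
  stopifnot(is.matrix(depth), res > 0)
  per_deg <- 1 / res
  if (abs(per_deg - round(per_deg)) > 1e-9) {
    stop("resolution must divide 1 degree evenly")
  }
  g <- structure(list(
    depth = depth,
    lat = lat_min + res * (seq_len(nrow(depth)) - 0.5),
    lon = lon_min + res * (seq_len(ncol(depth)) - 0.5),
    lat_min = lat_min, lon_min = lon_min,
    res = res
  ), class = "bathy_grid")
  g
}

#' @export
print.bathy_grid <- function(x, ...) {
  sea <- x$depth > 0
  cat(sprintf(
    "bathy_grid: %d x %d nodes at %g deg, lat [%g, %g), lon [%g, %g)\n",
    nrow(x$depth), ncol(x$depth), x$res,
    x$lat_min, x$lat_min + nrow(x$depth) * x$res,
    x$lon_min, x$lon_min + ncol(x$depth) * x$res))
  cat(sprintf("  sea fraction %.2f, depth range %g-%g m\n",
              mean(sea), min(x$depth[sea]), max(x$depth[sea])))
  invisible(x)
}

# nearest-node row/col indices for coordinate vectors; NA outside the domain
node_index <- function(grid, lat, lon) {
  i <- floor((lat - grid$lat_min) / grid$res) + 1L
  j <- floor((lon - grid$lon_min) / grid$res) + 1L
  i[i < 1L | i > nrow(grid$depth)] <- NA_integer_
  j[j < 1L | j > ncol(grid$depth)] <- NA_integer_
  list(i = i, j = j)
}

#' Sea-floor depth at a coordinate
#'
#' Nearest-node lookup; vectorised over coordinates.
#'
#' @param grid a [bathy_grid()].
#' @param lat,lon decimal degrees.
#' @return depth in metres (positive down; <= 0 means land).
#' @export
depth_at <- function(grid, lat, lon) {
  ix <- node_index(grid, lat, lon)
  if (anyNA(ix$i) || anyNA(ix$j)) stop("coordinate outside bathymetry domain")
  grid$depth[cbind(ix$i, ix$j)]
}

#' Depth envelope of one 1-degree cell
#'
#' Samples a 10 x 10 regular lattice of points inside the 1 x 1 degree cell
#' (offsets 0.05, 0.15, ..., 0.95 from the cell's SW corner), looks up the
#' nearest-node depth at each, and returns min/max over the points that fall
#' on sea floor.
#'
#' @param grid a [bathy_grid()].
#' @param lat_bin,lon_bin integer southern/western edge of the cell (degrees).
#' @return list with `min`, `max` (m) and `has_sea`; min/max are `NA` on
#'   all-land cells.
#' @export
cell_envelope <- function(grid, lat_bin, lon_bin) {
  off <- seq(0.05, 0.95, by = 0.1)
  pts <- expand.grid(lat = lat_bin + off, lon = lon_bin + off)
  d <- depth_at(grid, pts$lat, pts$lon)
  sea <- d > 0
  if (!any(sea)) return(list(min = NA_real_, max = NA_real_, has_sea = FALSE))
  list(min = min(d[sea]), max = max(d[sea]), has_sea = TRUE)
}

# Precompute cell envelopes for every 1-degree cell of the grid.
# Returns list(lat_bins, lon_bins, min, max) with [lat, lon] matrices.
cell_envelopes <- function(grid) {
  per <- as.integer(round(1 / grid$res))
  n_lat <- nrow(grid$depth) %/% per
  n_lon <- ncol(grid$depth) %/% per
  lat_bins <- grid$lat_min + seq_len(n_lat) - 1
  lon_bins <- grid$lon_min + seq_len(n_lon) - 1
  # The lattice offsets map to the same within-cell node sub-indices for every
  # cell, so the 10x10 nearest-node sampling reduces to a fixed index set per
  # block; min/max over that set reproduces cell_envelope() exactly.
  off <- seq(0.05, 0.95, by = 0.1)
  sub <- sort(unique(pmin(floor(off / grid$res) + 1L, per)))
  mn <- matrix(NA_real_, n_lat, n_lon)
  mx <- matrix(NA_real_, n_lat, n_lon)
  for (bi in seq_len(n_lat)) {
    rows <- (bi - 1L) * per + sub
    block <- grid$depth[rows, , drop = FALSE]
    for (bj in seq_len(n_lon)) {
      cols <- (bj - 1L) * per + sub
      d <- block[, cols]
      sea <- d > 0
      if (any(sea)) {
        mn[bi, bj] <- min(d[sea])
        mx[bi, bj] <- max(d[sea])
      }
    }
  }
  list(lat_bins = lat_bins, lon_bins = lon_bins, min = mn, max = mx)
}

#' Sea-floor depth envelope of a 1-degree latitude band
#'
#' Aggregates [cell_envelope()] results across a longitude range: minimum of
#' cell minima, maximum of cell maxima, `has_sea` if any cell has sea floor.
#' The default range is the full grid; passing a species' observed
#' longitudinal extent restricts the envelope to sea floor the species could
#' plausibly occupy.
#'
#' @param grid a [bathy_grid()].
#' @param lat_bin integer southern edge of the band.
#' @param lon_range optional numeric length-2 `c(min, max)` in degrees;
#'   default all longitudes.
#' @return one-row data.frame `lat_bin, min_depth_m, max_depth_m, has_sea`.
#' @export
latitude_envelope <- function(grid, lat_bin, lon_range = NULL) {
  ce <- cell_envelopes(grid)
  envelope_from_cells(ce, lat_bin, lon_range)
}

envelope_from_cells <- function(ce, lat_bin, lon_range = NULL) {
  bi <- match(lat_bin, ce$lat_bins)
  if (is.na(bi)) stop("latitude bin outside grid domain")
  keep <- if (is.null(lon_range)) rep(TRUE, length(ce$lon_bins)) else
    ce$lon_bins + 1 > lon_range[1] & ce$lon_bins < lon_range[2]
  mn <- ce$min[bi, keep]
  mx <- ce$max[bi, keep]
  if (all(is.na(mn))) {
    data.frame(lat_bin = lat_bin, min_depth_m = NA_real_,
               max_depth_m = NA_real_, has_sea = FALSE)
  } else {
    data.frame(lat_bin = lat_bin, min_depth_m = min(mn, na.rm = TRUE),
               max_depth_m = max(mx, na.rm = TRUE), has_sea = TRUE)
  }
}

#' Depth envelopes for every latitude band
#'
#' @param grid a [bathy_grid()].
#' @param lon_range optional `c(min, max)` longitude restriction.
#' @return data.frame with one row per 1-degree latitude bin:
#'   `lat_bin, min_depth_m, max_depth_m, has_sea`.
#' @export
latitude_envelopes <- function(grid, lon_range = NULL) {
  ce <- cell_envelopes(grid)
  do.call(rbind, lapply(ce$lat_bins, function(b)
    envelope_from_cells(ce, b, lon_range)))
}
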