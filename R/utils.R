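#' Round half-up to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; published coverage percentages use
#' conventional half-up rounding (e.g. 82.15 -> 82.2), so reports go through
#' this helper.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .5 still round up
  floor(abs(x) * scale + 0.5 + 1e-9) / scale * sign(x)
}

#' Percentage of a count over a total, half-up to one decimal
#'
#' @param n numerator count.
#' @param total denominator count (> 0).
#' @return percentage rounded half-up to 1 decimal.
#' @export
percent_of <- function(n, total) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, 1)
}

#' Great-circle midpoint of two coordinates
#'
#' Used to collapse trawl start/end extents to a single record coordinate.
#'
#' @param lat1,lon1,lat2,lon2 decimal-degree coordinates.
#' @return named numeric vector `c(lat, lon)`.
#' @export
gc_midpoint <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  l1 <- lon1 * to_rad; l2 <- lon2 * to_rad
  bx <- cos(p2) * cos(l2 - l1)
  by <- cos(p2) * sin(l2 - l1)
  lat <- atan2(sin(p1) + sin(p2), sqrt((cos(p1) + bx)^2 + by^2))
  lon <- l1 + atan2(by, cos(p1) + bx)
  out <- c(lat = lat / to_rad, lon = ((lon / to_rad + 180) %% 360) - 180)
  out
}

# Parse "a:b;c:d" interval strings into a 2-column matrix (lower, upper).
# Empty string -> zero-row matrix.
parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lower", "upper"))))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- t(vapply(strsplit(parts, ":", fixed = TRUE),
                  function(p) as.numeric(p[1:2]), numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

format_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) return("")
  paste(sprintf("%g:%g", m[, 1], m[, 2]), collapse = ";")
}

# TRUE where x falls inside any closed interval of matrix m (rows lower,upper).
in_any_interval <- function(x, m) {
  if (is.null(m) || nrow(m) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(m))) hit <- hit | (x >= m[i, 1] & x <= m[i, 2])
  hit
}

# Collapse a sorted logical vector over integer bins into maximal runs,
# returning a 2-col matrix of [first, last] bin labels for TRUE runs.
runs_to_intervals <- function(bins, keep) {
  stopifnot(length(bins) == length(keep))
  if (!any(keep)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lower", "upper"))))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  out <- cbind(lower = bins[starts[idx]], upper = bins[ends[idx]])
  out
}

#' Coastline-length habitat-complexity ratio
#'
#' Ratio of northern-tropical to southern-tropical coastline length, a crude
#' index of shallow-habitat spatial complexity on either side of the Equator.
#'
#' @param north_km,south_km coastline lengths in kilometres (both > 0).
#' @return the dimensionless ratio north/south.
#' @export
coastline_ratio <- function(north_km, south_km) {
  stopifnot(is.finite(north_km), is.finite(south_km), north_km > 0, south_km > 0)
  north_km / south_km
}

#' Load the bundled tropical coastline-length table
#'
#' Lengths (km) of tropical coastline north and south of the Equator per ocean
#' basin, measured from the Natural Earth 10-m coastline shapefile. Shipped as
#' plain CSV so ratio checks run without GIS software.
#'
#' @return data.frame with columns basin, sector, length_km.
#' @export
coastline_lengths <- function() {
  path <- system.file("extdata", "coastline_lengths.csv", package = "bathyrich",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
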