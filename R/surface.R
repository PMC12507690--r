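# Latitude x depth grids: richness, sampling effort, effort offsets,
# interpolation-uncertainty maps and stratum decline summaries.

new_lat_depth_grid <- function(values, lat_bins, depth_breaks, value_kind) {
  stopifnot(nrow(values) == length(lat_bins),
            ncol(values) == length(depth_breaks) - 1L)
  dimnames(values) <- list(lat_bins, depth_breaks[-length(depth_breaks)])
  structure(list(values = values, lat_bins = lat_bins,
                 depth_breaks = depth_breaks, value_kind = value_kind),
            class = "lat_depth_grid")
}

#' @export
print.lat_depth_grid <- function(x, ...) {
  cat(sprintf("lat_depth_grid (%s): %d lat bins x %d depth bins, range [%g, %g]\n",
              x$value_kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Species richness surface from an occupancy cube
#'
#' Counts, for every latitude x depth cell, the number of species present.
#'
#' @param cube an `occupancy_cube`.
#' @return a `lat_depth_grid` of integer richness.
#' @export
richness <- function(cube) {
  v <- if (dim(cube$presence)[1] == 0) {
    matrix(0L, length(cube$lat_bins), length(cube$depth_breaks) - 1L)
  } else {
    colSums(cube$presence)
  }
  new_lat_depth_grid(v, cube$lat_bins, cube$depth_breaks, "richness")
}

#' Latitudinal diversity curve at one depth
#'
#' Extracts the grid row whose half-open depth bin contains `depth_m` (a
#' depth on a bin edge falls in the bin starting there).
#'
#' @param grid a `lat_depth_grid`.
#' @param depth_m depth in metres, inside the grid's depth domain.
#' @return named numeric vector over latitude bins.
#' @export
latitudinal_curve <- function(grid, depth_m) {
  k <- findInterval(depth_m, grid$depth_breaks)
  if (k < 1 || k >= length(grid$depth_breaks)) {
    stop("depth outside the grid's depth domain")
  }
  stats::setNames(grid$values[, k], grid$lat_bins)
}

#' Sampling-effort grid
#'
#' Record counts per 1-degree latitude x 100-m depth cell. Records with
#' missing depth, or falling outside the axes, are not counted.
#'
#' @param records occurrence data.frame with resolved depths.
#' @param lat_bins integer latitude bins (default spanned by the records).
#' @param depth_breaks depth edges (default 100-m bins to 6000 m).
#' @return a `lat_depth_grid` of counts.
#' @export
effort_grid <- function(records, lat_bins = NULL,
                        depth_breaks = uniform_depth_breaks()) {
  if (is.null(lat_bins)) {
    lat_bins <- if (nrow(records) == 0) 0L else
      seq(floor(min(records$decimalLatitude)),
          floor(max(records$decimalLatitude)))
  }
  m <- matrix(0, length(lat_bins), length(depth_breaks) - 1L)
  ok <- !is.na(records$depth_m) &
    records$depth_m >= depth_breaks[1] &
    records$depth_m < depth_breaks[length(depth_breaks)]
  li <- match(floor(records$decimalLatitude[ok]), lat_bins)
  di <- findInterval(records$depth_m[ok], depth_breaks)
  use <- !is.na(li)
  if (any(use)) {
    key <- (di[use] - 1L) * length(lat_bins) + li[use]
    tab <- table(key)
    m[as.integer(names(tab))] <- as.integer(tab)
  }
  new_lat_depth_grid(m, lat_bins, depth_breaks, "effort")
}

#' Log effort offset
#'
#' `ln(count + 1)` per cell, the additive offset used to absorb uneven
#' collection effort in Poisson richness models.
#'
#' @param effort a `lat_depth_grid` of counts.
#' @return a `lat_depth_grid` of log-offsets.
#' @export
effort_offset <- function(effort) {
  stopifnot(all(effort$values >= 0))
  new_lat_depth_grid(log(effort$values + 1), effort$lat_bins,
                     effort$depth_breaks, "effort_offset")
}

#' Interpolation-uncertainty map
#'
#' Percentage of each cell's interpolated richness that was produced by
#' interpolation rather than direct sampling:
#' `100 * (interp - raw) / interp` where interpolated richness is positive,
#' 0 elsewhere.
#'
#' @param raw,interp `lat_depth_grid`s of richness on identical axes, with
#'   `interp >= raw` cell-wise.
#' @return a `lat_depth_grid` of percentages in `[0, 100]`.
#' @export
interpolation_uncertainty <- function(raw, interp) {
  stopifnot(identical(raw$lat_bins, interp$lat_bins),
            identical(raw$depth_breaks, interp$depth_breaks))
  if (any(raw$values > interp$values)) {
    stop("raw richness exceeds interpolated richness; invariant violated")
  }
  v <- matrix(0, nrow(raw$values), ncol(raw$values))
  pos <- interp$values > 0
  v[pos] <- 100 * (interp$values[pos] - raw$values[pos]) / interp$values[pos]
  new_lat_depth_grid(v, raw$lat_bins, raw$depth_breaks, "percent")
}

#' Latitudinal climate bands
#'
#' Tropical (|lat| < 23.4), temperate (23.4-66.5) and polar (> 66.5) bands,
#' the standard astronomical definitions.
#'
#' @return data.frame `name, abs_lat_min, abs_lat_max`.
#' @export
lat_bands <- function() {
  data.frame(name = c("tropical", "temperate", "polar"),
             abs_lat_min = c(0, 23.4, 66.5),
             abs_lat_max = c(23.4, 66.5, 90),
             stringsAsFactors = FALSE)
}

#' Richness decline between successive depth strata
#'
#' For each latitudinal band, the peak (per-cell maximum) richness within
#' each depth stratum and the percentage decline between successive strata
#' (`100 * (peak_prev - peak_next) / peak_prev`). Bands with no populated
#' cells in a stratum are flagged undefined (`NA`) rather than 0.
#'
#' @param grid a `lat_depth_grid` of richness.
#' @param strata data.frame as from [depth_strata()].
#' @param bands data.frame as from [lat_bands()].
#' @param summary_fun per-band, per-stratum summary (default `max`, peak
#'   richness; `mean` is a config switch).
#' @return data.frame with band, stratum peaks and `decline_pct` between
#'   each stratum and the previous one.
#' @export
stratum_decline <- function(grid, strata = depth_strata(),
                            bands = lat_bands(), summary_fun = max) {
  bin_lower <- grid$depth_breaks[-length(grid$depth_breaks)]
  abs_lat <- abs(grid$lat_bins + 0.5)
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    in_band <- abs_lat >= bands$abs_lat_min[b] &
      abs_lat < bands$abs_lat_max[b]
    peaks <- numeric(nrow(strata))
    for (s in seq_len(nrow(strata))) {
      in_str <- bin_lower >= strata$lower[s] & bin_lower < strata$upper[s]
      vals <- grid$values[in_band, in_str, drop = FALSE]
      peaks[s] <- if (length(vals) == 0) NA_real_ else summary_fun(vals)
    }
    decl <- c(NA_real_, ifelse(is.na(peaks[-nrow(strata)]) |
                                 is.na(peaks[-1]) |
                                 peaks[-nrow(strata)] == 0, NA_real_,
                               100 * (peaks[-nrow(strata)] - peaks[-1]) /
                                 peaks[-nrow(strata)]))
    rows[[b]] <- data.frame(band = bands$name[b], stratum = strata$name,
                            peak = peaks, decline_pct = decl,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a lat-depth grid as a CSV matrix
#'
#' Latitude bins as the first column, depth-bin lower edges as the header.
#'
#' @param grid a `lat_depth_grid`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(lat_bin = grid$lat_bins, grid$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
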