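# Raw and informed-interpolated species occupancy over latitude x depth.
# Informed interpolation bridges latitudinal gaps between records only where
# the sea-floor depth envelope overlaps a species' catalogued depth limits
# and no catalogued disjunction (e.g. an anti-tropical gap) intervenes;
# blocked latitudes split the range and unobserved segments are discarded.

#' Depth strata definitions
#'
#' The three major depth strata: shallow `[0, 200)`, bathyal `[200, 2000)`,
#' lower bathyal and abyssal `[2000, 6000]`.
#'
#' @return data.frame `name, lower, upper` (m).
#' @export
depth_strata <- function() {
  data.frame(name = c("shallow", "bathyal", "abyssal"),
             lower = c(0, 200, 2000), upper = c(200, 2000, 6000),
             stringsAsFactors = FALSE)
}

#' Stratified depth-bin breaks
#'
#' Bin edges at 10 m through the shallow stratum, 50 m through the bathyal
#' and 200 m through the abyssal stratum.
#'
#' @param depth_max deepest edge (default 6000 m).
#' @return ascending numeric vector of bin edges starting at 0.
#' @export
stratified_depth_breaks <- function(depth_max = 6000) {
  unique(c(seq(0, 200, by = 10), seq(250, 2000, by = 50),
           seq(2200, depth_max, by = 200)))
}

#' Uniform depth-bin breaks
#'
#' @param width bin width in metres (default 100).
#' @param depth_max deepest edge (default 6000 m).
#' @return ascending numeric vector of bin edges starting at 0.
#' @export
uniform_depth_breaks <- function(width = 100, depth_max = 6000) {
  seq(0, depth_max, by = width)
}

# indices of half-open bins [l, u) intersecting the open-ended interval
# (dmin, dmax): l < dmax and u > dmin. A degenerate interval falls back to
# the single bin containing dmin.
bins_for_interval <- function(breaks, dmin, dmax) {
  l <- breaks[-length(breaks)]
  u <- breaks[-1]
  idx <- which(l < dmax & u > dmin)
  if (length(idx) == 0) {
    k <- findInterval(dmin, breaks, rightmost.closed = TRUE)
    idx <- k[k >= 1 & k <= length(l)]
  }
  idx
}

new_occupancy_cube <- function(presence, species_ids, lat_bins, depth_breaks,
                               flavour) {
  dimnames(presence) <- list(species_ids, lat_bins,
                             depth_breaks[-length(depth_breaks)])
  structure(list(presence = presence, species_ids = species_ids,
                 lat_bins = lat_bins, depth_breaks = depth_breaks,
                 flavour = flavour),
            class = "occupancy_cube")
}

#' @export
print.occupancy_cube <- function(x, ...) {
  cat(sprintf("occupancy_cube (%s): %d species x %d lat bins x %d depth bins, %d occupied cells\n",
              x$flavour, dim(x$presence)[1], dim(x$presence)[2],
              dim(x$presence)[3], sum(x$presence)))
  invisible(x)
}

# resolved depth interval for one catalogue row under the fallback chain:
# shallow-flagged species get 0-10 m; otherwise catalogued limits; otherwise
# the union of record depths
resolve_depth_interval <- function(cat_row, record_depths = numeric(0)) {
  if (isTRUE(cat_row$shallow_flag)) return(c(0, 10))
  if (!is.na(cat_row$depth_min_m) && !is.na(cat_row$depth_max_m)) {
    return(c(cat_row$depth_min_m, cat_row$depth_max_m))
  }
  d <- record_depths[!is.na(record_depths)]
  if (length(d) == 0) stop("species ", cat_row$species_id,
                           " has no catalogued or recorded depths")
  range(d)
}

#' Summarise observed species ranges from validated records
#'
#' One row per species with at least one record: the set of observed
#' 1-degree latitude bins, the observed longitudinal extent, the observed
#' depth extent, and the resolved catalogue constraints (catalogued
#' latitudinal limits take precedence over observed extremes where narrower;
#' shallow-flagged species resolve to 0-10 m; species without catalogued
#' depth limits inherit the union of their record depths).
#'
#' @param records validated occurrence data.frame.
#' @param catalogue catalogue data.frame.
#' @return data.frame of class `species_ranges` with list column `obs_bins`.
#' @export
species_ranges <- function(records, catalogue) {
  sp <- unique(records$species_id)
  unknown <- setdiff(sp, catalogue$species_id)
  if (length(unknown)) {
    stop("records for species absent from catalogue: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  m <- match(sp, catalogue$species_id)
  rows <- lapply(seq_along(sp), function(k) {
    rec <- records[records$species_id == sp[k], , drop = FALSE]
    ci <- catalogue[m[k], , drop = FALSE]
    dint <- resolve_depth_interval(ci, rec$depth_m)
    list(species_id = sp[k],
         obs_bins = sort(unique(floor(rec$decimalLatitude))),
         lon_min = min(rec$decimalLongitude),
         lon_max = max(rec$decimalLongitude),
         obs_depth_min = suppressWarnings(min(rec$depth_m, na.rm = TRUE)),
         obs_depth_max = suppressWarnings(max(rec$depth_m, na.rm = TRUE)),
         depth_min = dint[1], depth_max = dint[2],
         lat_min = ci$lat_min, lat_max = ci$lat_max,
         exclusion_bands = ci$exclusion_bands)
  })
  out <- data.frame(
    species_id = vapply(rows, `[[`, character(1), "species_id"),
    lon_min = vapply(rows, `[[`, numeric(1), "lon_min"),
    lon_max = vapply(rows, `[[`, numeric(1), "lon_max"),
    depth_min = vapply(rows, `[[`, numeric(1), "depth_min"),
    depth_max = vapply(rows, `[[`, numeric(1), "depth_max"),
    lat_min = vapply(rows, `[[`, numeric(1), "lat_min"),
    lat_max = vapply(rows, `[[`, numeric(1), "lat_max"),
    exclusion_bands = vapply(rows, `[[`, character(1), "exclusion_bands"),
    stringsAsFactors = FALSE)
  out$obs_bins <- lapply(rows, `[[`, "obs_bins")
  class(out) <- c("species_ranges", "data.frame")
  out
}

# effective upper depth limit at one latitude: catalogued maximum capped at
# the envelope maximum where the envelope overlaps the species interval;
# otherwise (contradictory or absent envelope) the catalogued maximum
effective_depth_cap <- function(dmin, dmax, env_max, has_sea) {
  if (isTRUE(has_sea) && !is.na(env_max) && env_max >= dmin) {
    min(dmax, env_max)
  } else {
    dmax
  }
}

#' Raw occupancy cube from validated records
#'
#' A species is present in each 1-degree latitude bin holding at least one
#' of its records and, within such a bin, in every depth bin intersecting
#' its resolved depth interval (species are treated as bathymetrically
#' continuous at observed latitudes, but never extended across latitudes
#' without records). When `envelopes` are supplied the depth interval is
#' capped at the latitude's sea-floor envelope maximum, keeping the raw cube
#' comparable cell-by-cell with the interpolated one.
#'
#' @param records validated occurrence data.frame.
#' @param catalogue catalogue data.frame.
#' @param depth_breaks depth-bin edges (e.g. [stratified_depth_breaks()]).
#' @param lat_bins integer vector of 1-degree bins (southern edges) spanning
#'   the study domain.
#' @param envelopes optional per-latitude envelope data.frame from
#'   [latitude_envelopes()] (or a list of per-species such data.frames,
#'   named by species).
#' @return an `occupancy_cube` with flavour `"raw"`.
#' @export
raw_occupancy <- function(records, catalogue, depth_breaks, lat_bins,
                          envelopes = NULL) {
  ranges <- if (nrow(records)) species_ranges(records, catalogue) else NULL
  n_sp <- if (is.null(ranges)) 0L else nrow(ranges)
  pres <- array(FALSE, c(n_sp, length(lat_bins), length(depth_breaks) - 1L))
  sp_ids <- character(0)
  if (n_sp > 0) {
    sp_ids <- ranges$species_id
    for (k in seq_len(n_sp)) {
      env_k <- species_envelope(envelopes, sp_ids[k])
      for (b in intersect(ranges$obs_bins[[k]], lat_bins)) {
        li <- match(b, lat_bins)
        er <- envelope_row(env_k, b)
        cap <- effective_depth_cap(ranges$depth_min[k], ranges$depth_max[k],
                                   er$max_depth_m, er$has_sea)
        di <- bins_for_interval(depth_breaks, ranges$depth_min[k], cap)
        pres[k, li, di] <- TRUE
      }
    }
  }
  new_occupancy_cube(pres, sp_ids, lat_bins, depth_breaks, "raw")
}

species_envelope <- function(envelopes, species_id) {
  if (is.null(envelopes)) return(NULL)
  if (is.data.frame(envelopes)) return(envelopes)
  envelopes[[species_id]]
}

envelope_row <- function(env, lat_bin) {
  if (is.null(env)) {
    return(list(min_depth_m = NA_real_, max_depth_m = NA_real_,
                has_sea = NA))
  }
  i <- match(lat_bin, env$lat_bin)
  if (is.na(i)) {
    return(list(min_depth_m = NA_real_, max_depth_m = NA_real_,
                has_sea = FALSE))
  }
  list(min_depth_m = env$min_depth_m[i], max_depth_m = env$max_depth_m[i],
       has_sea = env$has_sea[i])
}

#' Informed interpolation of one species' range
#'
#' Candidate latitudes are the 1-degree bins spanning the observed extremes,
#' intersected with the catalogued latitudinal limits. A candidate is
#' occupied iff it holds an observation, or (a) it is not inside a
#' catalogued exclusion band, (b) the latitude's sea-floor depth envelope
#' overlaps the species' depth interval, and (c) it is not separated from an
#' observed latitude by a latitude failing (a) or (b): blocked latitudes act
#' as hard breaks and candidate segments containing no observation are
#' discarded. Within each occupied latitude, the occupied depth bins are the
#' species' depth interval intersected with `[0, envelope max]`.
#'
#' @param range one row of [species_ranges()].
#' @param envelopes per-latitude envelope data.frame (see
#'   [latitude_envelopes()]), typically restricted to the species' observed
#'   longitudinal extent padded by 1 degree.
#' @param depth_breaks depth-bin edges.
#' @param lat_bins integer vector of 1-degree bins defining the cube axis.
#' @return logical matrix `[length(lat_bins), n depth bins]` of occupied
#'   cells.
#' @export
informed_interpolate <- function(range, envelopes, depth_breaks, lat_bins) {
  obs <- range$obs_bins[[1]]
  if (length(obs) == 0) stop("species has no observed latitude bins")
  bands <- parse_intervals(range$exclusion_bands)
  cand <- seq(max(min(obs), floor(range$lat_min)),
              min(max(obs), ceiling(range$lat_max) - 1))
  cand <- intersect(cand, lat_bins)
  out <- matrix(FALSE, length(lat_bins), length(depth_breaks) - 1L)
  if (length(cand) == 0) cand <- intersect(obs, lat_bins)
  if (length(cand) == 0) return(out)

  centers <- cand + 0.5
  in_band <- in_any_interval_open(centers, bands)
  er <- lapply(cand, function(b) envelope_row(envelopes, b))
  env_ok <- vapply(er, function(e) {
    isTRUE(e$has_sea) && !is.na(e$min_depth_m) &&
      e$min_depth_m <= range$depth_max && e$max_depth_m >= range$depth_min
  }, logical(1))
  observed <- cand %in% obs
  blocked <- (in_band | !env_ok) & !observed

  # segment candidates at blocked latitudes; keep segments holding records
  seg <- cumsum(blocked)
  keep <- rep(FALSE, length(cand))
  for (s in unique(seg[!blocked])) {
    members <- which(seg == s & !blocked)
    if (any(observed[members])) keep[members] <- TRUE
  }
  keep <- keep | observed

  for (i in which(keep)) {
    li <- match(cand[i], lat_bins)
    cap <- effective_depth_cap(range$depth_min, range$depth_max,
                               er[[i]]$max_depth_m, er[[i]]$has_sea)
    di <- bins_for_interval(depth_breaks, range$depth_min, cap)
    out[li, di] <- TRUE
  }
  out
}

# strictly-inside test (bands are open gaps between closed intervals)
in_any_interval_open <- function(x, m) {
  if (is.null(m) || nrow(m) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(m))) hit <- hit | (x > m[i, 1] & x < m[i, 2])
  hit
}

#' Build the interpolated occupancy cube for all species
#'
#' Computes per-species envelopes (by default over each species' observed
#' longitudinal extent padded 1 degree) and stacks
#' [informed_interpolate()] over all species.
#'
#' @param ranges a [species_ranges()] data.frame.
#' @param bathy a [bathy_grid()], or a precomputed global envelope
#'   data.frame from [latitude_envelopes()].
#' @param depth_breaks depth-bin edges.
#' @param lat_bins integer vector of 1-degree bins.
#' @param lon_gating `"species"` (envelope over each species' observed
#'   longitudes, padded) or `"global"` (all longitudes).
#' @param pad degrees of longitudinal padding under species gating.
#' @return an `occupancy_cube` with flavour `"interpolated"`.
#' @export
build_interpolated_cube <- function(ranges, bathy, depth_breaks, lat_bins,
                                    lon_gating = c("species", "global"),
                                    pad = 1) {
  lon_gating <- match.arg(lon_gating)
  n_sp <- if (is.null(ranges)) 0L else nrow(ranges)
  pres <- array(FALSE, c(n_sp, length(lat_bins), length(depth_breaks) - 1L))
  sp_ids <- if (n_sp) ranges$species_id else character(0)
  if (n_sp > 0) {
    if (inherits(bathy, "bathy_grid")) {
      ce <- cell_envelopes(bathy)
      env_for <- function(k) {
        rng <- if (lon_gating == "species")
          c(ranges$lon_min[k] - pad, ranges$lon_max[k] + pad) else NULL
        env_from_cells_all(ce, rng)
      }
    } else {
      env_for <- function(k) bathy
    }
    for (k in seq_len(n_sp)) {
      pres[k, , ] <- informed_interpolate(ranges[k, , drop = FALSE],
                                          env_for(k), depth_breaks, lat_bins)
    }
  }
  new_occupancy_cube(pres, sp_ids, lat_bins, depth_breaks, "interpolated")
}

# vectorised latitude_envelopes from precomputed cell envelopes
env_from_cells_all <- function(ce, lon_range = NULL) {
  keep <- if (is.null(lon_range)) rep(TRUE, length(ce$lon_bins)) else
    ce$lon_bins + 1 > lon_range[1] & ce$lon_bins < lon_range[2]
  mn <- ce$min[, keep, drop = FALSE]
  mx <- ce$max[, keep, drop = FALSE]
  any_sea <- rowSums(!is.na(mn)) > 0
  data.frame(
    lat_bin = ce$lat_bins,
    min_depth_m = ifelse(any_sea, suppressWarnings(
      apply(mn, 1, min, na.rm = TRUE)), NA_real_),
    max_depth_m = ifelse(any_sea, suppressWarnings(
      apply(mx, 1, max, na.rm = TRUE)), NA_real_),
    has_sea = any_sea)
}

#' Recompute occupancy within one oceanic region
#'
#' Restricts records, catalogued latitudinal limits and sea-floor envelopes
#' to a rectangular region (a realm sector), then rebuilds the requested
#' cube so that cross-regional species reflect only their range limits
#' within the region.
#'
#' @param records validated occurrence data.frame.
#' @param catalogue catalogue data.frame.
#' @param bathy a [bathy_grid()].
#' @param region list with `name`, `lon_min`, `lon_max` and optional
#'   `lat_min`, `lat_max`.
#' @param depth_breaks,lat_bins cube axes.
#' @param flavour `"interpolated"` or `"raw"`.
#' @return an `occupancy_cube` (empty if no records fall in the region).
#' @export
clip_to_region <- function(records, catalogue, bathy, region, depth_breaks,
                           lat_bins, flavour = c("interpolated", "raw")) {
  flavour <- match.arg(flavour)
  r_lat <- c(region$lat_min %||% -90, region$lat_max %||% 90)
  keep <- records$decimalLongitude >= region$lon_min &
    records$decimalLongitude < region$lon_max &
    records$decimalLatitude >= r_lat[1] & records$decimalLatitude <= r_lat[2]
  rec <- records[keep, , drop = FALSE]
  cat2 <- catalogue
  cat2$lat_min <- pmax(cat2$lat_min, r_lat[1])
  cat2$lat_max <- pmin(cat2$lat_max, r_lat[2])
  if (nrow(rec) == 0) {
    return(new_occupancy_cube(
      array(FALSE, c(0, length(lat_bins), length(depth_breaks) - 1L)),
      character(0), lat_bins, depth_breaks, flavour))
  }
  ranges <- species_ranges(rec, cat2)
  ce <- cell_envelopes(bathy)
  env_region <- function(k) {
    lo <- max(region$lon_min, ranges$lon_min[k] - 1)
    hi <- min(region$lon_max, ranges$lon_max[k] + 1)
    env_from_cells_all(ce, c(lo, hi))
  }
  if (flavour == "raw") {
    envs <- lapply(seq_len(nrow(ranges)), env_region)
    names(envs) <- ranges$species_id
    raw_occupancy(rec, cat2, depth_breaks, lat_bins, envelopes = envs)
  } else {
    pres <- array(FALSE, c(nrow(ranges), length(lat_bins),
                           length(depth_breaks) - 1L))
    for (k in seq_len(nrow(ranges))) {
      pres[k, , ] <- informed_interpolate(ranges[k, , drop = FALSE],
                                          env_region(k), depth_breaks,
                                          lat_bins)
    }
    new_occupancy_cube(pres, ranges$species_id, lat_bins, depth_breaks,
                       "interpolated")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build matched raw and interpolated occupancy cubes
#'
#' Computes species ranges and per-species envelopes once and returns both
#' cube flavours on identical axes, so that raw and interpolated richness
#' are comparable cell by cell.
#'
#' @param records validated occurrence data.frame.
#' @param catalogue catalogue data.frame.
#' @param bathy a [bathy_grid()].
#' @param depth_breaks depth-bin edges (default [stratified_depth_breaks()]).
#' @param lat_bins integer latitude bins (default derived from the grid).
#' @param lon_gating,pad see [build_interpolated_cube()].
#' @return list with `raw`, `interpolated` (occupancy cubes) and `ranges`.
#' @export
build_cubes <- function(records, catalogue, bathy,
                        depth_breaks = stratified_depth_breaks(),
                        lat_bins = NULL,
                        lon_gating = c("species", "global"), pad = 1) {
  lon_gating <- match.arg(lon_gating)
  if (is.null(lat_bins)) {
    lat_bins <- seq(floor(min(bathy$lat - bathy$res / 2)),
                    ceiling(max(bathy$lat + bathy$res / 2)) - 1)
  }
  ranges <- species_ranges(records, catalogue)
  ce <- cell_envelopes(bathy)
  envs <- lapply(seq_len(nrow(ranges)), function(k) {
    rng <- if (lon_gating == "species")
      c(ranges$lon_min[k] - pad, ranges$lon_max[k] + pad) else NULL
    env_from_cells_all(ce, rng)
  })
  names(envs) <- ranges$species_id
  raw <- raw_occupancy(records, catalogue, depth_breaks, lat_bins,
                       envelopes = envs)
  pres <- array(FALSE, c(nrow(ranges), length(lat_bins),
                         length(depth_breaks) - 1L))
  for (k in seq_len(nrow(ranges))) {
    pres[k, , ] <- informed_interpolate(ranges[k, , drop = FALSE],
                                        envs[[k]], depth_breaks, lat_bins)
  }
  interp <- new_occupancy_cube(pres, ranges$species_id, lat_bins,
                               depth_breaks, "interpolated")
  list(raw = raw, interpolated = interp, ranges = ranges)
}
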