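# Shared fixtures: lean synthetic worlds and independent brute-force oracles.

# compact world config used where the check does not pin the problem size
lean_config <- function(seed, ...) {
  args <- utils::modifyList(list(seed = seed, n_species = 160,
                                 lon_count = 18, n_records = 6000),
                            list(...))
  do.call(world_config, args)
}

# full cleaning pipeline: sources -> duplicates -> depth imputation ->
# catalogue validation -> hadal removal
clean_records <- function(records, catalogue, bathy) {
  rec <- filter_sources(records)
  rec <- collapse_duplicates(rec)
  rec <- impute_missing_depths(rec, bathy)
  rec <- validate_against_catalogue(rec, catalogue, bathy)$records
  remove_hadal(rec)
}

# world -> per-latitude stratum modelling table (100-m cells)
world_stratum_table <- function(w, stratum) {
  rec <- clean_records(w$records, w$catalogue, w$bathy)
  cubes <- build_cubes(rec, w$catalogue, w$bathy,
                       depth_breaks = uniform_depth_breaks())
  ri <- richness(cubes$interpolated)
  ef <- effort_grid(rec, lat_bins = ri$lat_bins)
  tab <- cell_table(grid_environment(w$env, w$bathy), ri, ef)
  stratum_table(tab, stratum)
}

env_predictors <- c("temperature", "poc_flux", "salinity", "oxygen",
                    "nitrate")

# ---- independent oracle: per-cell literal informed-interpolation rules ----
# For every candidate latitude bin the oracle checks, cell by cell:
#   occupied iff the bin holds an observation, or it passes (a) not inside an
#   exclusion band, (b) envelope overlaps the depth interval, and (c) some
#   observed bin is reachable without crossing a bin failing (a) or (b).
brute_interpolate <- function(range, envelopes, depth_breaks, lat_bins) {
  obs <- range$obs_bins[[1]]
  bands <- bathyrich:::parse_intervals(range$exclusion_bands)
  out <- matrix(FALSE, length(lat_bins), length(depth_breaks) - 1L)
  lo <- max(min(obs), floor(range$lat_min))
  hi <- min(max(obs), ceiling(range$lat_max) - 1)
  if (lo > hi) return(out)
  cand <- lo:hi
  passes <- function(b) {
    ctr <- b + 0.5
    in_band <- nrow(bands) > 0 &&
      any(ctr > bands[, 1] & ctr < bands[, 2])
    i <- match(b, envelopes$lat_bin)
    env_ok <- !is.na(i) && isTRUE(envelopes$has_sea[i]) &&
      envelopes$min_depth_m[i] <= range$depth_max &&
      envelopes$max_depth_m[i] >= range$depth_min
    !in_band && env_ok
  }
  for (b in intersect(cand, lat_bins)) {
    occupied <- b %in% obs
    if (!occupied && passes(b)) {
      # rule (c): walk towards each observation; blocked bins break the path
      for (o in obs) {
        path <- if (o > b) b:o else o:b
        if (all(vapply(setdiff(path, obs), passes, logical(1)))) {
          occupied <- TRUE
          break
        }
      }
    }
    if (occupied) {
      i <- match(b, envelopes$lat_bin)
      emax <- if (is.na(i)) NA_real_ else envelopes$max_depth_m[i]
      hs <- if (is.na(i)) FALSE else envelopes$has_sea[i]
      cap <- if (isTRUE(hs) && !is.na(emax) && emax >= range$depth_min) {
        min(range$depth_max, emax)
      } else {
        range$depth_max
      }
      l <- depth_breaks[-length(depth_breaks)]
      u <- depth_breaks[-1]
      di <- which(l < cap & u > range$depth_min)
      if (length(di) == 0) {
        k <- findInterval(range$depth_min, depth_breaks,
                          rightmost.closed = TRUE)
        di <- k[k >= 1 & k <= length(l)]
      }
      out[match(b, lat_bins), di] <- TRUE
    }
  }
  out
}

# random abstract interpolation instance: envelopes, catalogue limits,
# observations and exclusion bands with no geometric consistency assumed
random_range_instance <- function(n_lat = 30, n_depth = 20) {
  lat_bins <- 0:(n_lat - 1)
  depth_breaks <- seq(0, 100 * n_depth, by = 100)
  env <- data.frame(
    lat_bin = lat_bins,
    min_depth_m = runif(n_lat, 0, 800),
    has_sea = runif(n_lat) > 0.15)
  env$max_depth_m <- env$min_depth_m + runif(n_lat, 0, 1600)
  env$min_depth_m[!env$has_sea] <- NA
  env$max_depth_m[!env$has_sea] <- NA
  dmin <- runif(1, 0, 1200)
  dmax <- dmin + runif(1, 50, 900)
  lat_min <- sample(0:(n_lat - 1), 1)
  lat_max <- lat_min + sample(seq_len(n_lat - lat_min), 1)
  nbands <- sample(0:2, 1)
  bands <- if (nbands > 0) {
    lo <- sort(sample(seq(lat_min, lat_max), nbands))
    bathyrich:::format_intervals(cbind(lo, pmin(lo + sample(1:5, nbands,
                                                            replace = TRUE),
                                                lat_max)))
  } else ""
  # observations lie inside the catalogued limits (validated upstream)
  obs_pool <- seq(lat_min, min(lat_max - 1, n_lat - 1))
  n_obs <- min(length(obs_pool), sample(1:6, 1))
  obs <- sort(obs_pool[sample.int(length(obs_pool), n_obs)])
  rng <- data.frame(species_id = "sp1", lon_min = 0, lon_max = 1,
                    depth_min = dmin, depth_max = dmax,
                    lat_min = lat_min, lat_max = lat_max,
                    exclusion_bands = bands, stringsAsFactors = FALSE)
  rng$obs_bins <- list(obs)
  list(range = rng, envelopes = env, depth_breaks = depth_breaks,
       lat_bins = lat_bins)
}

# Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- same_a == same_b
  (sum(agree) - n) / (n^2 - n)
}
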