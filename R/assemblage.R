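# Synthetic species assemblages: archetypal latitude x depth range rectangles
# clipped to the available sea floor, realm membership, effort-biased
# occurrence sampling, and lossless ground-truth export.

realm_names <- c("Atlantic", "NEPacific", "IWP")

# longitudinal sector [min, max) of a realm within the world's lon domain
realm_lon_range <- function(realm, config) {
  w <- config$lon_count / 3
  if (realm == "cross-regional") return(c(0, config$lon_count))
  k <- match(realm, realm_names)
  c((k - 1) * w, k * w)
}

# draw raw (unclipped) archetype parameters; returns list(intervals, dmin, dmax)
draw_archetype <- function(archetype, config) {
  switch(archetype,
    shallow_tropical = {
      ctr <- stats::rnorm(1, 8, 8); s <- stats::runif(1, 12, 30)
      list(intervals = cbind(ctr - s, ctr + s),
           dmin = 0, dmax = stats::runif(1, 60, 200), center = ctr)
    },
    shallow_antitropical = {
      s <- stats::runif(1, 12, 30)
      list(intervals = rbind(c(-23 - s, -23), c(23, 23 + s)),
           dmin = 0, dmax = stats::runif(1, 60, 200), center = NA)
    },
    bathyal_tropical = {
      ctr <- stats::rnorm(1, 5, 10); s <- stats::runif(1, 25, 50)
      list(intervals = cbind(ctr - s, ctr + s),
           dmin = stats::runif(1, 200, 350),
           dmax = stats::runif(1, 1200, 2000), center = ctr)
    },
    bathyal_bimodal = {
      s <- stats::runif(1, 15, 35)
      list(intervals = rbind(c(-20 - s, -20), c(20, 20 + s)),
           dmin = stats::runif(1, 200, 350),
           dmax = stats::runif(1, 1200, 2000), center = NA)
    },
    abyssal_cosmopolitan = {
      ctr <- stats::rnorm(1, 0, 5); s <- stats::runif(1, 65, 85)
      list(intervals = cbind(ctr - s, ctr + s),
           dmin = stats::runif(1, 2000, 2600),
           dmax = stats::runif(1, 4200, config$depth_max), center = ctr)
    },
    polar_endemic = {
      ctr <- sample(c(-1, 1), 1) * stats::runif(1, 68, 76)
      s <- stats::runif(1, 5, 10)
      list(intervals = cbind(ctr - s, ctr + s),
           dmin = 0, dmax = stats::runif(1, 300, 1000), center = ctr)
    },
    stop("unknown archetype: ", archetype))
}

# latitudinal placement weight for driver-biased worlds
placement_weight <- function(bias_var, lat, ref_depth, threshold_temp) {
  v <- switch(bias_var,
    temperature = env_temperature(lat, ref_depth, threshold_temp) + 2,
    poc = poc_export(env_npp(lat), ref_depth),
    stop("unknown placement bias variable: ", bias_var))
  pmax(v, 1e-6)
}

#' Generate a synthetic species assemblage with known ranges
#'
#' Each species draws an archetype from `config$archetype_mix`, raw
#' latitude/depth range rectangles from the archetype, and a realm; its true
#' latitudinal intervals are then clipped to the 1-degree bins where the
#' sea-floor depth envelope of its realm's longitudes overlaps its depth
#' interval. Anti-tropical and bimodal archetypes carry a tropical gap, so
#' end up with two (or more) disjoint intervals. A species whose depth
#' interval overlaps no sea floor anywhere is redrawn; after 100 retries it
#' is assigned the full habitable span for its depth interval with a warning.
#'
#' @param config a [world_config()].
#' @param bathy bathymetry from the same config.
#' @param env optional [generate_environment()] output; when supplied,
#'   species living wholly below 2,000 m are additionally restricted to
#'   latitudes where deep-water temperature is at or above the environment's
#'   thermal threshold, so deep richness is genuinely threshold-limited.
#' @param thermal_clip apply the deep-water thermal restriction when `env`
#'   is supplied (default `TRUE`); set `FALSE` to use `env` for placement
#'   bias only.
#' @param placement_bias optional named list, e.g.
#'   `list(shallow = "temperature", deep = "poc", power = 4)`: latitudinal
#'   centres of centre-based archetypes in the named stratum are sampled
#'   proportionally to that environmental field raised to `power`, producing
#'   worlds whose richness gradient is driven by a known variable. Requires
#'   `env`.
#' @return data.frame of class `assemblage`: `species_id`, `archetype`,
#'   `region_label`, `lon_min`, `lon_max`, `depth_min`, `depth_max` and a
#'   list column `lat_intervals` (2-column matrices of closed degree
#'   intervals, pairwise disjoint and sorted).
#' @export
generate_assemblage <- function(config, bathy, env = NULL,
                                placement_bias = NULL,
                                thermal_clip = TRUE) {
  if (!is.null(placement_bias) && is.null(env)) {
    stop("placement_bias requires env")
  }
  ce <- cell_envelopes(bathy)
  lat_bins <- ce$lat_bins
  mix <- config$archetype_mix
  n <- config$n_species
  empty <- data.frame(species_id = character(0), archetype = character(0),
                      region_label = character(0), lon_min = numeric(0),
                      lon_max = numeric(0), depth_min = numeric(0),
                      depth_max = numeric(0))
  empty$lat_intervals <- list()
  class(empty) <- c("assemblage", "data.frame")
  if (n == 0) return(empty)

  # per-realm node depths grouped by 1-degree bin (precomputed once):
  # a bin is habitable for a species iff at least one sea-floor node in the
  # realm's sector lies inside the species' depth window, so every bin of a
  # true range holds floor the species can actually occur (and be found) on
  realms <- c(realm_names, "cross-regional")
  node_bin <- floor(matrix(bathy$lat, nrow(bathy$depth), 1))[, 1]
  realm_env <- lapply(realms, function(r) {
    rng <- realm_lon_range(r, config)
    cols <- bathy$lon >= rng[1] & bathy$lon < rng[2]
    list(depth = bathy$depth[, cols, drop = FALSE], bin = node_bin)
  })
  names(realm_env) <- realms
  habitable_bins <- function(renv, dmin, dmax) {
    inwin <- rowSums(renv$depth >= dmin & renv$depth <= dmax) > 0
    hits <- rowsum((inwin) + 0, renv$bin)
    as.vector(hits[match(lat_bins, as.numeric(rownames(hits))), 1] > 0)
  }
  pb_power <- if (is.null(placement_bias$power)) 4 else placement_bias$power

  with_seed(config$seed + 303L, {
    archetypes <- sample(names(mix), n, replace = TRUE, prob = mix)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      a <- archetypes[i]
      realm <- if (a == "abyssal_cosmopolitan") "cross-regional" else
        sample(realm_names, 1)
      renv <- realm_env[[realm]]
      ok <- FALSE
      for (try in seq_len(100)) {
        dr <- draw_archetype(a, config)
        # optional driver-biased re-centring of centre-based archetypes
        stratum <- if (dr$dmin >= 2000) "deep" else
          if (dr$dmax <= 200) "shallow" else "bathyal"
        bvar <- placement_bias[[stratum]]
        if (!is.null(bvar) && !is.na(dr$center)) {
          ref_depth <- if (stratum == "shallow") 50 else
            (dr$dmin + dr$dmax) / 2
          w <- placement_weight(bvar, lat_bins + 0.5, ref_depth,
                                env$threshold_temp)
          ctr <- sample(lat_bins, 1, prob = w^pb_power) + 0.5
          # driver-structured worlds need range-size variation to express
          # the driver, so biased draws use tighter ranges
          half <- (dr$intervals[1, 2] - dr$intervals[1, 1]) / 5
          dr$intervals <- cbind(ctr - half, ctr + half)
        }
        habitable <- habitable_bins(renv, dr$dmin, dr$dmax)
        if (!is.null(env) && thermal_clip && dr$dmin >= 2000) {
          tmid <- env_temperature(lat_bins + 0.5, (dr$dmin + dr$dmax) / 2,
                                  env$threshold_temp)
          habitable <- habitable & tmid >= env$threshold_temp
        }
        inraw <- in_any_interval(lat_bins + 0.5, dr$intervals)
        keep <- habitable & inraw
        if (any(keep)) { ok <- TRUE; break }
      }
      if (!ok) {
        warning("species ", i, " (", a,
                "): no habitable latitude after 100 draws; ",
                "assigned full habitable span")
        keep <- habitable
        if (!any(keep)) stop("depth interval overlaps no sea floor anywhere")
      }
      runs <- runs_to_intervals(lat_bins, keep)
      intervals <- cbind(lower = runs[, 1], upper = runs[, 2] + 1)
      rng <- realm_lon_range(realm, config)
      rows[[i]] <- list(species_id = sprintf("sp%04d", i), archetype = a,
                        region_label = realm, lon_min = rng[1],
                        lon_max = rng[2], depth_min = dr$dmin,
                        depth_max = dr$dmax, lat_intervals = intervals)
    }
    out <- data.frame(
      species_id = vapply(rows, `[[`, character(1), "species_id"),
      archetype = vapply(rows, `[[`, character(1), "archetype"),
      region_label = vapply(rows, `[[`, character(1), "region_label"),
      lon_min = vapply(rows, `[[`, numeric(1), "lon_min"),
      lon_max = vapply(rows, `[[`, numeric(1), "lon_max"),
      depth_min = vapply(rows, `[[`, numeric(1), "depth_min"),
      depth_max = vapply(rows, `[[`, numeric(1), "depth_max"),
      stringsAsFactors = FALSE)
    out$lat_intervals <- lapply(rows, `[[`, "lat_intervals")
    class(out) <- c("assemblage", "data.frame")
    out
  })
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("assemblage of %d species\n", nrow(x)))
  if (nrow(x) > 0) print(table(x$archetype))
  invisible(x)
}

# candidate sea-floor nodes and effort weights per species
species_candidates <- function(truth, bathy, config) {
  latm <- matrix(bathy$lat, nrow(bathy$depth), ncol(bathy$depth))
  lonm <- matrix(bathy$lon, nrow(bathy$depth), ncol(bathy$depth),
                 byrow = TRUE)
  depth <- bathy$depth
  # north-temperate shallow effort mode, log-linear in the bias strength
  wfield <- exp(config$effort_bias *
                  (exp(-((latm - 45) / 25)^2) + exp(-pmax(depth, 0) / 800)))
  lapply(seq_len(nrow(truth)), function(i) {
    sel <- depth > 0 &
      depth >= truth$depth_min[i] & depth <= truth$depth_max[i] &
      lonm >= truth$lon_min[i] & lonm < truth$lon_max[i] &
      in_any_interval(latm, truth$lat_intervals[[i]])
    idx <- which(sel)
    list(idx = idx, w = wfield[idx])
  })
}

#' Expected sampling-effort field
#'
#' The expected number of occurrence records per 1-degree latitude x 100-m
#' depth cell implied by the effort model, summed over species. Integrates to
#' `config$n_records` exactly.
#'
#' @param truth an [generate_assemblage()] result.
#' @param bathy,config the matching bathymetry and config.
#' @return a `lat_depth_grid` of expected counts.
#' @export
effort_field <- function(truth, bathy, config) {
  cand <- species_candidates(truth, bathy, config)
  idx <- unlist(lapply(cand, `[[`, "idx"))
  w <- unlist(lapply(cand, `[[`, "w"))
  ex <- config$n_records * w / sum(w)
  nlat <- nrow(bathy$depth)
  ri <- (idx - 1L) %% nlat + 1L
  lat_bin <- floor(bathy$lat[ri])
  dep_bin <- floor(bathy$depth[idx] / 100) * 100
  breaks <- seq(0, ceiling(config$depth_max / 100) * 100, by = 100)
  bins <- floor(config$lat_min):(ceiling(config$lat_max) - 1)
  m <- matrix(0, length(bins), length(breaks) - 1)
  li <- match(lat_bin, bins)
  di <- match(dep_bin, breaks[-length(breaks)])
  key <- (di - 1L) * length(bins) + li
  agg <- rowsum(ex, key)
  m[as.integer(rownames(agg))] <- agg[, 1]
  new_lat_depth_grid(m, bins, breaks, "effort")
}

#' Sample effort-biased occurrence records from a true assemblage
#'
#' Records are drawn only from sea-floor nodes inside each species' true
#' latitudinal interval(s), longitudinal sector and depth interval. Sampling
#' intensity is proportional to an effort field with a northern-temperate
#' shallow mode whose strength is `config$effort_bias` (0 = uniform).
#' Coordinates are jittered within the node cell; recorded depth is the
#' sea-floor depth at the node. `config$missing_depth_fraction` of records
#' have depth withheld uniformly at random.
#'
#' @param truth an [generate_assemblage()] result (non-empty).
#' @param bathy,config the matching bathymetry and config.
#' @param source_probs named probabilities for the source tag.
#' @return data.frame of occurrence records: `species_id`,
#'   `decimalLatitude`, `decimalLongitude`, `depth_m` (`NA` when withheld)
#'   and `source`.
#' @export
sample_occurrences <- function(truth, bathy, config,
                               source_probs = c(obis = 0.55, gbif = 0.37,
                                                literature = 0.08)) {
  stopifnot(nrow(truth) > 0)
  cand <- species_candidates(truth, bathy, config)
  idx <- unlist(lapply(cand, `[[`, "idx"))
  w <- unlist(lapply(cand, `[[`, "w"))
  sp <- rep(seq_len(nrow(truth)), vapply(cand, function(x) length(x$idx),
                                         integer(1)))
  with_seed(config$seed + 404L, {
    draw <- sample.int(length(w), config$n_records, replace = TRUE,
                       prob = w)
    nlat <- nrow(bathy$depth)
    ri <- (idx[draw] - 1L) %% nlat + 1L
    ci <- (idx[draw] - 1L) %/% nlat + 1L
    jit <- bathy$res / 2 * 0.98
    lat <- bathy$lat[ri] + stats::runif(length(draw), -jit, jit)
    lon <- bathy$lon[ci] + stats::runif(length(draw), -jit, jit)
    depth <- bathy$depth[idx[draw]]
    miss <- stats::runif(length(draw)) < config$missing_depth_fraction
    depth[miss] <- NA_real_
    data.frame(
      species_id = truth$species_id[sp[draw]],
      decimalLatitude = lat,
      decimalLongitude = lon,
      depth_m = depth,
      source = sample(names(source_probs), length(draw), replace = TRUE,
                      prob = source_probs),
      stringsAsFactors = FALSE)
  })
}

#' Plant rule-violating contaminant records
#'
#' Appends records that violate the catalogue in a known way (latitude
#' outside the catalogued range or inside an exclusion band, depth outside
#' the catalogued limits, or coordinates on land), so that cleaning-stage
#' precision and recall can be asserted exactly.
#'
#' @param records valid occurrence records.
#' @param catalogue the species catalogue (see [catalogue_from_truth()]).
#' @param bathy the bathymetry grid.
#' @param n number of contaminants to plant.
#' @param seed RNG seed.
#' @return list with `records` (original plus contaminants, shuffled) and
#'   `planted` (the contaminant rows with a `violation` column).
#' @export
plant_contaminants <- function(records, catalogue, bathy, n, seed = 1L) {
  land <- which(bathy$depth <= 0)
  nlat <- nrow(bathy$depth)
  with_seed(seed, {
    rows <- vector("list", n)
    types <- rep(c("lat", "depth", "land"), length.out = n)
    for (k in seq_len(n)) {
      ci <- catalogue[sample.int(nrow(catalogue), 1), ]
      mid_lat <- (ci$lat_min + ci$lat_max) / 2
      mid_lon <- mean(bathy$lon)
      row <- switch(types[k],
        lat = {
          lo <- min(bathy$lat); hi <- max(bathy$lat)
          bad <- if (ci$lat_max + 2 <= hi) ci$lat_max + 2 else
            if (ci$lat_min - 2 >= lo) ci$lat_min - 2 else NA
          if (is.na(bad)) next
          data.frame(species_id = ci$species_id, decimalLatitude = bad,
                     decimalLongitude = mid_lon,
                     depth_m = (ci$depth_min_m + ci$depth_max_m) / 2,
                     source = "obis")
        },
        depth = data.frame(species_id = ci$species_id,
                           decimalLatitude = mid_lat,
                           decimalLongitude = mid_lon,
                           depth_m = ci$depth_max_m + 500,
                           source = "obis"),
        land = {
          if (length(land) == 0) next
          li <- land[sample.int(length(land), 1)]
          data.frame(species_id = ci$species_id,
                     decimalLatitude = bathy$lat[(li - 1L) %% nlat + 1L],
                     decimalLongitude = bathy$lon[(li - 1L) %/% nlat + 1L],
                     depth_m = 5, source = "obis")
        })
      row$violation <- types[k]
      rows[[k]] <- row
    }
    planted <- do.call(rbind, rows)
    extra <- setdiff(names(records), names(planted))
    for (col in extra) {
      planted[[col]] <- if (is.logical(records[[col]])) FALSE else NA
    }
    combined <- rbind(records, planted[, names(records)])
    combined <- combined[sample.int(nrow(combined)), ]
    rownames(combined) <- NULL
    list(records = combined, planted = planted)
  })
}

#' Build a descriptive range catalogue from generator truth
#'
#' The synthetic analogue of a literature-derived range catalogue: per
#' species, depth limits, latitudinal limits, realm membership, and
#' exclusion bands (the gaps between a species' disjoint true intervals,
#' i.e. its regions of known absence). Genera and families are synthetic
#' groupings (families follow archetypes; genera bundle a few species each)
#' so taxon-level coverage reporting is exercised.
#'
#' @param truth an [generate_assemblage()] result.
#' @return data.frame catalogue with columns `species_id, genus, family,
#'   depth_min_m, depth_max_m, lat_min, lat_max, regions, exclusion_bands,
#'   shallow_flag`.
#' @export
catalogue_from_truth <- function(truth) {
  n <- nrow(truth)
  fam <- paste0("fam_", truth$archetype)
  within <- stats::ave(seq_len(n), truth$archetype, FUN = seq_along)
  genus <- paste0("gen_", truth$archetype, "_", ceiling(within / 4))
  lat_min <- vapply(truth$lat_intervals, function(m)
    if (nrow(m)) min(m[, 1]) else NA_real_, numeric(1))
  lat_max <- vapply(truth$lat_intervals, function(m)
    if (nrow(m)) max(m[, 2]) else NA_real_, numeric(1))
  bands <- vapply(truth$lat_intervals, function(m) {
    if (nrow(m) < 2) return("")
    g <- cbind(m[-nrow(m), 2], m[-1, 1])
    format_intervals(g)
  }, character(1))
  data.frame(species_id = truth$species_id, genus = genus, family = fam,
             depth_min_m = truth$depth_min, depth_max_m = truth$depth_max,
             lat_min = lat_min, lat_max = lat_max,
             regions = truth$region_label, exclusion_bands = bands,
             shallow_flag = truth$depth_max <= 10,
             stringsAsFactors = FALSE)
}

#' Export ground truth to machine-readable files
#'
#' Writes `truth.csv` (one species per row, intervals encoded `lo:hi;lo:hi`)
#' and `config.json` to `dir`; [read_truth()] restores equal structures.
#'
#' @param truth an [generate_assemblage()] result.
#' @param config the [world_config()] that produced it.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_truth <- function(truth, config, dir) {
  if (!dir.exists(dir)) {
    okdir <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!okdir) stop("cannot create output directory: ", dir)
  }
  flat <- truth
  flat$lat_intervals <- vapply(truth$lat_intervals, format_intervals,
                               character(1))
  class(flat) <- "data.frame"
  csv <- file.path(dir, "truth.csv")
  js <- file.path(dir, "config.json")
  ok <- tryCatch({
    utils::write.csv(flat, csv, row.names = FALSE)
    cfg <- unclass(config)
    cfg$archetype_mix <- as.list(cfg$archetype_mix)
    jsonlite::write_json(cfg, js, auto_unbox = TRUE, digits = NA,
                         null = "null")
    TRUE
  }, error = function(e) stop("cannot write ground truth: ",
                              conditionMessage(e)))
  invisible(c(truth = csv, config = js))
}

#' Read ground truth written by [export_truth()]
#'
#' @param dir directory containing `truth.csv` and `config.json`.
#' @return list with `truth` (assemblage data.frame) and `config`
#'   ([world_config()]).
#' @export
read_truth <- function(dir) {
  flat <- utils::read.csv(file.path(dir, "truth.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(lat_intervals = "character"))
  flat$lat_intervals <- lapply(flat$lat_intervals, parse_intervals)
  class(flat) <- c("assemblage", "data.frame")
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$archetype_mix <- unlist(cfg$archetype_mix)
  config <- do.call(world_config, cfg[!vapply(cfg, is.null, logical(1))])
  list(truth = flat, config = config)
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper running bathymetry, environment, assemblage and
#' occurrence sampling under one config.
#'
#' @param config a [world_config()].
#' @param threshold_temp deep-water thermal threshold (deg C).
#' @param thermal_clip if `TRUE`, pass the environment to
#'   [generate_assemblage()] so deep species respect the thermal threshold.
#' @param placement_bias forwarded to [generate_assemblage()].
#' @return list with `config, bathy, env, truth, catalogue, records`.
#' @export
simulate_world <- function(config = world_config(), threshold_temp = 1.5,
                           thermal_clip = FALSE, placement_bias = NULL) {
  bathy <- generate_bathymetry(config)
  env <- generate_environment(config, bathy, threshold_temp)
  truth <- generate_assemblage(
    config, bathy,
    env = if (thermal_clip || !is.null(placement_bias)) env else NULL,
    placement_bias = placement_bias, thermal_clip = thermal_clip)
  catalogue <- catalogue_from_truth(truth)
  records <- sample_occurrences(truth, bathy, config)
  list(config = config, bathy = bathy, env = env, truth = truth,
       catalogue = catalogue, records = records)
}
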