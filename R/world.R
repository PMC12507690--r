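# Synthetic-world generation: bathymetry and sea-floor environmental fields
# with known ground truth, emulating the statistical structure of real global
# occurrence compilations (effort-biased sampling, ~1/3 missing depths,
# temperature declining with depth and latitude, POC flux decaying with depth).

# run expr under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Species range archetypes
#'
#' The six qualitative range shapes the generator draws from: tropical and
#' anti-tropical shelf species, tropical and bimodal bathyal species,
#' cosmopolitan abyssal species and polar endemics.
#'
#' @return character vector of archetype names.
#' @export
species_archetypes <- function() {
  c("shallow_tropical", "shallow_antitropical", "bathyal_tropical",
    "bathyal_bimodal", "abyssal_cosmopolitan", "polar_endemic")
}

#' Configuration of a synthetic world
#'
#' @param lat_min,lat_max latitudinal domain in degrees (default -78 to 82,
#'   the span of the study group from the Antarctic coastline to the Arctic
#'   basin).
#' @param depth_max maximum sea-floor depth generated, metres (default 6000).
#' @param lon_count number of 1-degree longitude columns (default 21, three
#'   7-degree ocean-realm sectors).
#' @param n_species number of species in the assemblage (default 300).
#' @param archetype_mix named proportions over [species_archetypes()],
#'   summing to 1.
#' @param effort_bias strength (>= 0) of the north-temperate/shallow sampling
#'   bias; 0 gives spatially uniform sampling over occupied cells.
#' @param missing_depth_fraction share of records whose depth is withheld
#'   (default 0.333; roughly one third of real locality records lack depths).
#' @param n_records expected total number of occurrence records drawn.
#' @param resolution bathymetry node spacing in degrees (must divide 1).
#' @param flat_depth optional constant depth override (m); produces a
#'   featureless all-sea world, used for closed-form checks.
#' @param seed integer RNG seed; the whole world is deterministic given the
#'   config.
#' @return object of class `world_config`.
#' @export
world_config <- function(lat_min = -78, lat_max = 82, depth_max = 6000,
                         lon_count = 21, n_species = 300,
                         archetype_mix = c(shallow_tropical = 0.30,
                                           shallow_antitropical = 0.10,
                                           bathyal_tropical = 0.20,
                                           bathyal_bimodal = 0.10,
                                           abyssal_cosmopolitan = 0.20,
                                           polar_endemic = 0.10),
                         effort_bias = 1, missing_depth_fraction = 0.333,
                         n_records = 20000, resolution = 0.5,
                         flat_depth = NULL, seed = 1L) {
  stopifnot(lat_min < lat_max, depth_max > 0, lon_count >= 1, n_species >= 0,
            effort_bias >= 0,
            missing_depth_fraction >= 0, missing_depth_fraction <= 1)
  if (abs(sum(archetype_mix) - 1) > 1e-9) {
    stop("archetype_mix proportions must sum to 1")
  }
  if (!all(names(archetype_mix) %in% species_archetypes())) {
    stop("unknown archetype in archetype_mix")
  }
  structure(list(
    lat_min = lat_min, lat_max = lat_max, depth_max = depth_max,
    lon_count = as.integer(lon_count), n_species = as.integer(n_species),
    archetype_mix = archetype_mix, effort_bias = effort_bias,
    missing_depth_fraction = missing_depth_fraction,
    n_records = as.integer(n_records), resolution = resolution,
    flat_depth = flat_depth, seed = as.integer(seed)
  ), class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf(
    "world_config: lat [%g, %g], depth <= %g m, %d deg of longitude\n",
    x$lat_min, x$lat_max, x$depth_max, x$lon_count))
  cat(sprintf("  %d species, %d expected records, effort bias %g, seed %d\n",
              x$n_species, x$n_records, x$effort_bias, x$seed))
  invisible(x)
}

# smooth seeded 2-D noise field on the node grid (sum of random sinusoids)
smooth_noise <- function(n_lat, n_lon, amplitude, n_waves = 6) {
  out <- matrix(0, n_lat, n_lon)
  li <- seq_len(n_lat) / n_lat
  lj <- seq_len(n_lon) / n_lon
  for (k in seq_len(n_waves)) {
    f1 <- stats::runif(1, 1, 5); f2 <- stats::runif(1, 1, 5)
    p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
    out <- out + outer(sin(2 * pi * f1 * li + p1), sin(2 * pi * f2 * lj + p2))
  }
  out * amplitude / n_waves
}

#' Generate a synthetic bathymetry grid
#'
#' Builds a sea floor with meridional coastlines bounding three ocean-basin
#' sectors: a narrow land strip at each sector edge, a shelf (< 200 m), a
#' continental slope, and an abyssal plain with smooth seeded relief. The
#' Arctic (north of 70 N) is generated shallower than the other basins.
#'
#' @param config a [world_config()].
#' @return a [bathy_grid()].
#' @export
generate_bathymetry <- function(config) {
  res <- config$resolution
  n_lat <- as.integer(round((config$lat_max - config$lat_min) / res))
  n_lon <- as.integer(round(config$lon_count / res))
  if (n_lat < 1 || n_lon < 1) stop("non-positive grid dimensions")
  if (!is.null(config$flat_depth)) {
    d <- matrix(config$flat_depth, n_lat, n_lon)
    return(bathy_grid(d, config$lat_min, 0, res))
  }
  with_seed(config$seed + 101L, {
    lat <- config$lat_min + res * (seq_len(n_lat) - 0.5)
    lon <- res * (seq_len(n_lon) - 0.5)
    sector_w <- config$lon_count / 3
    # distance (deg) to the nearest sector-edge coastline
    edges <- seq(0, config$lon_count, by = sector_w)
    dist_coast <- vapply(lon, function(x) min(abs(x - edges)), numeric(1))
    # cross-shelf profile: land strip, shelf, slope, abyssal plain
    profile <- function(dc) {
      ifelse(dc < 0.5, -50,
        ifelse(dc < 1.25, 10 + 190 * (dc - 0.5) / 0.75,
          ifelse(dc < 2.5, 200 + 4200 * (dc - 1.25) / 1.25, 4400)))
    }
    base <- matrix(rep(profile(dist_coast), each = n_lat), n_lat, n_lon)
    relief <- smooth_noise(n_lat, n_lon, amplitude = 900)
    d <- base + relief * pmin(1, base / 1500)  # relief only off the shelf
    arctic <- lat > 70
    d[arctic, ] <- d[arctic, ] * 0.45          # shallow Arctic basin
    d <- pmin(d, config$depth_max)
    d[base <= 0] <- -50
    bathy_grid(d, config$lat_min, 0, res)
  })
}

#' Generate sea-floor environmental fields
#'
#' Smooth analytic fields evaluated at every sea-floor node of the bathymetry,
#' plus small seeded noise. Temperature decreases with depth and absolute
#' latitude, with polar deep water placed below `threshold_temp` (the
#' generated thermal threshold that downstream breakpoint detection should
#' recover); NPP peaks at temperate latitudes; salinity is near-constant with
#' one step at 1,500 m (a water-mass proxy); nitrate and silicate are built
#' strongly correlated to exercise the collinearity screen; POC flux is the
#' Martin-curve export of surface NPP to the sea floor.
#'
#' @param config a [world_config()].
#' @param bathy bathymetry generated from the same config.
#' @param threshold_temp deep-water thermal threshold in deg C, inside
#'   `[-2, 30]` (default 1.5).
#' @return object of class `env_field_set`: node matrices (same shape as
#'   `bathy$depth`, `NA` on land) for temperature, salinity, oxygen, nitrate,
#'   silicate, npp and poc_flux, plus the analytic parameters.
#' @export
generate_environment <- function(config, bathy, threshold_temp = 1.5) {
  if (threshold_temp < -2 || threshold_temp > 30) {
    stop("threshold_temp outside [-2, 30]")
  }
  n_lat <- nrow(bathy$depth); n_lon <- ncol(bathy$depth)
  latm <- matrix(bathy$lat, n_lat, n_lon)
  depth <- bathy$depth
  sea <- depth > 0
  with_seed(config$seed + 202L, {
    temp <- env_temperature(latm, depth, threshold_temp)
    sal <- 34.2 + 0.5 * (depth > 1500) +
      smooth_noise(n_lat, n_lon, amplitude = 0.01)
    oxy <- 6.5 - 2.5 * exp(-((depth - 800) / 500)^2) +
      0.1 * abs(latm) / 90 + smooth_noise(n_lat, n_lon, amplitude = 0.05)
    nit <- 5 + 25 * (1 - exp(-depth / 1000)) + 0.01 * abs(latm) +
      smooth_noise(n_lat, n_lon, amplitude = 0.3)
    sil <- 1.6 * nit + smooth_noise(n_lat, n_lon, amplitude = 4.0)
    npp <- env_npp(latm) + smooth_noise(n_lat, n_lon, amplitude = 15)
    poc <- poc_export(npp, pmax(depth, 100))
    vars <- list(temperature = temp, salinity = sal, oxygen = oxy,
                 nitrate = nit, silicate = sil, npp = npp, poc_flux = poc)
    vars <- lapply(vars, function(m) { m[!sea] <- NA_real_; m })
    structure(list(vars = vars, threshold_temp = threshold_temp,
                   lat = bathy$lat, lon = bathy$lon),
              class = "env_field_set")
  })
}

# analytic temperature: deep profile crossing threshold_temp at |lat| = 60,
# plus a surface-intensified warm layer decaying over ~500 m; floor -1.9 C
env_temperature <- function(lat, depth, threshold_temp) {
  rad <- lat * pi / 180
  t_deep <- threshold_temp + 6 * (cos(rad) - cos(60 * pi / 180))
  amp <- 26 * cos(rad)^2 + 0.5
  pmax(-1.9, t_deep + amp * exp(-depth / 500))
}

# analytic surface NPP: temperate maxima near |lat| = 45
env_npp <- function(lat) {
  150 + 550 * exp(-((abs(lat) - 45) / 18)^2)
}

#' @export
print.env_field_set <- function(x, ...) {
  cat(sprintf("env_field_set: %s\n", paste(names(x$vars), collapse = ", ")))
  cat(sprintf("  deep-water thermal threshold %.2f degC\n", x$threshold_temp))
  invisible(x)
}
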