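# Raw occupancy and informed range interpolation.

simple_catalogue <- function(species_id, dmin, dmax, lat_min, lat_max,
                             bands = "") {
  data.frame(species_id = species_id, genus = "g", family = "f",
             depth_min_m = dmin, depth_max_m = dmax,
             lat_min = lat_min, lat_max = lat_max, regions = "Atlantic",
             exclusion_bands = bands, shallow_flag = FALSE,
             stringsAsFactors = FALSE)
}

test_that("raw occupancy fills the catalogued depth column at observed latitudes only", {
  cat1 <- simple_catalogue("sp1", 0, 100, -90, 90)
  rec <- data.frame(species_id = "sp1", decimalLatitude = 40.3,
                    decimalLongitude = 1, depth_m = 50, source = "obis")
  breaks <- seq(0, 200, by = 10)
  cube <- raw_occupancy(rec, cat1, breaks, lat_bins = 35:45)
  expect_equal(sum(cube$presence), 10)
  expect_equal(sum(cube$presence[1, match(40, cube$lat_bins), ]), 10)
  expect_true(all(cube$presence[1, cube$lat_bins != 40, ] == FALSE))

  empty <- raw_occupancy(rec[0, ], cat1, breaks, lat_bins = 35:45)
  expect_equal(sum(empty$presence), 0)
})

test_that("raw occupancy equals per-record brute-force marking", {
  set.seed(3)
  cat3 <- simple_catalogue(paste0("sp", 1:6), dmin = c(0, 0, 100, 200, 0, 50),
                           dmax = c(100, 300, 400, 800, 50, 250),
                           lat_min = -30, lat_max = 30)
  rec <- data.frame(species_id = sample(cat3$species_id, 60, replace = TRUE),
                    decimalLatitude = runif(60, -30, 30),
                    decimalLongitude = runif(60, 0, 5),
                    depth_m = runif(60, 0, 500), source = "obis")
  breaks <- seq(0, 800, by = 50)
  lat_bins <- -30:29
  cube <- raw_occupancy(rec, cat3, breaks, lat_bins)
  # oracle: mark each record's latitude bin across the catalogued interval
  oracle <- array(FALSE, dim(cube$presence))
  for (k in seq_len(nrow(rec))) {
    si <- match(rec$species_id[k], cube$species_ids)
    ci <- match(rec$species_id[k], cat3$species_id)
    li <- match(floor(rec$decimalLatitude[k]), lat_bins)
    l <- breaks[-length(breaks)]; u <- breaks[-1]
    di <- which(l < cat3$depth_max_m[ci] & u > cat3$depth_min_m[ci])
    oracle[si, li, di] <- TRUE
  }
  expect_equal(cube$presence, oracle, ignore_attr = TRUE)
})

test_that("informed interpolation bridges gaps and respects blocking", {
  breaks <- seq(0, 200, by = 10)
  env <- data.frame(lat_bin = 0:29, min_depth_m = 10, max_depth_m = 4000,
                    has_sea = TRUE)
  rng <- data.frame(species_id = "sp1", lon_min = 0, lon_max = 1,
                    depth_min = 0, depth_max = 100, lat_min = 0,
                    lat_max = 30, exclusion_bands = "",
                    stringsAsFactors = FALSE)
  rng$obs_bins <- list(c(10L, 20L))
  occ <- informed_interpolate(rng, env, breaks, lat_bins = 0:29)
  expect_equal(sum(rowSums(occ) > 0), 11)  # 10..20 inclusive

  # a latitude whose envelope misses the species' depths blocks the bridge
  env2 <- env
  env2[env2$lat_bin == 15, c("min_depth_m", "max_depth_m")] <- c(3000, 4000)
  occ2 <- informed_interpolate(rng, env2, breaks, lat_bins = 0:29)
  occupied <- which(rowSums(occ2) > 0) - 1
  expect_false(15 %in% occupied)
  expect_setequal(occupied, c(10:14, 16:20))  # both segments hold records

  # a segment holding no observation is discarded entirely
  env5 <- env
  env5[env5$lat_bin %in% c(13, 16), c("min_depth_m", "max_depth_m")] <-
    rep(c(3000, 4000), each = 2)
  rng5 <- rng
  rng5$obs_bins <- list(c(10L, 12L, 20L))
  occ5 <- informed_interpolate(rng5, env5, breaks, 0:29)
  occupied5 <- which(rowSums(occ5) > 0) - 1
  expect_setequal(occupied5, c(10:12, 17:20))  # 14:15 dropped with no record
})

test_that("anti-tropical exclusion bands stay empty", {
  breaks <- seq(0, 200, by = 10)
  env <- data.frame(lat_bin = -50:49, min_depth_m = 10, max_depth_m = 4000,
                    has_sea = TRUE)
  rng <- data.frame(species_id = "sp1", lon_min = 0, lon_max = 1,
                    depth_min = 0, depth_max = 100, lat_min = -50,
                    lat_max = 50, exclusion_bands = "-23:23",
                    stringsAsFactors = FALSE)
  rng$obs_bins <- list(c(-40L, 40L))
  occ <- informed_interpolate(rng, env, breaks, lat_bins = -50:49)
  occupied <- (-50:49)[rowSums(occ) > 0]
  expect_true(all(occupied <= -23 | occupied >= 23))
  expect_true(-40 %in% occupied && 40 %in% occupied)
})

test_that("informed interpolation matches the per-cell rule oracle", {
  set.seed(11)
  for (k in 1:40) {
    inst <- random_range_instance()
    got <- informed_interpolate(inst$range, inst$envelopes,
                                inst$depth_breaks, inst$lat_bins)
    want <- brute_interpolate(inst$range, inst$envelopes,
                              inst$depth_breaks, inst$lat_bins)
    expect_identical(got, want)
  }
})

test_that("flat worlds interpolate to full observed span times depth bins", {
  cfg <- world_config(lat_min = -40, lat_max = 40, lon_count = 3,
                      flat_depth = 800, n_species = 25, n_records = 4000,
                      missing_depth_fraction = 0, seed = 8,
                      archetype_mix = c(bathyal_tropical = 1))
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  catal <- catalogue_from_truth(truth)
  rec <- sample_occurrences(truth, b, cfg)
  cubes <- build_cubes(rec, catal, b, depth_breaks = seq(0, 800, 50))
  ranges <- cubes$ranges
  for (k in seq_len(nrow(ranges))) {
    span <- seq(min(ranges$obs_bins[[k]]), max(ranges$obs_bins[[k]]))
    occ_lats <- cubes$interpolated$lat_bins[
      rowSums(cubes$interpolated$presence[k, , ]) > 0]
    expect_setequal(occ_lats, span)
    l <- seq(0, 750, 50); u <- l + 50
    nbins <- sum(l < min(ranges$depth_max[k], 800) & u > ranges$depth_min[k])
    expect_equal(sum(cubes$interpolated$presence[k, , ]),
                 length(span) * nbins)
  }
})

test_that("interpolated occupancy contains raw occupancy cell-wise", {
  for (seed in c(2, 7)) {
    cfg <- lean_config(seed)
    w <- simulate_world(cfg)
    rec <- clean_records(w$records, w$catalogue, w$bathy)
    cubes <- build_cubes(rec, w$catalogue, w$bathy)
    expect_true(all(cubes$interpolated$presence | !cubes$raw$presence))
  }
})

test_that("adding a record never removes occupied cells", {
  set.seed(19)
  inst <- random_range_instance()
  inst$range$obs_bins <- list(c(5L, 20L))
  base <- informed_interpolate(inst$range, inst$envelopes,
                               inst$depth_breaks, inst$lat_bins)
  more <- inst$range
  more$obs_bins <- list(sort(c(5L, 12L, 20L, 25L)))
  grown <- informed_interpolate(more, inst$envelopes, inst$depth_breaks,
                                inst$lat_bins)
  expect_true(all(grown | !base))
})

test_that("range recovery: dense sampling recovers the true span, sparse stays inside", {
  # dense, unbiased sampling so every range-edge bin is hit almost surely
  cfg <- world_config(lat_min = -60, lat_max = 60, lon_count = 18,
                      n_species = 40, n_records = 40000, effort_bias = 0,
                      missing_depth_fraction = 0, seed = 14)
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  catal <- catalogue_from_truth(truth)
  rec <- sample_occurrences(truth, b, cfg)
  cubes <- build_cubes(rec, catal, b)
  n_rec <- table(rec$species_id)
  hit <- 0; eligible <- 0
  for (k in seq_len(nrow(truth))) {
    si <- match(truth$species_id[k], cubes$interpolated$species_ids)
    if (is.na(si) || n_rec[truth$species_id[k]] < 50) next
    eligible <- eligible + 1
    occ_lats <- cubes$interpolated$lat_bins[
      rowSums(cubes$interpolated$presence[si, , ]) > 0]
    true_bins <- unlist(lapply(seq_len(nrow(truth$lat_intervals[[k]])),
                               function(i) truth$lat_intervals[[k]][i, 1]:
                                 (truth$lat_intervals[[k]][i, 2] - 1)))
    if (length(occ_lats) && min(occ_lats) == min(true_bins) &&
        max(occ_lats) == max(true_bins)) hit <- hit + 1
  }
  expect_gte(eligible, 25)
  expect_gte(hit / eligible, 0.99)

  # sparse sampling: interpolated span never exceeds the true span
  cfg2 <- world_config(lat_min = -60, lat_max = 60, lon_count = 18,
                       n_species = 60, n_records = 150,
                       missing_depth_fraction = 0, seed = 15)
  truth2 <- generate_assemblage(cfg2, b)
  catal2 <- catalogue_from_truth(truth2)
  rec2 <- sample_occurrences(truth2, b, cfg2)
  cubes2 <- build_cubes(rec2, catal2, b)
  for (si in seq_along(cubes2$interpolated$species_ids)) {
    k <- match(cubes2$interpolated$species_ids[si], truth2$species_id)
    occ_lats <- cubes2$interpolated$lat_bins[
      rowSums(cubes2$interpolated$presence[si, , ]) > 0]
    expect_gte(min(occ_lats), min(truth2$lat_intervals[[k]][, 1]))
    expect_lte(max(occ_lats), max(truth2$lat_intervals[[k]][, 2]) - 1)
  }
})

test_that("regional clipping restricts species to the region's records", {
  cfg <- lean_config(25)
  w <- simulate_world(cfg)
  rec <- clean_records(w$records, w$catalogue, w$bathy)
  atl <- list(name = "Atlantic", lon_min = 0, lon_max = 6)
  iwp <- list(name = "IWP", lon_min = 12, lon_max = 18)
  breaks <- stratified_depth_breaks()
  lat_bins <- -78:81
  cube_iwp <- clip_to_region(rec, w$catalogue, w$bathy, iwp, breaks,
                             lat_bins)
  atl_only <- w$truth$species_id[w$truth$region_label == "Atlantic"]
  expect_length(intersect(cube_iwp$species_ids, atl_only), 0)
  # clipping to the full domain reproduces the unclipped cube
  full <- list(name = "all", lon_min = 0, lon_max = cfg$lon_count)
  cube_full <- clip_to_region(rec, w$catalogue, w$bathy, full, breaks,
                              lat_bins)
  cubes <- build_cubes(rec, w$catalogue, w$bathy, depth_breaks = breaks,
                       lat_bins = lat_bins)
  expect_equal(sort(cube_full$species_ids),
               sort(cubes$interpolated$species_ids))
  expect_equal(sum(cube_full$presence), sum(cubes$interpolated$presence))
  # per-region occupancy of cross-regional species respects region records
  crx <- w$truth$species_id[w$truth$region_label == "cross-regional"]
  rec_iwp <- rec[rec$decimalLongitude >= 12 & rec$decimalLongitude < 18 &
                   rec$species_id %in% crx, ]
  for (sp in intersect(crx, cube_iwp$species_ids)[1:5]) {
    si <- match(sp, cube_iwp$species_ids)
    occ_lats <- cube_iwp$lat_bins[rowSums(cube_iwp$presence[si, , ]) > 0]
    obs <- floor(rec_iwp$decimalLatitude[rec_iwp$species_id == sp])
    expect_gte(min(occ_lats), min(obs) - 0)
    expect_lte(max(occ_lats), max(obs) + 0)
  }
})
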