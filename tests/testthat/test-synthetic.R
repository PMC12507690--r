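# The synthetic-world generator: bathymetry, environment, assemblages,
# effort-biased sampling and ground-truth export.

test_that("flat-depth override produces a constant all-sea world", {
  cfg <- world_config(lat_min = 0, lat_max = 10, lon_count = 3,
                      flat_depth = 3000, seed = 1)
  b <- generate_bathymetry(cfg)
  expect_true(all(b$depth == 3000))
})

test_that("worlds are deterministic under the config seed", {
  cfg <- lean_config(42)
  b1 <- generate_bathymetry(cfg)
  b2 <- generate_bathymetry(cfg)
  expect_identical(b1, b2)
  e1 <- generate_environment(cfg, b1)
  e2 <- generate_environment(cfg, b1)
  expect_identical(e1, e2)
  t1 <- generate_assemblage(cfg, b1)
  r1 <- sample_occurrences(t1, b1, cfg)
  r2 <- sample_occurrences(t1, b1, cfg)
  expect_identical(r1, r2)
})

test_that("default bathymetry has a shelf but is mostly deeper water", {
  b <- generate_bathymetry(lean_config(3))
  shelf <- mean(b$depth > 0 & b$depth < 200)
  expect_gt(shelf, 0)
  expect_lt(shelf, 0.5)
  expect_true(any(b$depth <= 0))  # land exists
})

test_that("environment fields respect their construction constraints", {
  cfg <- lean_config(5)
  b <- generate_bathymetry(cfg)
  e <- generate_environment(cfg, b, threshold_temp = 1.2)
  # surface equatorial water is the warmest in its column
  t0 <- bathyrich:::env_temperature(0, 0, 1.2)
  expect_gt(t0, bathyrich:::env_temperature(0, 1000, 1.2))
  expect_gt(t0, bathyrich:::env_temperature(60, 0, 1.2))
  # polar deep water sits below the generated threshold
  expect_lt(bathyrich:::env_temperature(75, 4000, 1.2), 1.2)
  expect_lt(bathyrich:::env_temperature(-70, 4000, 1.2), 1.2)
  # nitrate and silicate are strongly collinear by construction
  r <- cor(as.vector(e$vars$nitrate), as.vector(e$vars$silicate),
           use = "complete.obs")
  expect_gt(r, 0.7)
  expect_error(generate_environment(cfg, b, threshold_temp = 45),
               "threshold_temp")
})

test_that("anti-tropical species carry two latitudinal intervals", {
  cfg <- world_config(lat_min = -60, lat_max = 60, lon_count = 3,
                      n_species = 40, flat_depth = 150, seed = 9,
                      archetype_mix = c(shallow_antitropical = 1))
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  expect_equal(nrow(truth), 40)
  expect_true(all(vapply(truth$lat_intervals, nrow, integer(1)) == 2))
  # the tropical gap is empty
  for (m in truth$lat_intervals) {
    expect_true(all(m[, 2] <= -23 | m[, 1] >= 23))
  }
})

test_that("empty assemblages are allowed", {
  cfg <- world_config(n_species = 0, lon_count = 3, flat_depth = 1000,
                      seed = 1, lat_min = 0, lat_max = 10)
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  expect_equal(nrow(truth), 0)
})

test_that("archetype counts stay inside the binomial 99% band", {
  cfg <- lean_config(21, n_species = 300)
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  counts <- table(factor(truth$archetype, levels = names(cfg$archetype_mix)))
  for (a in names(cfg$archetype_mix)) {
    p <- cfg$archetype_mix[[a]]
    expect_gte(counts[[a]], qbinom(0.005, 300, p))
    expect_lte(counts[[a]], qbinom(0.995, 300, p))
  }
})

test_that("every sampled occurrence lies inside its species' true range", {
  cfg <- lean_config(33)
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  rec <- sample_occurrences(truth, b, cfg)
  idx <- match(rec$species_id, truth$species_id)
  in_lat <- vapply(seq_len(nrow(rec)), function(k) {
    m <- truth$lat_intervals[[idx[k]]]
    any(rec$decimalLatitude[k] >= m[, 1] & rec$decimalLatitude[k] <= m[, 2])
  }, logical(1))
  expect_true(all(in_lat))
  known <- !is.na(rec$depth_m)
  expect_true(all(rec$depth_m[known] >= truth$depth_min[idx][known] &
                    rec$depth_m[known] <= truth$depth_max[idx][known]))
  expect_true(all(rec$decimalLongitude >= truth$lon_min[idx] &
                    rec$decimalLongitude < truth$lon_max[idx]))
})

test_that("missing-depth withholding matches the configured share", {
  cfg <- world_config(lat_min = -30, lat_max = 30, lon_count = 3,
                      flat_depth = 500, n_species = 20, n_records = 50000,
                      missing_depth_fraction = 0.333, seed = 13,
                      archetype_mix = c(bathyal_tropical = 1))
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  rec <- sample_occurrences(truth, b, cfg)
  expect_equal(mean(is.na(rec$depth_m)), 0.333, tolerance = 0.02 / 0.333)
  cfg0 <- world_config(lat_min = -30, lat_max = 30, lon_count = 3,
                       flat_depth = 500, n_species = 20, n_records = 2000,
                       missing_depth_fraction = 0, seed = 13,
                       archetype_mix = c(bathyal_tropical = 1))
  rec0 <- sample_occurrences(generate_assemblage(cfg0, b), b, cfg0)
  expect_false(anyNA(rec0$depth_m))
})

test_that("zero effort bias gives uniform sampling over occupied cells", {
  cfg <- world_config(lat_min = 0, lat_max = 20, lon_count = 3,
                      flat_depth = 500, n_species = 1, n_records = 10000,
                      effort_bias = 0, missing_depth_fraction = 0, seed = 17,
                      archetype_mix = c(bathyal_tropical = 1))
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  rec <- sample_occurrences(truth, b, cfg)
  ix <- bathyrich:::node_index(b, rec$decimalLatitude, rec$decimalLongitude)
  cell <- paste(ix$i, ix$j)
  cand <- bathyrich:::species_candidates(truth, b, cfg)[[1]]$idx
  counts <- table(factor(cell, levels = unique(cell)))
  # chi-square GOF against the uniform expectation over occupied cells
  observed <- rep(0L, length(cand))
  nlat <- nrow(b$depth)
  names(observed) <- paste((cand - 1L) %% nlat + 1L, (cand - 1L) %/% nlat + 1L)
  observed[names(counts)] <- as.integer(counts)
  p <- suppressWarnings(chisq.test(observed)$p.value)
  expect_gt(p, 0.01)
})

test_that("the effort field integrates to the expected sample size", {
  cfg <- lean_config(19)
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  ef <- effort_field(truth, b, cfg)
  expect_equal(sum(ef$values), cfg$n_records, tolerance = 0.01)
})

test_that("ground truth round-trips losslessly through export files", {
  cfg <- lean_config(23, n_species = 50)
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  dir <- withr::local_tempdir()
  export_truth(truth, cfg, dir)
  expect_equal(length(readLines(file.path(dir, "truth.csv"))), 50 + 1)
  back <- read_truth(dir)
  expect_equal(back$truth$species_id, truth$species_id)
  expect_equal(back$truth$depth_min, truth$depth_min)
  for (i in seq_len(nrow(truth))) {
    expect_equal(unname(back$truth$lat_intervals[[i]]),
                 unname(truth$lat_intervals[[i]]))
  }
  expect_equal(back$config$seed, cfg$seed)
  expect_equal(back$config$archetype_mix, cfg$archetype_mix)
})

test_that("an empty assemblage exports a valid file", {
  cfg <- world_config(n_species = 0, lon_count = 3, flat_depth = 1000,
                      lat_min = 0, lat_max = 5, seed = 2)
  b <- generate_bathymetry(cfg)
  truth <- generate_assemblage(cfg, b)
  dir <- withr::local_tempdir()
  export_truth(truth, cfg, dir)
  back <- read_truth(dir)
  expect_equal(nrow(back$truth), 0)
})

test_that("world configs validate their invariants", {
  expect_error(world_config(lat_min = 10, lat_max = 0), "lat_min")
  expect_error(world_config(archetype_mix = c(shallow_tropical = 0.5)),
               "sum to 1")
  expect_error(world_config(missing_depth_fraction = 1.5))
})
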