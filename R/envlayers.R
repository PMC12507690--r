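# Environmental predictor preparation: averaging sea-floor fields into
# 1-degree x 100-m cells, Martin-curve POC export, collinearity screening
# and per-stratum normalisation.

#' Particulate organic carbon export to depth
#'
#' Martin-type power-law attenuation of surface production:
#' `flux = export_ratio * NPP * (depth / z_ref)^(-b)`. Depths above the
#' reference depth are clamped to the reference-depth export with a warning.
#'
#' @param npp_surface surface net primary productivity (same units as the
#'   returned flux before the export ratio).
#' @param depth_m evaluation depth(s), metres.
#' @param b attenuation exponent (default 0.858, the classic open-ocean
#'   value).
#' @param z_ref reference export depth, metres (default 100).
#' @param export_ratio fraction of NPP exported at `z_ref` (default 0.1).
#' @return POC flux in g C m^-2 yr^-1 (given NPP in g C m^-2 yr^-1).
#' @export
poc_export <- function(npp_surface, depth_m, b = 0.858, z_ref = 100,
                       export_ratio = 0.1) {
  if (any(depth_m < z_ref)) {
    warning("depth above reference depth; flux clamped to export at z_ref")
    depth_m <- pmax(depth_m, z_ref)
  }
  export_ratio * npp_surface * (depth_m / z_ref)^(-b)
}

#' Average environmental fields into latitude x depth cells
#'
#' For each 1-degree latitude x 100-m depth cell, the mean of every
#' environmental variable over the sea-floor grid nodes whose floor depth
#' falls in the cell and whose location passes the region mask. Cells with
#' no contributing nodes are absent from the table (not zero).
#'
#' @param env an `env_field_set` from [generate_environment()] (node
#'   matrices over the bathymetry grid).
#' @param bathy the matching [bathy_grid()].
#' @param mask optional region mask: list with any of `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max` (inclusion caps) and `exclude` (list of boxes,
#'   each with lat/lon min/max, removed — e.g. a marginal sea).
#' @param depth_breaks 100-m bin edges (default to 6000 m).
#' @return data.frame of class `env_cell_table`: `lat_bin, depth_bin` (lower
#'   edges) plus one column per variable and `n_nodes`.
#' @export
grid_environment <- function(env, bathy, mask = NULL,
                             depth_breaks = uniform_depth_breaks()) {
  n_lat <- nrow(bathy$depth); n_lon <- ncol(bathy$depth)
  latv <- rep(bathy$lat, times = n_lon)
  lonv <- rep(bathy$lon, each = n_lat)
  depth <- as.vector(bathy$depth)
  keep <- depth > 0 & depth >= depth_breaks[1] &
    depth < depth_breaks[length(depth_breaks)]
  keep <- keep & pass_mask(latv, lonv, mask)
  if (!any(keep)) {
    out <- data.frame(lat_bin = numeric(0), depth_bin = numeric(0),
                      n_nodes = integer(0))
    for (v in names(env$vars)) out[[v]] <- numeric(0)
    class(out) <- c("env_cell_table", "data.frame")
    return(out)
  }
  lat_bin <- floor(latv[keep])
  depth_bin <- depth_breaks[findInterval(depth[keep], depth_breaks)]
  key <- paste(lat_bin, depth_bin, sep = "|")
  out <- data.frame(lat_bin = lat_bin, depth_bin = depth_bin)[!duplicated(key), ]
  out <- out[order(out$lat_bin, out$depth_bin), ]
  okey <- paste(out$lat_bin, out$depth_bin, sep = "|")
  out$n_nodes <- as.integer(table(key)[okey])
  for (v in names(env$vars)) {
    vals <- as.vector(env$vars[[v]])[keep]
    means <- tapply(vals, key, mean, na.rm = TRUE)
    out[[v]] <- as.numeric(means[okey])
  }
  rownames(out) <- NULL
  class(out) <- c("env_cell_table", "data.frame")
  out
}

pass_mask <- function(lat, lon, mask) {
  ok <- rep(TRUE, length(lat))
  if (is.null(mask)) return(ok)
  if (!is.null(mask$lat_min)) ok <- ok & lat >= mask$lat_min
  if (!is.null(mask$lat_max)) ok <- ok & lat <= mask$lat_max
  if (!is.null(mask$lon_min)) ok <- ok & lon >= mask$lon_min
  if (!is.null(mask$lon_max)) ok <- ok & lon <= mask$lon_max
  for (box in mask$exclude %||% list()) {
    inside <- lat >= (box$lat_min %||% -90) & lat <= (box$lat_max %||% 90) &
      lon >= (box$lon_min %||% -Inf) & lon <= (box$lon_max %||% Inf)
    ok <- ok & !inside
  }
  ok
}

#' Join richness response and effort offset onto the environment table
#'
#' Adds `richness` (from a richness grid on 100-m bins) and `effort_offset`
#' (log record count + 1) columns, keyed by (lat_bin, depth_bin).
#'
#' @param env_table an `env_cell_table`.
#' @param richness_grid `lat_depth_grid` of richness on 100-m bins.
#' @param effort optional `lat_depth_grid` of record counts on the same
#'   axes; absent cells get offset 0.
#' @return the table with `richness` and `effort_offset` columns; rows whose
#'   cell lies outside the richness grid are dropped.
#' @export
cell_table <- function(env_table, richness_grid, effort = NULL) {
  li <- match(env_table$lat_bin, richness_grid$lat_bins)
  dl <- richness_grid$depth_breaks[-length(richness_grid$depth_breaks)]
  di <- match(env_table$depth_bin, dl)
  ok <- !is.na(li) & !is.na(di)
  out <- env_table[ok, , drop = FALSE]
  out$richness <- richness_grid$values[cbind(li[ok], di[ok])]
  if (is.null(effort)) {
    out$effort_offset <- 0
  } else {
    le <- match(out$lat_bin, effort$lat_bins)
    de <- match(out$depth_bin, effort$depth_breaks[-length(effort$depth_breaks)])
    cnt <- rep(0, nrow(out))
    okk <- !is.na(le) & !is.na(de)
    cnt[okk] <- effort$values[cbind(le[okk], de[okk])]
    out$effort_offset <- log(cnt + 1)
  }
  rownames(out) <- NULL
  out
}

#' Screen predictors for collinearity
#'
#' Among predictor pairs with `|Pearson r|` strictly above the threshold,
#' drops the configured victim (the first of `priority` present in the
#' pair; if neither is, the second member). Constant columns cannot be
#' screened and are flagged.
#'
#' @param table data.frame holding the predictors.
#' @param predictors character vector of predictor column names (>= 2).
#' @param threshold absolute correlation above which a pair is collinear
#'   (default 0.7, strict).
#' @param priority victim priority list (default silicate, then phosphate).
#' @return list with `kept` (surviving predictor names), `dropped`
#'   (data.frame pair/r/victim) and `constant` (unscreenable columns).
#' @export
collinearity_screen <- function(table, predictors, threshold = 0.7,
                                priority = c("silicate", "phosphate")) {
  stopifnot(length(predictors) >= 2)
  x <- table[, predictors, drop = FALSE]
  sds <- vapply(x, stats::sd, numeric(1), na.rm = TRUE)
  constant <- predictors[!is.finite(sds) | sds == 0]
  screenable <- setdiff(predictors, constant)
  kept <- screenable
  dropped <- data.frame(var1 = character(0), var2 = character(0),
                        r = numeric(0), victim = character(0))
  pairs <- utils::combn(screenable, 2, simplify = FALSE)
  for (p in pairs) {
    if (!all(p %in% kept)) next
    r <- stats::cor(table[[p[1]]], table[[p[2]]],
                    use = "pairwise.complete.obs")
    if (is.finite(r) && abs(r) > threshold) {
      victim <- intersect(priority, p)
      victim <- if (length(victim)) victim[1] else p[2]
      kept <- setdiff(kept, victim)
      dropped <- rbind(dropped, data.frame(var1 = p[1], var2 = p[2], r = r,
                                           victim = victim))
    }
  }
  list(kept = kept, dropped = dropped, constant = constant)
}

#' Normalise predictors within depth strata
#'
#' Centres each predictor to mean 0 (and by default scales to unit standard
#' deviation) separately within each depth stratum; the response and offset
#' columns are untouched. Zero-variance columns are centred only and
#' flagged via the `flagged` attribute.
#'
#' @param table cell table with `depth_bin` column.
#' @param predictors character vector of columns to normalise.
#' @param strata data.frame as from [depth_strata()].
#' @param scale scale to unit SD (default TRUE); FALSE restores
#'   centring-only behaviour.
#' @return the table with normalised predictor columns.
#' @export
normalize_per_stratum <- function(table, predictors,
                                  strata = depth_strata(), scale = TRUE) {
  flagged <- character(0)
  for (s in seq_len(nrow(strata))) {
    in_s <- table$depth_bin >= strata$lower[s] &
      table$depth_bin < strata$upper[s]
    if (!any(in_s)) next
    for (v in predictors) {
      col <- table[[v]][in_s]
      mu <- mean(col, na.rm = TRUE)
      sdv <- stats::sd(col, na.rm = TRUE)
      col <- col - mu
      if (scale) {
        if (is.finite(sdv) && sdv > 0) {
          col <- col / sdv
        } else {
          flagged <- union(flagged, v)
        }
      }
      table[[v]][in_s] <- col
    }
  }
  attr(table, "flagged") <- flagged
  table
}

#' Per-latitude stratum table for driver modelling
#'
#' Collapses the (latitude, 100-m depth) cell table to one row per latitude
#' bin within a depth stratum: the response is the maximum richness over the
#' stratum's cells at that latitude (depth sections are treated
#' independently of depth within a stratum), predictors are averaged over
#' the same cells, and the effort offset is the log of the summed record
#' count.
#'
#' @param table a cell table from [cell_table()] (with `richness` and
#'   `effort_offset` columns).
#' @param stratum stratum name from [depth_strata()].
#' @param predictors predictor columns to average.
#' @return data.frame with one row per latitude bin.
#' @export
stratum_table <- function(table, stratum = c("shallow", "bathyal",
                                             "abyssal"),
                          predictors = c("temperature", "salinity",
                                         "oxygen", "nitrate", "silicate",
                                         "npp", "poc_flux")) {
  stratum <- match.arg(stratum)
  st <- depth_strata()
  s <- st[st$name == stratum, ]
  rows <- table$depth_bin >= s$lower & table$depth_bin < s$upper
  sub <- table[rows, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  predictors <- intersect(predictors, names(sub))
  lats <- sort(unique(sub$lat_bin))
  out <- data.frame(lat_bin = lats)
  for (v in predictors) {
    out[[v]] <- as.numeric(tapply(sub[[v]], sub$lat_bin, mean,
                                  na.rm = TRUE)[as.character(lats)])
  }
  out$richness <- as.numeric(tapply(sub$richness, sub$lat_bin,
                                    max)[as.character(lats)])
  if ("effort_offset" %in% names(sub)) {
    cnt <- tapply(exp(sub$effort_offset) - 1, sub$lat_bin, sum)
    out$effort_offset <- log(as.numeric(cnt[as.character(lats)]) + 1)
  }
  out$depth_bin <- s$lower
  out
}
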