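# Reading, repairing and validating occurrence records against a descriptive
# range catalogue: source filtering, duplicate collapsing, trawl-extent
# midpoints, depth imputation from bathymetry, range-based rejection, hadal
# removal, and taxon-coverage reporting.

occ_columns <- c("species_id", "decimalLatitude", "decimalLongitude",
                 "depth_m", "source")

#' Read occurrence records from CSV
#'
#' Expects Darwin-Core-like columns `species_id, decimalLatitude,
#' decimalLongitude, depth_m, source`. Rows with unparseable or out-of-bounds
#' coordinates (|lat| > 90, lon outside [-180, 180)) are skipped with a
#' warning; blank `depth_m` cells become missing depths. If columns
#' `lat_end`/`lon_end` are present (trawl extents), the record coordinate is
#' replaced by the great-circle midpoint of start and end.
#'
#' @param path CSV file path.
#' @return data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(occ_columns, "depth_m"), names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"depth_m" %in% names(df)) df$depth_m <- NA_real_
  df$decimalLatitude <- suppressWarnings(as.numeric(df$decimalLatitude))
  df$decimalLongitude <- suppressWarnings(as.numeric(df$decimalLongitude))
  df$depth_m <- suppressWarnings(as.numeric(df$depth_m))
  if (all(c("lat_end", "lon_end") %in% names(df))) {
    has_end <- is.finite(df$lat_end) & is.finite(df$lon_end)
    if (any(has_end)) {
      mids <- t(mapply(gc_midpoint,
                       df$decimalLatitude[has_end], df$decimalLongitude[has_end],
                       df$lat_end[has_end], df$lon_end[has_end]))
      df$decimalLatitude[has_end] <- mids[, 1]
      df$decimalLongitude[has_end] <- mids[, 2]
    }
  }
  bad <- !is.finite(df$decimalLatitude) | !is.finite(df$decimalLongitude) |
    abs(df$decimalLatitude) > 90 |
    df$decimalLongitude < -180 | df$decimalLongitude >= 180 |
    (!is.na(df$depth_m) & df$depth_m < 0) |
    is.na(df$species_id) | !nzchar(df$species_id)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, union(occ_columns, names(df)), drop = FALSE]
}

#' Remove records from excluded sources
#'
#' Drops records whose source tag is in `excluded_tags` (e.g. citizen-science
#' repositories whose identifications are not expert-verified); order is
#' preserved.
#'
#' @param records occurrence data.frame.
#' @param excluded_tags character vector of source tags to drop.
#' @return filtered records.
#' @export
filter_sources <- function(records, excluded_tags = "inat") {
  out <- records[!(records$source %in% excluded_tags), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse duplicate records
#'
#' Records with the same species, coordinates equal to 4 decimal places and
#' depth equal to 1 m (missing depths compare equal to each other) are
#' collapsed to the first occurrence.
#'
#' @param records occurrence data.frame.
#' @return de-duplicated records.
#' @export
collapse_duplicates <- function(records) {
  key <- paste(records$species_id,
               round(records$decimalLatitude, 4),
               round(records$decimalLongitude, 4),
               ifelse(is.na(records$depth_m), "NA", round(records$depth_m)),
               sep = "|")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute missing depths from bathymetry
#'
#' Replaces missing record depths with the sea-floor depth at the nearest
#' bathymetry node; records with known depth are unchanged. Adds a logical
#' `depth_imputed` column. Records whose coordinate falls outside the grid
#' domain (or on land, where no sensible floor depth exists) are flagged
#' `depth_unresolved` and left missing.
#'
#' @param records occurrence data.frame.
#' @param bathy a [bathy_grid()].
#' @return records with `depth_imputed` (and possibly `depth_unresolved`)
#'   columns.
#' @export
impute_missing_depths <- function(records, bathy) {
  records$depth_imputed <- FALSE
  miss <- is.na(records$depth_m)
  if (any(miss)) {
    ix <- node_index(bathy, records$decimalLatitude[miss],
                     records$decimalLongitude[miss])
    inside <- !is.na(ix$i) & !is.na(ix$j)
    d <- rep(NA_real_, sum(miss))
    d[inside] <- bathy$depth[cbind(ix$i[inside], ix$j[inside])]
    ok <- inside & !is.na(d) & d > 0
    depth_new <- records$depth_m
    depth_new[miss][ok] <- d[ok]
    records$depth_m <- depth_new
    imput <- records$depth_imputed
    imput[miss][ok] <- TRUE
    records$depth_imputed <- imput
    if (any(!ok)) {
      unres <- rep(FALSE, nrow(records))
      unres[which(miss)[!ok]] <- TRUE
      records$depth_unresolved <- unres
    }
  }
  records
}

#' Validate records against the range catalogue
#'
#' Implements the cleaning rules: a record is rejected if its species is
#' absent from the catalogue (`unknown_species`); if its latitude lies
#' outside the catalogued latitudinal limits or inside a catalogued
#' exclusion band (`outside_lat_range`); if its known or imputed depth lies
#' outside the catalogued depth limits by more than `depth_tolerance_m`
#' (`outside_depth_range`; records with unresolved depth are not
#' depth-checked); or if its coordinate falls on land in the bathymetry
#' (`on_land`). Rejection reasons are assessed in that order and the first
#' matching reason is recorded.
#'
#' @param records occurrence data.frame.
#' @param catalogue catalogue data.frame (see [catalogue_from_truth()]).
#' @param bathy a [bathy_grid()]; used for the on-land test.
#' @param depth_tolerance_m slack (m) allowed beyond catalogued depth limits
#'   (default 0).
#' @return list with `records` (retained rows) and `report` (a
#'   `validation_report`).
#' @export
validate_against_catalogue <- function(records, catalogue, bathy,
                                       depth_tolerance_m = 0) {
  if (is.null(catalogue) || nrow(catalogue) == 0) {
    stop("catalogue is required for validation")
  }
  n <- nrow(records)
  m <- match(records$species_id, catalogue$species_id)
  reason <- rep(NA_character_, n)
  reason[is.na(m)] <- "unknown_species"

  known <- which(is.na(reason))
  km <- m[known]
  lat <- records$decimalLatitude[known]
  out_lat <- lat < catalogue$lat_min[km] | lat > catalogue$lat_max[km]
  bands <- lapply(catalogue$exclusion_bands[km], parse_intervals)
  in_band <- mapply(function(x, b) {
    if (nrow(b) == 0) FALSE else any(x > b[, 1] & x < b[, 2])
  }, lat, bands)
  reason[known[out_lat | in_band]] <- "outside_lat_range"

  known <- which(is.na(reason))
  km <- m[known]
  depth <- records$depth_m[known]
  dmin <- catalogue$depth_min_m[km] - depth_tolerance_m
  dmax <- catalogue$depth_max_m[km] + depth_tolerance_m
  bad_d <- !is.na(depth) & (depth < dmin | depth > dmax)
  reason[known[bad_d]] <- "outside_depth_range"

  known <- which(is.na(reason))
  ix <- node_index(bathy, records$decimalLatitude[known],
                   records$decimalLongitude[known])
  inside <- !is.na(ix$i) & !is.na(ix$j)
  floor_d <- rep(NA_real_, length(known))
  floor_d[inside] <- bathy$depth[cbind(ix$i[inside], ix$j[inside])]
  on_land <- inside & floor_d <= 0
  reason[known[on_land]] <- "on_land"

  keep <- is.na(reason)
  tab <- table(factor(reason[!keep],
                      levels = c("unknown_species", "outside_lat_range",
                                 "outside_depth_range", "on_land")))
  by_source <- table(records$source)
  report <- structure(list(
    read = n, retained = sum(keep), rejected = sum(!keep),
    by_reason = as.list(tab), by_source = as.list(by_source)
  ), class = "validation_report")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: %d read, %d retained, %d rejected\n",
              x$read, x$retained, x$rejected))
  for (r in names(x$by_reason)) {
    if (x$by_reason[[r]] > 0) cat(sprintf("  %-20s %d\n", r, x$by_reason[[r]]))
  }
  invisible(x)
}

#' Convert a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path optional file to write; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Remove hadal records
#'
#' Drops records with resolved depth strictly greater than `cutoff` (hadal
#' trench records are sparse, taxonomically poor and very unevenly sampled).
#' Depth exactly at the cutoff is retained.
#'
#' @param records occurrence data.frame with resolved depths.
#' @param cutoff depth cutoff in metres (default 6000).
#' @return filtered records.
#' @export
remove_hadal <- function(records, cutoff = 6000) {
  drop <- !is.na(records$depth_m) & records$depth_m > cutoff
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Taxon coverage of the record set against the catalogue
#'
#' Counts and percentages (half-up, one decimal) of catalogue species,
#' genera and families represented by at least one retained record.
#'
#' @param records occurrence data.frame (retained records).
#' @param catalogue catalogue data.frame with `species_id, genus, family`.
#' @return data.frame with rows species/genus/family and columns
#'   `covered, total, percent`.
#' @export
coverage_report <- function(records, catalogue) {
  if (is.null(catalogue) || nrow(catalogue) == 0) stop("empty catalogue")
  seen <- unique(records$species_id)
  hit <- catalogue$species_id %in% seen
  lvl <- function(col, covered_mask) {
    total <- length(unique(catalogue[[col]]))
    covered <- length(unique(catalogue[[col]][covered_mask]))
    c(covered = covered, total = total)
  }
  sp <- c(covered = sum(hit), total = nrow(catalogue))
  ge <- lvl("genus", hit)
  fa <- lvl("family", hit)
  out <- data.frame(rank = c("species", "genus", "family"),
                    covered = c(sp["covered"], ge["covered"], fa["covered"]),
                    total = c(sp["total"], ge["total"], fa["total"]))
  out$percent <- ifelse(out$covered == 0, 0,
                        percent_of(out$covered, out$total))
  rownames(out) <- NULL
  out
}
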