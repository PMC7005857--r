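# Occurrence-record cleaning: country-mismatch removal with a 10-arc-minute
# border buffer, relocation of near-shore points to the coastline, removal of
# country-centroid coordinates and exact coordinate duplicates, and a
# per-taxon climate-outlier filter (2.5 x IQR fences on >= 3 of the 19
# bioclim layers). Steps compose into an audited pipeline whose report
# satisfies a record-conservation invariant.

#' Remove records whose passport country contradicts their location
#'
#' A record is removed iff it carries a country code and its point lies
#' farther than `buffer_arcmin` outside that country's polygon. Records with
#' no country code cannot be contradicted and are kept (flagged in the
#' pipeline report); unknown codes are removed.
#'
#' @param records `presence_records`.
#' @param countries a `country_map`.
#' @param buffer_arcmin border buffer in arc-minutes (default 10).
#' @return list with `kept`, `removed` (with `reason`), and `flagged`
#'   (record ids lacking a country code).
#' @export
filter_country_mismatch <- function(records, countries, buffer_arcmin = 10) {
  stopifnot(buffer_arcmin >= 0)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  has_code <- !is.na(records$country_code)
  for (i in which(has_code)) {
    k <- match(records$country_code[i], countries$codes)
    if (is.na(k)) { reason[i] <- "unknown country"; next }
    d <- dist_to_polygon(records$lon[i], records$lat[i],
                         countries$polygons[[k]])
    if (d > buffer_arcmin * ARCMIN_M) {
      reason[i] <- "outside declared country beyond buffer"
    }
  }
  keep <- is.na(reason)
  list(kept = records[keep, , drop = FALSE],
       removed = cbind(records[!keep, , drop = FALSE],
                       reason = reason[!keep]),
       flagged = records$record_id[!has_code])
}

#' Relocate near-shore sea points to the coastline
#'
#' Points in the sea (inside no country polygon) and within `buffer_arcmin`
#' of the coastline are moved to the nearest coastline point and then nudged
#' `nudge_arcmin` towards the country's centroid, so the relocated point
#' falls just inside the land rather than exactly on the boundary (land
#' masks, like the country tiles here, have cell-aligned coastlines, so an
#' on-boundary point would otherwise sit in a sea raster cell). Sea points
#' beyond the buffer and all land points are unchanged.
#'
#' @param records `presence_records`.
#' @param countries a `country_map`.
#' @param buffer_arcmin coastal buffer in arc-minutes (default 10).
#' @param nudge_arcmin inland nudge in arc-minutes (default 0.1, about 185 m).
#' @return list with `records` (possibly modified, `georef_status` set to
#'   `relocated_coast`) and `relocated` (ids with original coordinates and
#'   relocation distance in metres).
#' @export
relocate_coastal <- function(records, countries, buffer_arcmin = 10,
                             nudge_arcmin = 0.1) {
  moved <- data.frame(record_id = character(), orig_lat = numeric(),
                      orig_lon = numeric(), dist_m = numeric(),
                      stringsAsFactors = FALSE)
  at_sea <- is.na(country_at(countries, records$lon, records$lat))
  for (i in which(at_sea)) {
    p <- c(records$lon[i], records$lat[i])
    best <- NULL; best_d <- Inf; best_k <- NA
    for (k in seq_along(countries$codes)) {
      for (r in countries$polygons[[k]]) {
        r <- as.matrix(r)
        if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
        hit <- nearest_on_line(p, r)
        if (hit$dist_m < best_d) { best_d <- hit$dist_m; best <- hit$point; best_k <- k }
      }
    }
    if (best_d < 1 || best_d > buffer_arcmin * ARCMIN_M) next
    cen <- countries$centroids[best_k, ]
    dir <- cen - best
    len <- sqrt(sum(dir^2))
    if (len > 0) best <- best + dir / len * (nudge_arcmin / 60)
    moved <- rbind(moved, data.frame(record_id = records$record_id[i],
                                     orig_lat = records$lat[i],
                                     orig_lon = records$lon[i],
                                     dist_m = best_d, stringsAsFactors = FALSE))
    records$lon[i] <- best[[1]]; records$lat[i] <- best[[2]]
    records$georef_status[i] <- "relocated_coast"
  }
  list(records = records, relocated = moved)
}

#' Remove records at country centroids
#'
#' Coordinates equal (within `tol_arcmin`) to any country centroid are likely
#' georeferenced at country level and are removed.
#'
#' @param records `presence_records`.
#' @param countries a `country_map`.
#' @param tol_arcmin distance tolerance in arc-minutes (default 1).
#' @return list with `kept` and `removed`.
#' @export
drop_centroids <- function(records, countries, tol_arcmin = 1) {
  stopifnot(tol_arcmin >= 0)
  pts <- cbind(records$lon, records$lat)
  near <- rep(FALSE, nrow(records))
  for (k in seq_len(nrow(countries$centroids))) {
    d <- gc_dist(pts, countries$centroids[k, ])
    near <- near | (d <= tol_arcmin * ARCMIN_M)
  }
  list(kept = records[!near, , drop = FALSE],
       removed = cbind(records[near, , drop = FALSE],
                       reason = if (any(near)) "country centroid" else character(0)))
}

#' Remove exact coordinate duplicates within each taxon
#'
#' Coordinates are compared after rounding to `precision_decimals`; within a
#' taxon each rounded location keeps one survivor, the record with the
#' smallest `record_id` (stable).
#'
#' @param records `presence_records`.
#' @param precision_decimals rounding precision (default 4, about 11 m).
#' @return list with `kept` and `removed`.
#' @export
dedupe <- function(records, precision_decimals = 4) {
  stopifnot(precision_decimals >= 0)
  key <- paste(records$taxon_id,
               sprintf("%.*f", precision_decimals, records$lat),
               sprintf("%.*f", precision_decimals, records$lon))
  ord <- order(key, records$record_id)
  dup <- duplicated(key[ord])
  keep_idx <- sort(ord[!dup])
  drop_idx <- sort(ord[dup])
  list(kept = records[keep_idx, , drop = FALSE],
       removed = cbind(records[drop_idx, , drop = FALSE],
                       reason = if (length(drop_idx)) "duplicate coordinates" else character(0)))
}

#' Per-taxon climate fences (quartile +/- k x IQR)
#'
#' @param env numeric matrix of layer values (rows = records of one taxon).
#' @param k fence multiplier.
#' @return list with `lo` and `hi` vectors (one per layer).
#' @export
climate_fences <- function(env, k = 2.5) {
  q1 <- apply(env, 2, stats::quantile, 0.25, type = 7, na.rm = TRUE)
  q3 <- apply(env, 2, stats::quantile, 0.75, type = 7, na.rm = TRUE)
  iqr <- q3 - q1
  list(lo = q1 - k * iqr, hi = q3 + k * iqr)
}

#' Remove climate-outlier records
#'
#' For each taxon with at least `min_taxon_records` records on data cells,
#' per-layer quartile fences (Q1 - k x IQR, Q3 + k x IQR; type-7 quartiles)
#' are computed over that taxon's records; a record is removed iff at least
#' `min_vars` of the 19 layers fall outside its taxon's fences. Records on
#' nodata cells are removed with reason "no climate data". Taxa with fewer
#' than `min_taxon_records` records are exempt from the fence test.
#'
#' @param records `presence_records`.
#' @param stack a `climate_stack`.
#' @param k fence multiplier (default 2.5).
#' @param min_vars layers that must violate the fence (default 3).
#' @param min_taxon_records minimum records for quartiles (default 4).
#' @return list with `kept` and `removed`.
#' @export
filter_climate_outliers <- function(records, stack, k = 2.5, min_vars = 3,
                                    min_taxon_records = 4) {
  env <- stack_lookup(stack, records$lon, records$lat)
  nodata <- !stats::complete.cases(env)
  reason <- rep(NA_character_, nrow(records))
  reason[nodata] <- "no climate data"
  for (tx in unique(records$taxon_id)) {
    rows <- which(records$taxon_id == tx & !nodata)
    if (length(rows) < min_taxon_records) next
    f <- climate_fences(env[rows, , drop = FALSE], k)
    nv <- rowSums(sweep(env[rows, , drop = FALSE], 2, f$lo, "<") |
                  sweep(env[rows, , drop = FALSE], 2, f$hi, ">"))
    reason[rows[nv >= min_vars]] <- "climate outlier"
  }
  keep <- is.na(reason)
  list(kept = records[keep, , drop = FALSE],
       removed = cbind(records[!keep, , drop = FALSE], reason = reason[!keep]))
}

#' Run the full cleaning pipeline
#'
#' Steps in order: country-mismatch filter, coastal relocation, centroid
#' removal, per-taxon deduplication, climate-outlier filter. Relocation runs
#' after the country filter, whose buffer spares near-shore points, so valid
#' coastal records survive and are repaired rather than discarded. The
#' report's step counts satisfy
#' `n_in(step k+1) = n_in(step k) - n_removed(step k)`.
#'
#' @param records `presence_records`.
#' @param countries a `country_map`.
#' @param stack a `climate_stack`.
#' @param config list of parameters: `buffer_arcmin` (10), `centroid_tol_arcmin`
#'   (1), `dedupe_decimals` (4), `iqr_k` (2.5), `min_outlier_vars` (3).
#' @return list with `records` (cleaned) and `report` (a `cleaning_report`:
#'   `steps` data.frame with per-step counts, `detail` data.frame with one
#'   row per removed/modified record and its reason, `flagged_no_country`).
#' @export
clean_pipeline <- function(records, countries, stack, config = list()) {
  cfg <- utils::modifyList(list(buffer_arcmin = 10, centroid_tol_arcmin = 1,
                                dedupe_decimals = 4, iqr_k = 2.5,
                                min_outlier_vars = 3), config)
  steps <- data.frame(step = character(), n_in = integer(),
                      n_removed = integer(), n_modified = integer(),
                      n_out = integer(), stringsAsFactors = FALSE)
  detail <- data.frame(record_id = character(), step = character(),
                       action = character(), reason = character(),
                       stringsAsFactors = FALSE)
  log_step <- function(name, n_in, removed, modified = character(0)) {
    steps <<- rbind(steps, data.frame(
      step = name, n_in = n_in, n_removed = length(removed$record_id),
      n_modified = length(modified), n_out = n_in - length(removed$record_id),
      stringsAsFactors = FALSE))
    if (length(removed$record_id)) {
      detail <<- rbind(detail, data.frame(record_id = removed$record_id,
                                          step = name, action = "removed",
                                          reason = removed$reason,
                                          stringsAsFactors = FALSE))
    }
    if (length(modified)) {
      detail <<- rbind(detail, data.frame(record_id = modified, step = name,
                                          action = "modified",
                                          reason = "relocated to coastline",
                                          stringsAsFactors = FALSE))
    }
  }

  s1 <- filter_country_mismatch(records, countries, cfg$buffer_arcmin)
  log_step("country_mismatch", nrow(records), s1$removed)
  s2 <- relocate_coastal(s1$kept, countries, cfg$buffer_arcmin)
  log_step("coastal_relocation", nrow(s1$kept),
           list(record_id = character(0), reason = character(0)),
           s2$relocated$record_id)
  s3 <- drop_centroids(s2$records, countries, cfg$centroid_tol_arcmin)
  log_step("centroid_removal", nrow(s2$records), s3$removed)
  s4 <- dedupe(s3$kept, cfg$dedupe_decimals)
  log_step("dedupe", nrow(s3$kept), s4$removed)
  s5 <- filter_climate_outliers(s4$kept, stack, cfg$iqr_k, cfg$min_outlier_vars)
  log_step("climate_outliers", nrow(s4$kept), s5$removed)

  report <- structure(list(steps = steps, detail = detail,
                           flagged_no_country = s1$flagged),
                      class = "cleaning_report")
  out <- s5$kept
  rownames(out) <- NULL
  class(out) <- c("presence_records", "data.frame")
  list(records = out, report = report)
}
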