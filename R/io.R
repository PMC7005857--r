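# Readers and writers for occurrence tables, country polygons (GeoJSON) and
# the accession / screening / resistance fixture tables. Occurrence tables are
# CSV/TSV with a header; column names are remappable via `schema`.

PRESENCE_SOURCES <- c("herbarium", "genebank", "living_collection")
GEOREF_STATUS <- c("original", "manually_georeferenced", "relocated_coast")

default_schema <- function() {
  list(record_id = "record_id", taxon_id = "taxon_id", lat = "lat", lon = "lon",
       source = "source", country_code = "country_code",
       georef_status = "georef_status")
}

#' Construct a presence-record table
#'
#' The central occurrence container: one row per georeferenced record with its
#' provenance (herbarium, genebank or living collection) and passport country.
#'
#' @param record_id,taxon_id character vectors.
#' @param lat,lon WGS84 decimal degrees; longitudes are normalised to
#'   \[-180, 180\].
#' @param source one of `herbarium`, `genebank`, `living_collection`.
#' @param country_code ISO-3166 alpha-3 code or NA.
#' @param georef_status provenance of the coordinates.
#' @return data.frame of class `presence_records`.
#' @export
presence_records <- function(record_id, taxon_id, lat, lon, source,
                             country_code = NA_character_,
                             georef_status = "original") {
  lon <- ((lon + 180) %% 360) - 180
  df <- data.frame(record_id = as.character(record_id),
                   taxon_id = as.character(taxon_id),
                   lat = as.numeric(lat), lon = as.numeric(lon),
                   source = as.character(source),
                   country_code = as.character(country_code),
                   georef_status = as.character(georef_status),
                   stringsAsFactors = FALSE)
  bad <- validate_presence(df)
  if (length(bad)) stop("invalid presence records: ", paste(bad, collapse = "; "))
  class(df) <- c("presence_records", "data.frame")
  df
}

validate_presence <- function(df) {
  msgs <- character()
  if (any(!is.finite(df$lat) | df$lat < -90 | df$lat > 90)) msgs <- c(msgs, "lat out of range")
  if (any(!is.finite(df$lon) | df$lon < -180 | df$lon > 180)) msgs <- c(msgs, "lon out of range")
  if (any(is.na(df$taxon_id) | df$taxon_id == "")) msgs <- c(msgs, "empty taxon_id")
  if (any(!df$source %in% PRESENCE_SOURCES)) msgs <- c(msgs, "unknown source")
  msgs
}

#' Read an occurrence table
#'
#' Rows that fail coordinate parsing or violate record invariants are returned
#' in a `rejects` data.frame with a reason, never silently dropped.
#'
#' @param path CSV or TSV file (delimiter sniffed from the extension:
#'   `.tsv` means tab).
#' @param schema named list mapping the canonical field names
#'   (`taxon_id`, `lat`, `lon`, `source`, ...) to the file's column names;
#'   defaults to identity.
#' @return list with `records` (a `presence_records` data.frame) and
#'   `rejects` (row index, reason).
#' @export
read_presence_table <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("cannot read occurrence table: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = '"',
                           colClasses = "character", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  sch <- utils::modifyList(default_schema(), as.list(schema))
  for (fld in c("taxon_id", "lat", "lon", "source")) {
    if (!sch[[fld]] %in% names(raw)) {
      stop("required column '", sch[[fld]], "' (", fld, ") missing from ", path)
    }
  }
  get <- function(fld, default = NA_character_) {
    if (sch[[fld]] %in% names(raw)) raw[[sch[[fld]]]] else rep(default, nrow(raw))
  }
  df <- data.frame(record_id = get("record_id"), taxon_id = get("taxon_id"),
                   lat = suppressWarnings(as.numeric(get("lat"))),
                   lon = suppressWarnings(as.numeric(get("lon"))),
                   source = get("source"), country_code = get("country_code"),
                   georef_status = get("georef_status", "original"),
                   stringsAsFactors = FALSE)
  if (all(is.na(df$record_id))) df$record_id <- sprintf("r%06d", seq_len(nrow(df)))
  df$georef_status[is.na(df$georef_status)] <- "original"
  df$country_code[!is.na(df$country_code) & df$country_code == ""] <- NA_character_

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(reason) & (!is.finite(df$lat))] <- "lat not parseable"
  reason[is.na(reason) & (!is.finite(df$lon))] <- "lon not parseable"
  reason[is.na(reason) & (df$lat < -90 | df$lat > 90)] <- "lat out of range"
  df$lon <- ifelse(is.finite(df$lon), ((df$lon + 180) %% 360) - 180, df$lon)
  reason[is.na(reason) & (is.na(df$taxon_id) | df$taxon_id == "")] <- "empty taxon_id"
  reason[is.na(reason) & !df$source %in% PRESENCE_SOURCES] <- "unknown source"

  ok <- is.na(reason)
  rec <- df[ok, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("presence_records", "data.frame")
  rejects <- data.frame(row = which(!ok), record_id = df$record_id[!ok],
                        reason = reason[!ok], stringsAsFactors = FALSE)
  list(records = rec, rejects = rejects)
}

#' Write an occurrence table
#'
#' @param records a `presence_records` data.frame.
#' @param path output CSV path.
#' @export
write_presence_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

# ---- country polygons ---------------------------------------------------

#' Construct a country map
#'
#' @param codes character vector of country codes.
#' @param polygons list (per country) of lists of rings (two-column matrices).
#' @param centroids two-column matrix (lon, lat), one row per country.
#' @return a `country_map`: list with `codes`, `polygons`, `centroids`.
#' @export
country_map <- function(codes, polygons, centroids) {
  stopifnot(length(codes) == length(polygons), nrow(centroids) == length(codes))
  structure(list(codes = codes, polygons = polygons,
                 centroids = as.matrix(centroids)),
            class = "country_map")
}

#' Which country contains each point
#'
#' @param countries a `country_map`.
#' @param lon,lat coordinates.
#' @return character vector of country codes; NA for sea points.
#' @export
country_at <- function(countries, lon, lat) {
  out <- rep(NA_character_, length(lon))
  for (i in seq_along(countries$codes)) {
    hit <- is.na(out) & point_in_polygon(lon, lat, countries$polygons[[i]])
    out[hit] <- countries$codes[i]
  }
  out
}

#' Read country polygons and centroids from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features with
#' properties `code`, `centroid_lon`, `centroid_lat`.
#'
#' @param path GeoJSON file.
#' @return a `country_map`.
#' @export
read_countries <- function(path) {
  if (!file.exists(path)) stop("cannot read countries: ", path)
  gj <- jsonlite::read_json(path)
  codes <- character(); polys <- list(); cent <- NULL
  for (feat in gj$features) {
    code <- feat$properties$code
    geom <- feat$geometry
    ring_of <- function(coords) {
      do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    }
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_of),
      MultiPolygon = lapply(geom$coordinates, function(poly) ring_of(poly[[1]])),
      stop("unsupported geometry type: ", geom$type))
    codes <- c(codes, code)
    polys[[length(polys) + 1]] <- rings
    cent <- rbind(cent, c(feat$properties$centroid_lon,
                          feat$properties$centroid_lat))
  }
  country_map(codes, polys, cent)
}

#' Write a country map to GeoJSON
#'
#' @param countries a `country_map`.
#' @param path output file.
#' @export
write_countries <- function(countries, path) {
  feats <- lapply(seq_along(countries$codes), function(i) {
    rings <- countries$polygons[[i]]
    coords <- lapply(rings, function(r) {
      r <- as.matrix(r)
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature",
         properties = list(code = countries$codes[i],
                           centroid_lon = countries$centroids[i, 1],
                           centroid_lat = countries$centroids[i, 2]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- fixture tables -----------------------------------------------------

#' Read a genebank accession table
#'
#' Columns: `taxon_id`, `holding_institute`, `n_accessions`,
#' `safety_duplicated`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_accession_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "holding_institute", "n_accessions", "safety_duplicated")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("accession table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$n_accessions < 0)) stop("negative accession count")
  if (any(df$safety_duplicated > df$n_accessions)) {
    stop("safety_duplicated exceeds n_accessions")
  }
  df
}

#' Read a screening-score table
#'
#' Columns: `taxon_id`, `accession_id`, `assay` (dehydration|salinity),
#' `score` (Likert 1-5; 1 = high tolerance).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_screening_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "accession_id", "assay", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("screening table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$score %in% 1:5)) stop("screening score outside 1-5 Likert scale")
  if (!all(df$assay %in% c("dehydration", "salinity"))) stop("unknown assay")
  df
}

#' Read a biotic-resistance review table
#'
#' Columns: `taxon_id`, `stressor`, `status`
#' (resistant_reported | no_resistance_reported | not_evaluated);
#' one row per taxon x stressor.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_resistance_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "stressor", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("resistance table missing columns: ", paste(miss, collapse = ", "))
  ok <- c("resistant_reported", "no_resistance_reported", "not_evaluated")
  if (!all(df$status %in% ok)) stop("unknown resistance status")
  if (anyDuplicated(df[c("taxon_id", "stressor")])) {
    stop("duplicate taxon x stressor rows")
  }
  df
}

#' Read a taxonomy table
#'
#' Columns: `taxon_id`, `name`, `subgenus`, `section`, `gene_pool` (A-D),
#' `domesticated` (logical).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_taxonomy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "name", "subgenus", "section", "gene_pool", "domesticated")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxonomy missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$gene_pool %in% c("A", "B", "C", "D"))) stop("gene_pool must be A-D")
  df$domesticated <- as.logical(df$domesticated)
  df
}
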