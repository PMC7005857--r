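# Ex situ conservation status and the geographic gap analysis: per-taxon
# accession categories (absent / fewer than 10 / at least 10), sampled and
# unconserved taxonomic-richness rasters, modelled-but-unreported gap
# richness, and zonal priority-country rankings.

#' Categorise the ex situ conservation status of each taxon
#'
#' Accessions are summed over holding institutes; categories follow the
#' genebank thresholds: 0 = absent, 1-9 = poor, >= 10 = adequate. Taxa in the
#' taxonomy but missing from the accession table are absent.
#'
#' @param accessions accession data.frame (`taxon_id`, `n_accessions`,
#'   `safety_duplicated`).
#' @param taxonomy taxonomy data.frame (`taxon_id`), fixing the taxon set.
#' @return data.frame: `taxon_id`, `total_accessions`, `safety_duplicated`,
#'   `category`.
#' @export
exsitu_status <- function(accessions, taxonomy) {
  if (any(accessions$n_accessions < 0)) stop("negative accession count")
  tot <- tapply(accessions$n_accessions, accessions$taxon_id, sum)
  saf <- tapply(accessions$safety_duplicated, accessions$taxon_id, sum)
  taxa <- taxonomy$taxon_id
  m <- match(taxa, names(tot))
  total <- ifelse(is.na(m), 0L, as.integer(tot[m]))
  out <- data.frame(
    taxon_id = taxa, total_accessions = total,
    safety_duplicated = ifelse(is.na(m), 0L, as.integer(saf[m])),
    category = ifelse(total == 0, "absent",
                      ifelse(total < 10, "poor", "adequate")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sampled taxonomic richness raster
#'
#' Per cell, the number of distinct taxa with at least one record (of the
#' filtered sources) in the cell.
#'
#' @param records `presence_records`.
#' @param grid a [grid_def()] defining the counting grid.
#' @param source_filter optional subset of
#'   `c("herbarium", "genebank", "living_collection")`.
#' @param taxon_filter optional subset of taxon ids.
#' @return a `grid_raster` of integer counts.
#' @export
sampled_richness <- function(records, grid, source_filter = NULL,
                             taxon_filter = NULL) {
  if (!is.null(source_filter)) {
    records <- records[records$source %in% source_filter, , drop = FALSE]
  }
  if (!is.null(taxon_filter)) {
    records <- records[records$taxon_id %in% taxon_filter, , drop = FALSE]
  }
  vals <- matrix(0, grid$nrow, grid$ncol)
  if (nrow(records)) {
    ix <- cell_index(grid, records$lon, records$lat)
    ok <- !is.na(ix$cell)
    counts <- tapply(records$taxon_id[ok], ix$cell[ok],
                     function(t) length(unique(t)))
    vals[as.integer(names(counts))] <- as.integer(counts)
  }
  grid_raster(grid, vals)
}

#' Richness of taxa not adequately conserved ex situ
#'
#' Sampled richness restricted to taxa whose ex situ category is `absent` or
#' `poor`.
#'
#' @param records `presence_records`.
#' @param status output of [exsitu_status()].
#' @param grid counting grid.
#' @param source_filter optional source subset.
#' @return a `grid_raster`.
#' @export
unconserved_richness <- function(records, status, grid, source_filter = NULL) {
  bad <- status$taxon_id[status$category %in% c("absent", "poor")]
  sampled_richness(records, grid, source_filter, taxon_filter = bad)
}

#' Modelled-but-unreported gap richness
#'
#' Per cell, the number of taxa whose binary suitability is 1 and which have
#' zero reported records (any source) in the cell.
#'
#' @param binary_maps named list (by taxon) of binary `grid_raster`s.
#' @param records `presence_records` (all sources).
#' @param grid counting grid (must match the maps).
#' @return a `grid_raster`.
#' @export
modelled_gap <- function(binary_maps, records, grid) {
  vals <- matrix(0, grid$nrow, grid$ncol)
  for (tx in names(binary_maps)) {
    bm <- binary_maps[[tx]]
    if (!grid_equal(bm$grid, grid)) stop("grid mismatch in binary map for ", tx)
    suitable <- !is.na(bm$values) & bm$values >= 1
    rec <- records[records$taxon_id == tx, , drop = FALSE]
    if (nrow(rec)) {
      ix <- cell_index(grid, rec$lon, rec$lat)
      ok <- !is.na(ix$cell)
      suitable[cbind(ix$row[ok], ix$col[ok])] <- FALSE
    }
    vals <- vals + suitable
  }
  grid_raster(grid, vals)
}

#' Rank countries by zonal gap richness
#'
#' Countries are scored by aggregating the gap raster over cells whose
#' centres fall inside the country polygon (zonal sum by default; mean and
#' max also available) and ranked in decreasing score, ties broken
#' alphabetically by code.
#'
#' @param gap_raster a `grid_raster`.
#' @param countries a `country_map`.
#' @param top_k number of countries to return (default: all).
#' @param stat "sum" (default), "mean" or "max".
#' @return data.frame: `country_code`, `score`, `rank`.
#' @export
priority_countries <- function(gap_raster, countries, top_k = NULL,
                               stat = c("sum", "mean", "max")) {
  stat <- match.arg(stat)
  g <- gap_raster$grid
  idx <- expand.grid(row = seq_len(g$nrow), col = seq_len(g$ncol))
  ctr <- cell_centre(g, idx$row, idx$col)
  code <- country_at(countries, ctr$lon, ctr$lat)
  v <- gap_raster$values[cbind(idx$row, idx$col)]
  keep <- !is.na(code) & !is.na(v)
  f <- switch(stat, sum = sum, mean = mean, max = max)
  sc <- tapply(v[keep], code[keep], f)
  all_sc <- stats::setNames(rep(0, length(countries$codes)), countries$codes)
  all_sc[names(sc)] <- sc
  out <- data.frame(country_code = names(all_sc), score = as.numeric(all_sc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$country_code), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  out
}
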