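# Shared synthetic fixtures, built once per test session.

.world_cache <- new.env(parent = emptyenv())

# default study world: 100 x 100 grid, 6 countries, 10 taxa, ~1000 records
get_world <- function(seed = 42) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- suppressWarnings(simulate_world(world_spec(seed = seed)))
  }
  .world_cache[[key]]
}

# small fast world: 50 x 50 grid, 4 countries, 4 taxa
get_small_world <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.world_cache[[key]])) {
    spec <- world_spec(seed = seed, res_arcmin = 24, n_countries = 4,
                       n_taxa = 4, records_per_taxon = 60)
    .world_cache[[key]] <- suppressWarnings(simulate_world(spec))
  }
  .world_cache[[key]]
}

# a tiny climate stack with uncorrelated random layers on an all-land grid
random_stack <- function(nrow = 10, ncol = 10, seed = 1, res_arcmin = 60) {
  set.seed(seed)
  g <- grid_def(nrow, ncol, 0, 0, res_arcmin)
  layers <- lapply(stats::setNames(BIOCLIM_NAMES, BIOCLIM_NAMES), function(nm) {
    matrix(stats::rnorm(nrow * ncol, 20, 5), nrow, ncol)
  })
  climate_stack(g, layers)
}

# a stack whose BIO1 encodes per-cell values we control, on an all-land
# grid; records placed one per cell (for planted ANOVA/HSD cases)
planted_variable_world <- function(values_by_taxon, seed = 1) {
  n_per <- lengths(values_by_taxon)
  total <- sum(n_per)
  side <- ceiling(sqrt(total))
  st <- random_stack(side, side, seed = seed)
  cells <- seq_len(total)
  row <- (cells - 1) %% side + 1; col <- (cells - 1) %/% side + 1
  vals <- unlist(values_by_taxon)
  for (i in cells) st$layers$BIO1[row[i], col[i]] <- vals[i]
  ctr <- cell_centre(st$grid, row, col)
  recs <- recs_at(ctr$lon, ctr$lat,
                  taxon = rep(names(values_by_taxon), n_per),
                  id = sprintf("p%04d", cells))
  list(stack = st, records = recs)
}

# presence records at given coordinates with defaults filled in
recs_at <- function(lon, lat, taxon = "tA", source = "herbarium",
                    country = NA_character_, id = NULL) {
  n <- length(lon)
  presence_records(
    record_id = if (is.null(id)) sprintf("x%03d", seq_len(n)) else id,
    taxon_id = rep_len(taxon, n), lat = lat, lon = lon,
    source = rep_len(source, n), country_code = rep_len(country, n))
}
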