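# Synthetic study system with known ground truth. The generator emulates the
# six input classes the pipeline consumes: a 19-layer bioclim stack with
# smooth gradients and a planted correlation structure, rectangular country
# tiles with a surrounding sea, niche-structured presence records, genebank
# accession counts, Likert screening scores, and a biotic-resistance review
# table. Injected record errors are tracked in a ledger so cleaning recall is
# measurable exactly.

# Deterministic sub-seed per generator stage, derived from the one global
# seed; kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}

#' Specification of a synthetic study world
#'
#' Defaults define a 20 x 20 degree tropical extent at 12 arc-minutes
#' (a 100 x 100 grid), six countries, ten taxa with Gaussian niches in
#' (BIO1, BIO12) space, and low error rates typical of curated occurrence
#' datasets.
#'
#' @param seed global integer seed; all stage seeds derive from it.
#' @param xmin,xmax,ymin,ymax extent in decimal degrees.
#' @param res_arcmin grid resolution in arc-minutes.
#' @param n_countries number of rectangular country tiles.
#' @param n_taxa number of taxa (ignored when `niches` is given).
#' @param records_per_taxon presences sampled per taxon.
#' @param niches optional data.frame with columns `taxon_id`, `bio1_c`,
#'   `bio12_c`, `bio1_sd`, `bio12_sd` (niche centre and breadth);
#'   defaults from [default_niches()].
#' @param layer_cor named vector of target Pearson correlations of the 17
#'   distractor layers with their parent gradient (temperature layers with
#'   BIO1, precipitation layers with BIO12).
#' @param noise_bio1,noise_bio12 sd of the seeded noise added to the two
#'   gradient layers (deg C, mm).
#' @param error_rates named list with elements `country_mismatch`, `offshore`,
#'   `centroid`, `duplicate`, `climate_outlier`, each in \[0, 1\].
#' @return a `world_spec` list.
#' @export
world_spec <- function(seed = 1L,
                       xmin = 0, xmax = 20, ymin = 0, ymax = 20,
                       res_arcmin = 12,
                       n_countries = 6, n_taxa = 10,
                       records_per_taxon = 100,
                       niches = NULL,
                       layer_cor = default_layer_cor(),
                       noise_bio1 = 0.5, noise_bio12 = 60,
                       error_rates = list(country_mismatch = 0.02,
                                          offshore = 0.02, centroid = 0.02,
                                          duplicate = 0.05,
                                          climate_outlier = 0.02)) {
  stopifnot(res_arcmin > 0, n_countries >= 1, n_taxa >= 1)
  rates <- unlist(error_rates)
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  spec <- list(seed = as.integer(seed), xmin = xmin, xmax = xmax,
               ymin = ymin, ymax = ymax, res_arcmin = res_arcmin,
               n_countries = n_countries, n_taxa = n_taxa,
               records_per_taxon = records_per_taxon,
               layer_cor = layer_cor,
               noise_bio1 = noise_bio1, noise_bio12 = noise_bio12,
               error_rates = error_rates)
  spec$niches <- if (is.null(niches)) default_niches(spec) else niches
  spec$n_taxa <- nrow(spec$niches)
  class(spec) <- "world_spec"
  spec
}

#' Default distractor-layer correlation targets
#'
#' Temperature layers (BIO2-BIO11) correlate with the BIO1 gradient,
#' precipitation layers (BIO13-BIO19) with BIO12, at magnitudes loosely
#' echoing real bioclim collinearity (e.g. warmest-quarter temperature is
#' nearly collinear with annual mean temperature).
#'
#' @return named numeric vector of length 17.
#' @export
default_layer_cor <- function() {
  c(BIO2 = 0.30, BIO3 = 0.40, BIO4 = -0.50, BIO5 = 0.90, BIO6 = 0.85,
    BIO7 = -0.45, BIO8 = 0.80, BIO9 = 0.60, BIO10 = 0.95, BIO11 = 0.90,
    BIO13 = 0.90, BIO14 = 0.50, BIO15 = -0.35, BIO16 = 0.95, BIO17 = 0.55,
    BIO18 = 0.70, BIO19 = 0.60)
}

#' Default taxon niches
#'
#' Niche centres spread along the BIO1 (annual mean temperature) axis, with
#' BIO12 (annual precipitation) centres assigned by a fixed rotation so the
#' hottest and driest specialists are different taxa. Breadths are moderate
#' (1.5 deg C, 150 mm) so niches overlap but remain separable.
#'
#' @param spec a partial `world_spec` (needs `n_taxa`).
#' @return data.frame of niche parameters plus planted screening classes.
#' @export
default_niches <- function(spec) {
  n <- spec$n_taxa
  bio1 <- if (n == 1) 24 else seq(17, 28, length.out = n)
  p12 <- if (n == 1) 1700 else seq(2300, 1250, length.out = n)
  rot <- ((seq_len(n) + floor(n / 2) - 1) %% n) + 1
  niches <- data.frame(
    taxon_id = sprintf("Taxon_%02d", seq_len(n)),
    bio1_c = bio1, bio12_c = p12[rot],
    bio1_sd = 1.5, bio12_sd = 150,
    stringsAsFactors = FALSE)
  # planted pot-experiment tolerance: hottest fifth tolerate dehydration,
  # driest fifth tolerate salinity; one taxon in three never screened
  n_top <- max(1, floor(n / 5))
  hot <- rank(-niches$bio1_c, ties.method = "first") <= n_top
  dry <- rank(niches$bio12_c, ties.method = "first") <= n_top
  unscreened <- seq_len(n) %% 3 == 0
  cls <- function(top) ifelse(top, "high", ifelse(seq_len(n) %% 2 == 0,
                                                  "intermediate", "low"))
  niches$dehydration_class <- ifelse(unscreened, "none", cls(hot))
  niches$salinity_class <- ifelse(unscreened, "none", cls(dry))
  niches
}

#' Generate the synthetic country tiles
#'
#' Rectangular, non-overlapping tiles covering part of the extent; the
#' remainder (an eastern strip plus margins) is sea. Centroids are exact tile
#' centres.
#'
#' @param spec a `world_spec`.
#' @return a `country_map`.
#' @export
make_countries <- function(spec) {
  w <- spec$xmax - spec$xmin; h <- spec$ymax - spec$ymin
  x0 <- spec$xmin + 0.05 * w; x1 <- spec$xmin + 0.70 * w
  y0 <- spec$ymin + 0.05 * h; y1 <- spec$ymin + 0.95 * h
  n <- spec$n_countries
  # exact factorisation so the tiles fill the land block without sea holes
  # (coastlines then coincide with the block's cell-aligned boundary)
  divs <- which(n %% seq_len(floor(sqrt(n))) == 0)
  ncol_t <- max(divs); nrow_t <- n / ncol_t
  tw <- (x1 - x0) / ncol_t; th <- (y1 - y0) / nrow_t
  res_deg <- spec$res_arcmin / 60
  if (tw < 4 * res_deg || th < 4 * res_deg) {
    stop("extent too small for ", n, " countries at this resolution")
  }
  codes <- character(n); polys <- vector("list", n); cent <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol_t; cc <- (i - 1) %% ncol_t
    xa <- x0 + cc * tw; ya <- y0 + r * th
    ring <- cbind(c(xa, xa + tw, xa + tw, xa, xa),
                  c(ya, ya, ya + th, ya + th, ya))
    codes[i] <- sprintf("C%02d", i)
    polys[[i]] <- list(ring)
    cent[i, ] <- c(xa + tw / 2, ya + th / 2)
  }
  country_map(codes, polys, cent)
}

#' Generate the 19-layer synthetic climate stack
#'
#' BIO1 (deg C) decreases with absolute latitude, BIO12 (mm) increases to the
#' west; the 17 remaining layers are seeded linear mixtures of the
#' standardised parent gradient and iid noise that hit the requested Pearson
#' correlations. Sea cells (outside every country tile) are nodata in all
#' layers. Deterministic given `spec$seed`.
#'
#' @param spec a `world_spec`.
#' @param noise optionally override both noise sds (0 gives the noise-free
#'   limit where BIO1 is strictly monotone in absolute latitude).
#' @return a `climate_stack`.
#' @export
make_climate_stack <- function(spec, noise = NULL) {
  bad <- abs(spec$layer_cor) > 1
  if (any(bad)) {
    stop("correlation target not achievable (non-positive-definite) for: ",
         paste(names(spec$layer_cor)[bad], collapse = ", "))
  }
  if (!is.null(noise)) spec$noise_bio1 <- spec$noise_bio12 <- noise
  res_deg <- spec$res_arcmin / 60
  nr <- round((spec$ymax - spec$ymin) / res_deg)
  nc <- round((spec$xmax - spec$xmin) / res_deg)
  g <- grid_def(nr, nc, spec$xmin, spec$ymin, spec$res_arcmin)
  lat <- spec$ymin + (nr - seq_len(nr) + 0.5) * res_deg       # row 1 = north
  lon <- spec$xmin + (seq_len(nc) - 0.5) * res_deg
  latm <- matrix(lat, nr, nc)
  lonm <- matrix(lon, nr, nc, byrow = TRUE)

  set.seed(sub_seed(spec$seed, 1L))
  bio1 <- 30 - 0.75 * abs(latm) + matrix(stats::rnorm(nr * nc, 0, spec$noise_bio1), nr, nc)
  bio12 <- 500 + 100 * (spec$xmax - lonm) / (spec$xmax - spec$xmin) * 20 +
    matrix(stats::rnorm(nr * nc, 0, spec$noise_bio12), nr, nc)

  # land mask first: parents are standardised over land cells so the
  # requested correlations hold on the cells the pipeline actually sees
  countries <- make_countries(spec)
  landm <- matrix(!is.na(country_at(countries, as.vector(lonm),
                                    as.vector(latm))), nr, nc)
  zstd <- function(m) (m - mean(m[landm])) / stats::sd(m[landm])
  z1 <- zstd(bio1); z12 <- zstd(bio12)
  mix <- function(parent_z, r, mu, sigma) {
    eps <- matrix(stats::rnorm(nr * nc), nr, nc)
    mu + sigma * (r * parent_z + sqrt(1 - r^2) * eps)
  }
  temp_mu <- c(BIO2 = 12, BIO3 = 50, BIO4 = 300, BIO5 = 33, BIO6 = 12,
               BIO7 = 20, BIO8 = 24, BIO9 = 22, BIO10 = 28, BIO11 = 18)
  temp_sd <- c(BIO2 = 2, BIO3 = 8, BIO4 = 80, BIO5 = 3, BIO6 = 3,
               BIO7 = 4, BIO8 = 3, BIO9 = 3, BIO10 = 3, BIO11 = 3)
  prec_mu <- c(BIO13 = 250, BIO14 = 20, BIO15 = 60, BIO16 = 600,
               BIO17 = 90, BIO18 = 400, BIO19 = 200)
  prec_sd <- c(BIO13 = 60, BIO14 = 8, BIO15 = 15, BIO16 = 140,
               BIO17 = 30, BIO18 = 110, BIO19 = 60)
  layers <- list(BIO1 = bio1, BIO12 = bio12)
  for (nm in names(temp_mu)) {
    layers[[nm]] <- mix(z1, spec$layer_cor[[nm]], temp_mu[[nm]], temp_sd[[nm]])
  }
  for (nm in names(prec_mu)) {
    layers[[nm]] <- mix(z12, spec$layer_cor[[nm]], prec_mu[[nm]], prec_sd[[nm]])
  }

  for (nm in names(layers)) layers[[nm]][!landm] <- NA_real_
  climate_stack(g, layers[BIOCLIM_NAMES])
}

#' Sample niche-structured presence records for one taxon
#'
#' Land cells are drawn with probability proportional to
#' exp(-Mahalanobis^2 / 2) of the cell's (BIO1, BIO12) values to the taxon's
#' niche centre (diagonal covariance from the niche breadths); points are
#' jittered uniformly within their cell. Deterministic given `seed`.
#'
#' @param spec a `world_spec`.
#' @param stack the world's `climate_stack`.
#' @param countries the world's `country_map`.
#' @param taxon_id taxon to sample (must appear in `spec$niches`).
#' @param n number of records.
#' @param seed integer seed.
#' @return a `presence_records` data.frame.
#' @export
sample_presences <- function(spec, stack, countries, taxon_id, n,
                             seed = spec$seed) {
  stopifnot(n >= 1)
  ni <- spec$niches[spec$niches$taxon_id == taxon_id, ]
  if (nrow(ni) != 1) stop("taxon has no niche definition: ", taxon_id)
  b1 <- as.vector(stack$layers$BIO1); b12 <- as.vector(stack$layers$BIO12)
  land <- which(!is.na(b1))
  d2 <- ((b1[land] - ni$bio1_c) / ni$bio1_sd)^2 +
    ((b12[land] - ni$bio12_c) / ni$bio12_sd)^2
  w <- exp(-0.5 * (d2 - min(d2)))   # shift for numerical stability
  if (!any(w > 0)) stop("no land cell with positive probability for ", taxon_id)
  g <- stack$grid
  set.seed(seed)
  cells <- sample(land, n, replace = TRUE, prob = w)
  row <- (cells - 1) %% g$nrow + 1
  col <- (cells - 1) %/% g$nrow + 1
  ctr <- cell_centre(g, row, col)
  lon <- ctr$lon + (stats::runif(n) - 0.5) * g$res * 0.9
  lat <- ctr$lat + (stats::runif(n) - 0.5) * g$res * 0.9
  src <- sample(PRESENCE_SOURCES, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  presence_records(
    record_id = sprintf("%s_r%05d", taxon_id, seq_len(n)),
    taxon_id = taxon_id, lat = lat, lon = lon, source = src,
    country_code = country_at(countries, lon, lat))
}

# find a sea point at roughly `offset_arcmin` from the boundary of the
# record's own country; returns c(lon, lat) or NULL
.sea_point_near <- function(countries, code, offset_arcmin, band_lo, band_hi,
                            max_try = 200) {
  i <- match(code, countries$codes)
  ring <- countries$polygons[[i]][[1]]
  nseg <- nrow(ring) - 1
  for (try in seq_len(max_try)) {
    s <- sample.int(nseg, 1)
    t <- stats::runif(1)
    a <- ring[s, ]; b <- ring[s + 1, ]
    pt <- a + t * (b - a)
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len <- sqrt(dx^2 + dy^2); if (len == 0) next
    nvec <- c(-dy, dx) / len
    off <- offset_arcmin / 60
    for (sgn in c(1, -1)) {
      cand <- pt + sgn * off * nvec
      if (!is.na(country_at(countries, cand[1], cand[2]))) next
      dmin <- min(vapply(seq_along(countries$codes), function(k) {
        dist_to_polygon(cand[1], cand[2], countries$polygons[[k]])
      }, numeric(1)))
      if (dmin >= band_lo * ARCMIN_M && dmin <= band_hi * ARCMIN_M) return(cand)
    }
  }
  NULL
}

#' Inject ledgered errors into presence records
#'
#' For each error type, `floor(rate * n)` records are modified (disjoint
#' subsets): `country_mismatch` swaps the passport country for a distant one;
#' `offshore` moves the point into the sea (half within 10 arc-minutes of the
#' coast, half well beyond); `centroid` snaps the point to its country
#' centroid; `duplicate` appends an exact coordinate copy; `climate_outlier`
#' moves the point to a land cell whose climate violates the taxon's
#' 2.5 x IQR fences on at least `min_vars` layers (selected with a stricter
#' internal fence so the violation survives the injection itself). Every
#' change is recorded in the ledger.
#'
#' @param records clean `presence_records`.
#' @param spec the `world_spec` (error rates, grid).
#' @param countries the `country_map`.
#' @param stack the `climate_stack`.
#' @param seed integer seed.
#' @param min_vars layers a planted outlier must violate (default 3).
#' @return list with `records` (modified table) and `ledger` (data.frame:
#'   `record_id`, `error_type`, `orig_lat`, `orig_lon`, `orig_country`).
#' @export
inject_errors <- function(records, spec, countries, stack,
                          seed = spec$seed, min_vars = 3) {
  rates <- spec$error_rates
  n <- nrow(records)
  counts <- lapply(rates, function(r) floor(r * n))
  for (nm in names(rates)) {
    if (rates[[nm]] > 0 && counts[[nm]] == 0) {
      warning("rate ", nm, " = ", rates[[nm]], " yields zero injections at n = ", n)
    }
  }
  set.seed(sub_seed(seed, 7L))
  total_mod <- sum(unlist(counts))
  if (total_mod > n) stop("error rates too high: would modify more records than exist")
  picks <- sample.int(n, total_mod)
  split_idx <- split(picks, rep(names(counts), unlist(counts)))
  ledger <- data.frame(record_id = character(), error_type = character(),
                       orig_lat = numeric(), orig_lon = numeric(),
                       orig_country = character(), stringsAsFactors = FALSE)
  log_row <- function(id, type, lat, lon, ctry) {
    ledger <<- rbind(ledger, data.frame(record_id = id, error_type = type,
                                        orig_lat = lat, orig_lon = lon,
                                        orig_country = ctry,
                                        stringsAsFactors = FALSE))
  }

  # country mismatch: assign the most distant country's code
  for (i in split_idx$country_mismatch) {
    d <- vapply(seq_along(countries$codes), function(k) {
      dist_to_polygon(records$lon[i], records$lat[i], countries$polygons[[k]])
    }, numeric(1))
    k <- which.max(d)
    if (d[k] <= 10 * ARCMIN_M) next  # cannot place a convincing mismatch
    log_row(records$record_id[i], "country_mismatch",
            records$lat[i], records$lon[i], records$country_code[i])
    records$country_code[i] <- countries$codes[k]
  }

  # offshore: half within the 10-arcmin coastal buffer, half beyond
  off <- split_idx$offshore
  if (length(off)) {
    n_in <- ceiling(length(off) / 2)
    for (j in seq_along(off)) {
      i <- off[j]
      within <- j <= n_in
      cand <- if (within) {
        .sea_point_near(countries, records$country_code[i], 5, 1, 9)
      } else {
        .sea_point_near(countries, records$country_code[i], 40, 15, 120)
      }
      if (is.null(cand)) next
      log_row(records$record_id[i],
              if (within) "offshore_within" else "offshore_beyond",
              records$lat[i], records$lon[i], records$country_code[i])
      records$lon[i] <- cand[1]; records$lat[i] <- cand[2]
    }
  }

  # centroid: snap to own country's centroid
  for (i in split_idx$centroid) {
    k <- match(records$country_code[i], countries$codes)
    if (is.na(k)) next
    log_row(records$record_id[i], "centroid",
            records$lat[i], records$lon[i], records$country_code[i])
    records$lon[i] <- countries$centroids[k, 1]
    records$lat[i] <- countries$centroids[k, 2]
  }

  # climate outlier: move to a land cell violating strict fences on >= min_vars
  # layers for the taxon; avoid cells hosting a centroid
  out_idx <- split_idx$climate_outlier
  no_outlier_cell <- character(0)
  if (length(out_idx)) {
    env_all <- stack_lookup(stack, records$lon, records$lat)
    g <- stack$grid
    cent_cells <- cell_index(g, countries$centroids[, 1],
                             countries$centroids[, 2])$cell
    for (i in out_idx) {
      tx <- records$taxon_id[i]
      rows <- which(records$taxon_id == tx)
      env <- env_all[rows, , drop = FALSE]
      env <- env[stats::complete.cases(env), , drop = FALSE]
      if (nrow(env) < 4) next
      q1 <- apply(env, 2, stats::quantile, 0.25, type = 7)
      q3 <- apply(env, 2, stats::quantile, 0.75, type = 7)
      iqr <- q3 - q1
      lo <- q1 - 4 * iqr; hi <- q3 + 4 * iqr   # stricter than the 2.5 filter
      nviol <- rep(0L, g$nrow * g$ncol)
      for (v in seq_along(BIOCLIM_NAMES)) {
        lv <- as.vector(stack$layers[[BIOCLIM_NAMES[v]]])
        nviol <- nviol + (!is.na(lv) & (lv < lo[v] | lv > hi[v]))
      }
      cand <- which(nviol >= min_vars)
      cand <- setdiff(cand, cent_cells)
      if (!length(cand)) {
        no_outlier_cell <- c(no_outlier_cell, tx)
        next
      }
      cell <- if (length(cand) == 1) cand else sample(cand, 1)
      row <- (cell - 1) %% g$nrow + 1; col <- (cell - 1) %/% g$nrow + 1
      ctr <- cell_centre(g, row, col)
      nlon <- ctr$lon + (stats::runif(1) - 0.5) * g$res * 0.5
      nlat <- ctr$lat + (stats::runif(1) - 0.5) * g$res * 0.5
      log_row(records$record_id[i], "climate_outlier",
              records$lat[i], records$lon[i], records$country_code[i])
      records$lon[i] <- nlon; records$lat[i] <- nlat
      records$country_code[i] <- country_at(countries, nlon, nlat)
    }
  }

  if (length(no_outlier_cell)) {
    warning("no planted-outlier cell available for broad-niche taxa: ",
            paste(unique(no_outlier_cell), collapse = ", "),
            " (fewer climate outliers injected than requested)")
  }

  # duplicates: exact coordinate copies of untouched records, appended with a
  # record_id that sorts after the original (so dedupe removes the copy)
  dup_idx <- split_idx$duplicate
  if (length(dup_idx)) {
    dups <- records[dup_idx, , drop = FALSE]
    dups$record_id <- paste0(dups$record_id, "_dup")
    for (j in seq_len(nrow(dups))) {
      log_row(dups$record_id[j], "duplicate", dups$lat[j], dups$lon[j],
              dups$country_code[j])
    }
    records <- rbind(records, dups)
  }
  rownames(records) <- NULL
  class(records) <- c("presence_records", "data.frame")
  list(records = records, ledger = ledger)
}

#' Generate a synthetic taxonomy
#'
#' Taxa are assigned round-robin to sections nested in the four gene pools;
#' the first taxon of each gene pool is flagged domesticated.
#'
#' @param spec a `world_spec`.
#' @return data.frame (`taxon_id`, `name`, `subgenus`, `section`,
#'   `gene_pool`, `domesticated`).
#' @export
make_taxonomy <- function(spec) {
  n <- spec$n_taxa
  pools <- c("A", "B", "C", "D")
  sub_of <- c(A = "Ceratotropis", B = "Plectotropis", C = "Vigna", D = "Vigna")
  gp <- pools[(seq_len(n) - 1) %% 4 + 1]
  sec_in_pool <- ((seq_len(n) - 1) %/% 4) %% 2 + 1
  section <- sprintf("sect_%s%d", gp, sec_in_pool)
  data.frame(taxon_id = spec$niches$taxon_id,
             name = paste("Vigna", tolower(spec$niches$taxon_id)),
             subgenus = unname(sub_of[gp]), section = section, gene_pool = gp,
             domesticated = !duplicated(gp),
             stringsAsFactors = FALSE)
}

#' Generate synthetic genebank accession counts
#'
#' Roughly a quarter of taxa are planted as poorly conserved: about 7% absent
#' from all genebanks and 18% with fewer than 10 accessions; the rest hold
#' 10-500 accessions over one to three institutes.
#'
#' @param spec a `world_spec`.
#' @param seed integer seed.
#' @return list with `table` (accession data.frame) and `truth`
#'   (planted per-taxon category).
#' @export
make_accessions <- function(spec, seed = spec$seed) {
  set.seed(sub_seed(seed, 11L))
  taxa <- spec$niches$taxon_id
  n <- length(taxa)
  n_absent <- max(1, round(0.07 * n))
  n_poor <- max(1, round(0.18 * n))
  cat_v <- rep("adequate", n)
  ord <- sample.int(n)
  cat_v[ord[seq_len(n_absent)]] <- "absent"
  cat_v[ord[n_absent + seq_len(n_poor)]] <- "poor"
  rows <- list()
  for (i in seq_len(n)) {
    if (cat_v[i] == "absent") next
    total <- if (cat_v[i] == "poor") sample(1:9, 1) else sample(10:500, 1)
    k <- sample(1:3, 1)
    split <- if (k == 1) total else {
      cuts <- sort(sample(seq_len(max(total - 1, 1)), min(k - 1, total - 1)))
      diff(c(0, cuts, total))
    }
    split <- split[split > 0]
    for (j in seq_along(split)) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = taxa[i], holding_institute = sprintf("INST%02d", j),
        n_accessions = split[j],
        safety_duplicated = sample(0:split[j], 1),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows),
       truth = data.frame(taxon_id = taxa, category = cat_v,
                          stringsAsFactors = FALSE))
}

#' Generate synthetic Likert screening scores
#'
#' Per screened taxon and assay, a handful of accessions score on the 1-5
#' scale (1 = high tolerance); the planted class in `spec$niches` fixes the
#' best score (high -> 1, intermediate -> 2, low -> 3-5). Taxa with class
#' `none` are unscreened.
#'
#' @param spec a `world_spec`.
#' @param seed integer seed.
#' @param n_accessions accessions scored per taxon and assay.
#' @return screening data.frame.
#' @export
make_screening <- function(spec, seed = spec$seed, n_accessions = 3) {
  set.seed(sub_seed(seed, 13L))
  rows <- list()
  for (i in seq_len(nrow(spec$niches))) {
    ni <- spec$niches[i, ]
    for (assay in c("dehydration", "salinity")) {
      cls <- ni[[paste0(assay, "_class")]]
      if (is.null(cls) || cls == "none") next
      best <- switch(cls, high = 1L, intermediate = 2L,
                     low = sample(3:5, 1))
      scores <- c(best, sample(best:5, n_accessions - 1, replace = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = ni$taxon_id,
        accession_id = sprintf("%s_%s_a%02d", ni$taxon_id,
                               substr(assay, 1, 3), seq_len(n_accessions)),
        assay = assay, score = scores, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic biotic-resistance review table
#'
#' Bruchids and Yellow Mosaic Disease are reviewed for most taxa; planted
#' resistance frequencies (75% for bruchids among evaluated taxa, 100% for
#' YMD) echo the rates reported in genus-wide legume reviews.
#'
#' @param spec a `world_spec`.
#' @param seed integer seed.
#' @return resistance data.frame (one row per taxon x stressor).
#' @export
make_resistance <- function(spec, seed = spec$seed) {
  set.seed(sub_seed(seed, 17L))
  taxa <- spec$niches$taxon_id
  rows <- list()
  params <- list(bruchids = c(eval_p = 0.8, resist_p = 0.75),
                 YMD = c(eval_p = 0.5, resist_p = 1.0))
  for (stressor in names(params)) {
    p <- params[[stressor]]
    for (tx in taxa) {
      status <- if (stats::runif(1) > p["eval_p"]) "not_evaluated"
      else if (stats::runif(1) <= p["resist_p"]) "resistant_reported"
      else "no_resistance_reported"
      rows[[length(rows) + 1]] <- data.frame(taxon_id = tx, stressor = stressor,
                                             status = status,
                                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build (and optionally write) the full synthetic fixture set
#'
#' Generates countries, climate stack, presence records for every taxon
#' (with injected, ledgered errors), taxonomy, accession counts, screening
#' scores and the resistance table. With `dir` set, writes records CSV, the
#' 19 ASCII rasters, countries GeoJSON, the fixture CSVs and the ledger CSV.
#'
#' @param spec a `world_spec`.
#' @param dir optional output directory.
#' @return list with all generated objects (`spec`, `countries`, `stack`,
#'   `records`, `clean_records`, `ledger`, `taxonomy`, `accessions`,
#'   `accession_truth`, `screening`, `resistance`).
#' @export
simulate_world <- function(spec, dir = NULL) {
  countries <- make_countries(spec)
  stack <- make_climate_stack(spec)
  recs <- list()
  for (i in seq_len(nrow(spec$niches))) {
    tx <- spec$niches$taxon_id[i]
    recs[[i]] <- sample_presences(spec, stack, countries, tx,
                                  spec$records_per_taxon,
                                  seed = sub_seed(spec$seed, 100L + i))
  }
  clean <- do.call(rbind, recs)
  class(clean) <- c("presence_records", "data.frame")
  inj <- inject_errors(clean, spec, countries, stack)
  acc <- make_accessions(spec)
  world <- list(spec = spec, countries = countries, stack = stack,
                records = inj$records, clean_records = clean,
                ledger = inj$ledger,
                taxonomy = make_taxonomy(spec),
                accessions = acc$table, accession_truth = acc$truth,
                screening = make_screening(spec),
                resistance = make_resistance(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_presence_table(world$records, file.path(dir, "records.csv"))
    write_raster_stack(stack, file.path(dir, "rasters"))
    write_countries(countries, file.path(dir, "countries.geojson"))
    utils::write.csv(world$taxonomy, file.path(dir, "taxonomy.csv"), row.names = FALSE)
    utils::write.csv(world$accessions, file.path(dir, "accessions.csv"), row.names = FALSE)
    utils::write.csv(world$screening, file.path(dir, "screening.csv"), row.names = FALSE)
    utils::write.csv(world$resistance, file.path(dir, "resistance.csv"), row.names = FALSE)
    utils::write.csv(world$ledger, file.path(dir, "ledger.csv"), row.names = FALSE)
  }
  world
}
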