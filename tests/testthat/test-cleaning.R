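# Country tiles for geometric cases: one 4x4-degree country at the origin.
one_country <- function() {
  country_map("C01", list(list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))),
              matrix(c(2, 2), 1))
}

test_that("country filter respects the 10-arc-minute border buffer", {
  cm <- one_country()
  arc <- 1 / 60
  recs <- recs_at(lon = c(2, 4 + 5 * arc, 4 + 30 * arc, 2, 2),
                  lat = c(2, 2, 2, 2, 2),
                  country = c("C01", "C01", "C01", NA, "ZZZ"))
  out <- filter_country_mismatch(recs, cm)
  # interior point and 5-arcmin overshoot kept; 30-arcmin overshoot removed
  expect_true(all(c("x001", "x002", "x004") %in% out$kept$record_id))
  expect_true("x003" %in% out$removed$record_id)
  expect_equal(out$removed$reason[out$removed$record_id == "x003"],
               "outside declared country beyond buffer")
  # unknown code removed with its own reason; missing code kept but flagged
  expect_equal(out$removed$reason[out$removed$record_id == "x005"],
               "unknown country")
  expect_equal(out$flagged, "x004")
})

test_that("country filter decisions match a brute-force distance oracle", {
  cm <- one_country()
  set.seed(17)
  lon <- runif(60, -1, 6); lat <- runif(60, -1, 6)
  recs <- recs_at(lon, lat, country = "C01")
  out <- filter_country_mismatch(recs, cm, buffer_arcmin = 10)
  # oracle: densify the boundary and take the minimum haversine distance
  ring <- cm$polygons[[1]][[1]]
  dense <- do.call(rbind, lapply(1:4, function(i) {
    a <- ring[i, ]; b <- ring[i %% 4 + 1, ]
    t <- seq(0, 1, length.out = 4000)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  for (i in seq_len(60)) {
    inside <- point_in_ring(lon[i], lat[i], ring)
    dmin <- min(gc_dist(cbind(lon[i], lat[i]), dense))
    should_keep <- inside || dmin <= 10 * ARCMIN_M
    expect_equal(recs$record_id[i] %in% out$kept$record_id, should_keep,
                 label = paste("record", i))
  }
})

test_that("coastal relocation moves only near-shore sea points, onto the coast", {
  cm <- one_country()
  arc <- 1 / 60
  recs <- recs_at(lon = c(2, 4 + 5 * arc, 4 + 60 * arc),
                  lat = c(2, 2, 2), country = "C01")
  out <- relocate_coastal(recs, cm, buffer_arcmin = 10)
  r <- out$records
  # land point and far-offshore point unchanged
  expect_equal(r$lon[1], 2)
  expect_equal(r$lon[3], 4 + 60 * arc)
  expect_equal(r$georef_status[c(1, 3)], c("original", "original"))
  # near-shore point relocated: its shift equals the brute-force minimum
  # distance to the densified coastline (within the small inland nudge)
  expect_equal(r$georef_status[2], "relocated_coast")
  ring <- cm$polygons[[1]][[1]]
  dense <- do.call(rbind, lapply(1:4, function(i) {
    a <- ring[i, ]; b <- ring[i %% 4 + 1, ]
    t <- seq(0, 1, length.out = 8000)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  dmin <- min(gc_dist(c(4 + 5 * arc, 2), dense))
  expect_equal(out$relocated$dist_m, dmin, tolerance = 1e-3)
  moved <- gc_dist(c(4 + 5 * arc, 2), c(r$lon[2], r$lat[2]))
  expect_lt(abs(moved - dmin), 0.15 * ARCMIN_M)
  # relocated point is on land now
  expect_equal(country_at(cm, r$lon[2], r$lat[2]), "C01")
})

test_that("centroid removal equals the brute-force all-centroid distance check", {
  w <- get_small_world()
  cm <- w$countries
  set.seed(23)
  lon <- runif(80, 0, 20); lat <- runif(80, 0, 20)
  # plant a few exact centroid hits
  lon[1:3] <- cm$centroids[1:3, 1]; lat[1:3] <- cm$centroids[1:3, 2]
  recs <- recs_at(lon, lat)
  out <- drop_centroids(recs, cm, tol_arcmin = 1)
  for (i in seq_len(80)) {
    dmin <- min(gc_dist(cbind(lon[i], lat[i]), cm$centroids))
    expect_equal(recs$record_id[i] %in% out$removed$record_id,
                 dmin <= ARCMIN_M, label = paste("record", i))
  }
  expect_true(all(recs_at(lon, lat)$record_id[1:3] %in% out$removed$record_id))
})

test_that("deduplication keeps one stable survivor per taxon and rounded site", {
  recs <- recs_at(lon = c(1.00001, 1.00002, 1.00001, 5),
                  lat = c(2.00001, 2.00002, 2.00001, 5),
                  taxon = c("tA", "tA", "tB", "tA"),
                  id = c("r2", "r1", "r3", "r4"))
  out <- dedupe(recs, precision_decimals = 4)
  # same rounded coordinates within tA collapse to the smallest record_id
  expect_setequal(out$kept$record_id, c("r1", "r3", "r4"))
  expect_equal(out$removed$record_id, "r2")
  # counting oracle: kept rows = distinct (taxon, rounded lat, lon) triples
  set.seed(31)
  n <- 200
  recs2 <- recs_at(lon = round(runif(n, 0, 0.01), 4),
                   lat = round(runif(n, 0, 0.01), 4),
                   taxon = sample(c("tA", "tB"), n, replace = TRUE),
                   id = sprintf("q%03d", sample(n)))
  out2 <- dedupe(recs2, 4)
  k <- nrow(unique(data.frame(recs2$taxon_id, round(recs2$lat, 4),
                              round(recs2$lon, 4))))
  expect_equal(nrow(out2$kept), k)
  expect_equal(nrow(out2$kept) + nrow(out2$removed), n)
})

test_that("climate fences follow the quartile arithmetic of the outlier rule", {
  # values {1,2,3,4,100}: Q1 = 2, Q3 = 4, IQR = 2, upper fence 4 + 2.5*2 = 9
  f <- climate_fences(matrix(c(1, 2, 3, 4, 100), 5, 1), k = 2.5)
  expect_equal(unname(f$lo), -3)
  expect_equal(unname(f$hi), 9)
})

test_that("outlier removal needs at least three violating layers", {
  st <- random_stack(8, 8, seed = 4)
  set.seed(5)
  # 12 records on distinct cells
  ctr <- cell_centre(st$grid, sample(8, 12, TRUE), sample(8, 12, TRUE))
  recs <- recs_at(ctr$lon + 0.1, ctr$lat + 0.1, taxon = "tA")
  ix <- cell_index(st$grid, recs$lon, recs$lat)
  # make record 1 extreme on exactly 2 layers (and typical on the other 17):
  # must be kept
  for (nm in BIOCLIM_NAMES) {
    st$layers[[nm]][ix$row[1], ix$col[1]] <-
      median(st$layers[[nm]][cbind(ix$row[-1], ix$col[-1])])
  }
  for (nm in c("BIO2", "BIO3")) st$layers[[nm]][ix$row[1], ix$col[1]] <- 1e4
  out2 <- filter_climate_outliers(recs, st, k = 2.5, min_vars = 3)
  expect_true("x001" %in% out2$kept$record_id)
  # extreme on 3 layers: removed
  st$layers$BIO4[ix$row[1], ix$col[1]] <- 1e4
  out3 <- filter_climate_outliers(recs, st, k = 2.5, min_vars = 3)
  expect_true("x001" %in% out3$removed$record_id)
  expect_equal(out3$removed$reason, "climate outlier")
})

test_that("outlier removal matches the ledger and a brute-force fence oracle", {
  w <- get_world()
  # restrict to untouched + planted-outlier records of one taxon
  led <- w$ledger
  planted <- led$record_id[led$error_type == "climate_outlier"]
  touched <- led$record_id
  recs <- w$records[w$records$record_id %in%
                      c(planted, setdiff(w$records$record_id, touched)), ]
  out <- filter_climate_outliers(recs, w$stack)
  expect_true(all(planted %in% out$removed$record_id))
  # brute-force per-taxon fence check reproduces every removal decision
  env <- stack_lookup(w$stack, recs$lon, recs$lat)
  removed_ids <- out$removed$record_id[out$removed$reason == "climate outlier"]
  for (tx in unique(recs$taxon_id)) {
    rows <- which(recs$taxon_id == tx & complete.cases(env))
    vals <- env[rows, , drop = FALSE]
    q1 <- apply(vals, 2, quantile, 0.25)
    q3 <- apply(vals, 2, quantile, 0.75)
    nv <- rowSums(t(t(vals) < q1 - 2.5 * (q3 - q1)) |
                    t(t(vals) > q3 + 2.5 * (q3 - q1)))
    expect_setequal(recs$record_id[rows[nv >= 3]],
                    intersect(removed_ids, recs$record_id[rows]))
  }
})

test_that("the composed pipeline is audited, idempotent and order-correct", {
  w <- get_world()
  cl <- clean_pipeline(w$records, w$countries, w$stack)
  st <- cl$report$steps
  # conservation: each step's output feeds the next
  expect_equal(st$n_out, st$n_in - st$n_removed)
  expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
  expect_equal(st$n_out[nrow(st)], nrow(cl$records))
  # every removal carries a reason
  expect_false(any(is.na(cl$report$detail$reason)))

  # removals land at the step matching their injected error type
  d <- merge(w$ledger, cl$report$detail, by = "record_id")
  step_of <- c(country_mismatch = "country_mismatch",
               offshore_beyond = "country_mismatch",
               centroid = "centroid_removal",
               duplicate = "dedupe",
               climate_outlier = "climate_outliers")
  for (ty in names(step_of)) {
    sub <- d[d$error_type == ty & d$action == "removed", ]
    expect_true(all(sub$step == step_of[[ty]]), label = ty)
  }
  # near-shore offshore points survive via relocation, not removal
  within <- w$ledger$record_id[w$ledger$error_type == "offshore_within"]
  relocated <- cl$report$detail$record_id[cl$report$detail$action == "modified"]
  expect_true(all(within %in% relocated))

  # idempotence: a second pass removes and modifies nothing
  cl2 <- clean_pipeline(cl$records, w$countries, w$stack)
  expect_equal(sum(cl2$report$steps$n_removed), 0)
  expect_equal(sum(cl2$report$steps$n_modified), 0)
  expect_equal(nrow(cl2$records), nrow(cl$records))
})

test_that("an error-free world passes through the pipeline unchanged", {
  w <- get_small_world()
  cl <- clean_pipeline(w$clean_records, w$countries, w$stack)
  expect_equal(sum(cl$report$steps$n_removed), 0)
  expect_equal(nrow(cl$records), nrow(w$clean_records))
})
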