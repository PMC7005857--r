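test_that("spatial thinning keeps one record per occupied cell, then subsamples", {
  # all points in distinct cells with keep_frac = 1: identity
  pts <- cbind(c(0.1, 1.1, 2.1), c(0.1, 1.1, 2.1))
  expect_equal(resample_presences(pts, 1, keep_frac = 1, seed = 1), 1:3)
  # ten points in one cell: stage 1 keeps exactly one
  pts1 <- cbind(runif(10, 0, 0.5), runif(10, 0, 0.5))
  expect_equal(length(resample_presences(pts1, 1, keep_frac = 1, seed = 2)), 1)
  # keep_frac = 0.8 rounds up
  pts2 <- cbind(seq(0.1, 9.1), seq(0.1, 9.1))
  expect_equal(length(resample_presences(pts2, 1, keep_frac = 0.8, seed = 3)),
               8)
})

test_that("thinning retention is cellwise unique and near-uniform over runs", {
  set.seed(19)
  pts <- cbind(runif(40, 0, 2), runif(40, 0, 2))
  cellkey <- paste(floor(pts[, 1]), floor(pts[, 2]))
  tally <- numeric(40)
  for (s in 1:400) {
    keep <- resample_presences(pts, 1, keep_frac = 1, seed = s)
    expect_false(any(duplicated(cellkey[keep])))
    tally[keep] <- tally[keep] + 1
  }
  # within each multi-occupant cell, per-point retention is uniform
  for (ck in unique(cellkey)) {
    members <- which(cellkey == ck)
    if (length(members) < 2) next
    p <- 1 / length(members)
    expected <- 400 * p
    margin <- 4 * sqrt(400 * p * (1 - p))
    expect_true(all(abs(tally[members] - expected) <= margin), label = ck)
  }
})

test_that("background sampling stays inside the buffered hull at 10x density", {
  w <- get_small_world()
  cl <- clean_pipeline(w$records, w$countries, w$stack)
  pts <- as.matrix(cl$records[cl$records$taxon_id == "Taxon_02",
                              c("lon", "lat")])
  hull <- hull_region(pts, 0.1)
  bg <- sample_background(hull, w$stack, 20, ratio = 10, seed = 4)
  expect_equal(nrow(bg), 200)
  expect_true(all(in_hull_region(hull, bg$lon, bg$lat)))
  # buffered region contains the raw hull, which contains all presences
  expect_true(all(in_hull_region(hull, pts[, 1], pts[, 2])))
})

test_that("background draws are uniform over eligible cells", {
  w <- get_small_world()
  pts <- as.matrix(w$clean_records[w$clean_records$taxon_id == "Taxon_01",
                                   c("lon", "lat")])
  hull <- hull_region(pts, 0.1)
  bg <- sample_background(hull, w$stack, 2000, ratio = 10, seed = 8)
  counts <- table(bg$cell)
  g <- w$stack$grid
  land <- which(!is.na(w$stack$layers$BIO1))
  ctr <- cell_centre(g, (land - 1) %% g$nrow + 1, (land - 1) %/% g$nrow + 1)
  n_elig <- sum(in_hull_region(hull, ctr$lon, ctr$lat))
  full <- c(as.numeric(counts), rep(0, n_elig - length(counts)))
  gof <- chisq.test(full, p = rep(1 / n_elig, n_elig))
  expect_gt(gof$p.value, 0.01)
})

test_that("maximum entropy reduces to uniform when presence matches background", {
  set.seed(6)
  env <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("BIO1", "BIO12")))
  m <- fit_maxent(env, env, beta = 0.05)
  expect_true(all(m$weights == 0))
  raw <- maxent_raw(m, env)
  expect_true(all(raw == 1))
})

test_that("fitted suitability rises along a planted 1-D gradient", {
  set.seed(14)
  bg_v <- runif(1000, 0, 10)
  pres_v <- 10 - abs(rnorm(100, 0, 1.5))  # clustered at high values
  m <- fit_maxent(cbind(BIO1 = pres_v), cbind(BIO1 = bg_v), beta = 0.05)
  grid_v <- seq(1, 9, by = 0.5)
  s <- maxent_raw(m, cbind(BIO1 = grid_v))
  expect_true(all(diff(s) > 0))
})

test_that("the fitted model satisfies the KKT feature-matching box condition", {
  w <- get_small_world()
  cl <- clean_pipeline(w$records, w$countries, w$stack)
  pts <- as.matrix(cl$records[cl$records$taxon_id == "Taxon_03",
                              c("lon", "lat")])
  pe <- stack_lookup(w$stack, pts[, 1], pts[, 2])
  pe <- pe[complete.cases(pe), ]
  hull <- hull_region(pts, 0.1)
  bg <- sample_background(hull, w$stack, nrow(pe), 10, seed = 2)
  be <- stack_lookup(w$stack, bg$lon, bg$lat)
  beta <- 0.05
  m <- fit_maxent(pe, be, beta = beta)
  # E_P[f] under the fitted Gibbs distribution over background
  fb <- vignagap:::.build_features(be[, m$variables], m$centres, m$scales)
  fp <- vignagap:::.build_features(pe[, m$variables], m$centres, m$scales)
  q <- exp(fb %*% m$weights); q <- q / sum(q)
  gap <- abs(as.vector(crossprod(fb, q)) - colMeans(fp))
  expect_true(all(gap <= beta + 1e-6))
})

test_that("prediction is a pure function of climate", {
  w <- get_small_world()
  st <- w$stack
  pe <- cbind(BIO1 = rnorm(30, 24), BIO12 = rnorm(30, 1500, 100))
  be <- cbind(BIO1 = rnorm(300, 22, 3), BIO12 = rnorm(300, 1600, 300))
  m <- fit_maxent(pe, be, beta = 0.05)
  # two cells given identical climate get identical suitability
  st2 <- st
  land <- which(!is.na(st$layers$BIO1))
  i <- land[1]; j <- land[200]
  for (nm in BIOCLIM_NAMES) st2$layers[[nm]][j] <- st2$layers[[nm]][i]
  pred <- predict_suitability(m, st2, clip = NULL)
  expect_equal(pred$values[i], pred$values[j])
  # prediction at a cell equals direct evaluation of exp(w . f) there
  env_i <- cbind(BIO1 = st2$layers$BIO1[i], BIO12 = st2$layers$BIO12[i])
  raw_all <- maxent_raw(m, cbind(BIO1 = as.vector(st2$layers$BIO1)[land],
                                 BIO12 = as.vector(st2$layers$BIO12)[land]))
  expect_equal(pred$values[i], maxent_raw(m, env_i) / max(raw_all))
  # zero weights give a constant raster
  m0 <- m; m0$weights <- rep(0, length(m0$weights))
  p0 <- predict_suitability(m0, st, clip = NULL)
  expect_equal(range(p0$values, na.rm = TRUE), c(1, 1))
  # missing variable errors by name
  m2 <- m; m2$variables <- c("BIO1", "BIO99")
  expect_error(predict_suitability(m2, st), "BIO99")
})

test_that("max sens+spec threshold matches exhaustive scans and tie-break", {
  # separable case: smallest candidate attaining the maximum is 0.8
  expect_equal(threshold_max_ss(c(0.9, 0.8), c(0.2, 0.1)), 0.8)
  scan_oracle <- function(p, b) {
    cand <- sort(unique(c(p, b)))
    ss <- sapply(cand, function(t) mean(p >= t) + mean(b < t))
    cand[which(ss >= max(ss) - 1e-12)[1]]  # smallest maximiser
  }
  expect_equal(threshold_max_ss(c(0.9, 0.4), c(0.5, 0.1)),
               scan_oracle(c(0.9, 0.4), c(0.5, 0.1)))
  # identical distributions: best sens+spec is about 1
  set.seed(3)
  x <- runif(200)
  tau <- threshold_max_ss(x, x)
  expect_equal(tau, scan_oracle(x, x))
  expect_lte(mean(x >= tau) + mean(x < tau), 1 + 1e-12)
  # random instances against the oracle
  for (s in 1:20) {
    set.seed(s)
    p <- round(runif(30), 2); b <- round(runif(50), 2)
    expect_equal(threshold_max_ss(p, b), scan_oracle(p, b), label = s)
  }
})

test_that("the protocol averages runs, clips to the hull, and is deterministic", {
  w <- get_small_world()
  cl <- clean_pipeline(w$records, w$countries, w$stack)
  pts <- as.matrix(cl$records[cl$records$taxon_id == "Taxon_04",
                              c("lon", "lat")])
  cfg <- list(seed = 9)
  sm <- run_protocol(pts, w$stack, cfg)
  expect_false(sm$skipped)
  # averaged raster is the exact cellwise mean of the per-run rasters
  manual <- (sm$runs[[1]]$values + sm$runs[[2]]$values + sm$runs[[3]]$values) / 3
  expect_equal(sm$continuous$values, manual)
  # all binary-positive cells lie inside the buffered hull
  g <- w$stack$grid
  pos <- which(sm$binary$values == 1)
  expect_gt(length(pos), 0)
  ctr <- cell_centre(g, (pos - 1) %% g$nrow + 1, (pos - 1) %/% g$nrow + 1)
  expect_true(all(in_hull_region(sm$hull, ctr$lon, ctr$lat)))
  # binary = continuous >= tau within the clip
  inside <- !is.na(sm$continuous$values)
  expect_equal(sm$binary$values[inside] == 1,
               sm$continuous$values[inside] >= sm$tau)
  # determinism under the same seed
  sm2 <- run_protocol(pts, w$stack, cfg)
  expect_identical(sm2$continuous$values, sm$continuous$values)
  expect_identical(sm2$tau, sm$tau)
  # too few records: skipped with a reason
  sk <- run_protocol(pts[1:3, ], w$stack, cfg)
  expect_true(sk$skipped)
  expect_match(sk$reason, "fewer than 5")
})

test_that("degenerate single-cell clusters still produce a covering binary map", {
  w <- get_small_world()
  g <- w$stack$grid
  land <- which(!is.na(w$stack$layers$BIO1))
  cell <- land[10]
  ctr <- cell_centre(g, (cell - 1) %% g$nrow + 1, (cell - 1) %/% g$nrow + 1)
  set.seed(2)
  pts <- cbind(ctr$lon + runif(8, -0.05, 0.05),
               ctr$lat + runif(8, -0.05, 0.05))
  sm <- run_protocol(pts, w$stack,
                     list(n_runs = 1, keep_frac = 1, seed = 3,
                          variables = c("BIO1", "BIO12")))
  ix <- cell_index(g, pts[, 1], pts[, 2])
  expect_true(all(sm$binary$values[cbind(ix$row, ix$col)] == 1))
})
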