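# Presence-background niche modelling: spatial thinning on a grid scaled to
# 10% of the longest inter-point distance, background sampling from the
# buffered convex hull, a maximum-entropy (Gibbs) model with standardised
# linear + quadratic features and an L1 penalty, run averaging,
# max-sensitivity-plus-specificity thresholding, and hull clipping.

#' Spatial-thinning grid cell size
#'
#' Cell size in degrees = `thin_frac` x longest inter-point distance,
#' converted to degrees at the points' mean latitude.
#'
#' @param points two-column matrix (lon, lat).
#' @param thin_frac fraction of the longest inter-point distance (default 0.1).
#' @return cell size in degrees.
#' @export
thinning_cell_deg <- function(points, thin_frac = 0.1) {
  d_km <- longest_interpoint_distance(points)
  mean_lat <- mean(points[, 2])
  cell <- thin_frac * d_km / (KM_PER_DEG * cos(mean_lat * pi / 180))
  if (cell <= 0) stop("degenerate thinning grid")
  cell
}

#' Thin presences on a grid, then subsample
#'
#' Stage 1 keeps one record uniformly at random per occupied grid cell
#' (spatial thinning against collection bias); stage 2 draws
#' `ceiling(keep_frac x n_thinned)` of the survivors without replacement.
#' Deterministic given `seed`.
#'
#' @param points two-column matrix (lon, lat).
#' @param cell_deg thinning cell size in degrees.
#' @param keep_frac fraction retained after thinning (default 0.8).
#' @param seed integer seed.
#' @param origin grid origin (lon, lat); align to the raster origin so
#'   thinning cells nest in the climate grid.
#' @return integer indices into `points` of the retained records.
#' @export
resample_presences <- function(points, cell_deg, keep_frac = 0.8, seed = 1L,
                               origin = c(0, 0)) {
  stopifnot(keep_frac > 0, keep_frac <= 1)
  set.seed(seed)
  cx <- floor((points[, 1] - origin[1]) / cell_deg)
  cy <- floor((points[, 2] - origin[2]) / cell_deg)
  key <- paste(cx, cy)
  thinned <- unname(vapply(split(seq_len(nrow(points)), key), function(ix) {
    if (length(ix) == 1) ix else sample(ix, 1)
  }, integer(1)))
  n_keep <- ceiling(keep_frac * length(thinned))
  sort(if (n_keep >= length(thinned)) thinned else sample(thinned, n_keep))
}

#' Convex hull of presences with a proportional buffer
#'
#' The buffer distance is `buffer_frac` x the longest inter-point distance.
#' Membership is evaluated as: inside the hull, or within the buffer distance
#' of the hull boundary (equivalent to the buffered polygon, without
#' constructing offset geometry). Degenerate hulls (< 3 distinct points)
#' reduce to a distance buffer around the points/segment.
#'
#' @param points two-column matrix (lon, lat).
#' @param buffer_frac fraction of the longest inter-point distance (default 0.1).
#' @return a `hull_region` (hull ring, buffer in km).
#' @export
hull_region <- function(points, buffer_frac = 0.1) {
  points <- as.matrix(points)
  d_km <- longest_interpoint_distance(points)
  ring <- convex_hull_ring(points)
  structure(list(ring = ring, buffer_km = buffer_frac * d_km,
                 degenerate = nrow(unique(ring)) < 3),
            class = "hull_region")
}

#' Test membership in a buffered hull region
#'
#' @param region a `hull_region`.
#' @param lon,lat coordinates.
#' @return logical vector.
#' @export
in_hull_region <- function(region, lon, lat) {
  buf_m <- region$buffer_km * 1000
  if (region$degenerate) {
    ring <- region$ring
    d <- if (nrow(ring) == 1) gc_dist(cbind(lon, lat), ring[1, ])
    else dist_to_line_m(lon, lat, ring)
    return(d <= buf_m)
  }
  inside <- point_in_ring(lon, lat, region$ring)
  inside | dist_to_line_m(lon, lat, region$ring) <= buf_m
}

#' Sample background points from the buffered hull
#'
#' Draws `ratio x n_presence` points uniformly over the data cells whose
#' centres fall inside the region (cells may repeat; sampling is with
#' replacement, matching a uniform background process). Points are cell
#' centres.
#'
#' @param region a `hull_region`.
#' @param stack a `climate_stack`.
#' @param n_presence number of presence records.
#' @param ratio background-to-presence ratio (default 10).
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat`, `cell`.
#' @export
sample_background <- function(region, stack, n_presence, ratio = 10, seed = 1L) {
  g <- stack$grid
  land <- which(!is.na(stack$layers$BIO1))
  row <- (land - 1) %% g$nrow + 1; col <- (land - 1) %/% g$nrow + 1
  ctr <- cell_centre(g, row, col)
  elig <- land[in_hull_region(region, ctr$lon, ctr$lat)]
  if (!length(elig)) stop("buffered hull contains no data cells")
  n_bg <- ratio * n_presence
  set.seed(seed)
  cells <- elig[sample.int(length(elig), n_bg, replace = TRUE)]
  row <- (cells - 1) %% g$nrow + 1; col <- (cells - 1) %/% g$nrow + 1
  cbind(cell_centre(g, row, col), cell = cells)
}

# ---- maximum-entropy model ---------------------------------------------

# standardised linear + quadratic feature expansion; centring/scaling
# parameters come from the background sample and travel with the model
.build_features <- function(env, centres, scales) {
  z <- sweep(sweep(as.matrix(env), 2, centres, "-"), 2, scales, "/")
  cbind(z, z^2)
}

#' Fit a presence-background maximum-entropy model
#'
#' Finds the Gibbs distribution P(cell) proportional to exp(w . f(cell)) over
#' the background that matches the presence feature means, by minimising the
#' L1-penalised convex objective
#' `-mean_presence(w . f) + log mean_background exp(w . f) + beta ||w||_1`
#' with proximal gradient descent (soft-thresholding, backtracking line
#' search). Features are standardised linear and quadratic terms of each
#' variable (centring/scaling from the background). At the optimum every
#' feature satisfies the box condition
#' `|E_P f_j - mean_presence f_j| <= beta`.
#'
#' @param presence_env matrix/data.frame of variable values at presences.
#' @param background_env same variables at background points.
#' @param beta L1 regularisation strength (default 0.05).
#' @param max_iter iteration cap (default 5000).
#' @param tol KKT tolerance (default 1e-8).
#' @return a `maxent_model`: weights, feature metadata, `beta`, training
#'   sizes.
#' @export
fit_maxent <- function(presence_env, background_env, beta = 0.05,
                       max_iter = 5000, tol = 1e-8) {
  presence_env <- as.matrix(presence_env)
  background_env <- as.matrix(background_env)
  if (nrow(presence_env) < 5) stop("need >= 5 presence rows")
  if (nrow(background_env) < nrow(presence_env)) {
    stop("background must be at least as large as presence")
  }
  if (anyNA(presence_env) || anyNA(background_env)) {
    stop("environmental values contain NA; filter nodata rows first")
  }
  vars <- colnames(presence_env)
  centres <- colMeans(background_env)
  scales <- apply(background_env, 2, stats::sd)
  scales[scales == 0] <- 1
  Fp <- .build_features(presence_env, centres, scales)
  Fb <- .build_features(background_env, centres, scales)
  p_mean <- colMeans(Fp)
  nfeat <- ncol(Fb)

  obj <- function(w) {
    eta <- Fb %*% w
    m <- max(eta)
    -sum(p_mean * w) + m + log(mean(exp(eta - m)))
  }
  grad <- function(w) {
    eta <- Fb %*% w
    q <- exp(eta - max(eta)); q <- q / sum(q)
    as.vector(crossprod(Fb, q)) - p_mean
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  w <- numeric(nfeat)
  step <- 1
  fw <- obj(w)
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    # KKT box condition for the L1 problem
    viol <- ifelse(w > 0, abs(g + beta),
                   ifelse(w < 0, abs(g - beta), pmax(abs(g) - beta, 0)))
    if (max(viol) < tol) {
      return(structure(list(weights = w, variables = vars, centres = centres,
                            scales = scales, beta = beta, p_mean = p_mean,
                            n_presence = nrow(presence_env),
                            n_background = nrow(background_env),
                            iterations = it, converged = TRUE),
                       class = "maxent_model"))
    }
    repeat {
      w_new <- soft(w - step * g, step * beta)
      f_new <- obj(w_new)
      dw <- w_new - w
      if (f_new <= fw + sum(g * dw) + sum(dw^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (sum((w_new - w)^2) == 0 && step < 1e-12) break
    w <- w_new; fw <- obj(w)
    step <- min(step * 1.5, 1e3)
  }
  g <- grad(w)
  stop("maximum-entropy fit did not converge; gradient norm ",
       format(sqrt(sum(g^2))))
}

#' Evaluate a fitted maximum-entropy model at environmental values
#'
#' Returns exp(w . f), unnormalised.
#'
#' @param model a `maxent_model`.
#' @param env matrix/data.frame with the model's variables.
#' @return numeric vector.
#' @export
maxent_raw <- function(model, env) {
  env <- as.matrix(env)[, model$variables, drop = FALSE]
  f <- .build_features(env, model$centres, model$scales)
  as.vector(exp(f %*% model$weights))
}

#' Predict a continuous suitability raster
#'
#' Per-cell exp(w . f) normalised to \[0, 1\] by the maximum over the clip
#' region; nodata outside the clip region.
#'
#' @param model a `maxent_model`.
#' @param stack a `climate_stack` providing the model's variables.
#' @param clip a `hull_region` (or NULL to use all data cells).
#' @return a `grid_raster` of suitabilities.
#' @export
predict_suitability <- function(model, stack, clip = NULL) {
  miss <- setdiff(model$variables, names(stack$layers))
  if (length(miss)) stop("stack lacks model variable(s): ",
                         paste(miss, collapse = ", "))
  g <- stack$grid
  land <- which(!is.na(stack$layers$BIO1))
  if (!is.null(clip)) {
    row <- (land - 1) %% g$nrow + 1; col <- (land - 1) %/% g$nrow + 1
    ctr <- cell_centre(g, row, col)
    land <- land[in_hull_region(clip, ctr$lon, ctr$lat)]
  }
  env <- do.call(cbind, lapply(model$variables, function(v) {
    as.vector(stack$layers[[v]])[land]
  }))
  colnames(env) <- model$variables
  raw <- maxent_raw(model, env)
  vals <- matrix(NA_real_, g$nrow, g$ncol)
  vals[land] <- raw / max(raw)
  grid_raster(g, vals)
}

#' Maximum sensitivity + specificity threshold
#'
#' Scans all distinct observed scores as candidate thresholds tau (suitable
#' means score >= tau); returns the tau maximising
#' sensitivity(tau) + specificity(tau), breaking ties by the smallest tau.
#'
#' @param presence_scores suitability scores at presences.
#' @param background_scores suitability scores at background points.
#' @return the threshold tau.
#' @export
threshold_max_ss <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  cand <- sort(unique(c(presence_scores, background_scores)))
  ss <- vapply(cand, function(tau) {
    mean(presence_scores >= tau) + mean(background_scores < tau)
  }, numeric(1))
  cand[which(ss >= max(ss) - 1e-12)[1]]
}

#' Area under the ROC curve (presences vs background)
#'
#' Rank-based (Mann-Whitney) estimate; ties count one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(presence_scores, background_scores) {
  r <- rank(c(presence_scores, background_scores))
  np <- length(presence_scores); nb <- length(background_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Run the full niche-modelling protocol for one taxon
#'
#' Three (by default) maximum-entropy fits on independently thinned and
#' subsampled presences; the continuous raster is the cellwise mean of the
#' run predictions; the threshold is computed from the averaged raster's
#' scores at all supplied presences against the background sample; the
#' binary raster is clipped to the buffered convex hull. Taxa with fewer
#' than `min_model_records` presences are skipped.
#'
#' @param points two-column matrix (lon, lat) of cleaned presences.
#' @param stack a `climate_stack`.
#' @param config list: `n_runs` (3), `keep_frac` (0.8), `thin_frac` (0.1),
#'   `buffer_frac` (0.1), `bg_ratio` (10), `beta` (0.05), `seed` (1),
#'   `min_model_records` (5), `variables` (NULL = prune the 19 layers on the
#'   background sample at |r| <= 0.7).
#' @return a `suitability_map`: `continuous` and `binary` `grid_raster`s,
#'   `tau`, `hull` (the clip region), `models` (per-run fits), `background`;
#'   or a list with `skipped = TRUE` and a reason when there are too few
#'   records.
#' @export
run_protocol <- function(points, stack, config = list()) {
  cfg <- utils::modifyList(list(n_runs = 3, keep_frac = 0.8, thin_frac = 0.1,
                                buffer_frac = 0.1, bg_ratio = 10, beta = 0.05,
                                seed = 1L, min_model_records = 5,
                                variables = NULL), config)
  points <- as.matrix(points)
  if (nrow(points) < cfg$min_model_records) {
    return(list(skipped = TRUE,
                reason = sprintf("fewer than %d presence records",
                                 cfg$min_model_records)))
  }
  hull <- hull_region(points, cfg$buffer_frac)
  bg <- sample_background(hull, stack, nrow(points), cfg$bg_ratio,
                          seed = sub_seed(cfg$seed, 301L))
  bg_env <- stack_lookup(stack, bg$lon, bg$lat)
  vars <- cfg$variables
  if (is.null(vars)) vars <- prune_correlated(bg_env, r_max = 0.7)
  cell_deg <- thinning_cell_deg(points, cfg$thin_frac)
  g <- stack$grid

  models <- vector("list", cfg$n_runs)
  preds <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    keep <- resample_presences(points, cell_deg, cfg$keep_frac,
                               seed = sub_seed(cfg$seed, 310L + r),
                               origin = c(g$xmin, g$ymin))
    pe <- stack_lookup(stack, points[keep, 1], points[keep, 2])
    pe <- pe[stats::complete.cases(pe), vars, drop = FALSE]
    models[[r]] <- fit_maxent(pe, bg_env[, vars, drop = FALSE], cfg$beta)
    preds[[r]] <- predict_suitability(models[[r]], stack, hull)
  }
  avg <- preds[[1]]$values
  if (cfg$n_runs > 1) {
    for (r in 2:cfg$n_runs) avg <- avg + preds[[r]]$values
    avg <- avg / cfg$n_runs
  }
  continuous <- grid_raster(g, avg)
  pres_scores <- raster_lookup(continuous, points[, 1], points[, 2])
  pres_scores <- pres_scores[!is.na(pres_scores)]
  bg_scores <- raster_lookup(continuous, bg$lon, bg$lat)
  tau <- threshold_max_ss(pres_scores, bg_scores)
  bin <- ifelse(!is.na(avg) & avg >= tau, 1, ifelse(is.na(avg), NA, 0))
  structure(list(continuous = continuous,
                 binary = grid_raster(g, bin), tau = tau, hull = hull,
                 models = models, runs = preds, background = bg,
                 variables = vars, skipped = FALSE),
            class = "suitability_map")
}
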