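# Spherical geometry helpers shared by the cleaning, niche and gap modules.
# All distances are great-circle (haversine) on a sphere of radius 6371 km;
# arc-minute buffers are angular distances converted at that radius.

#' Earth radius (m) used for all great-circle distances
#' @keywords internal
EARTH_RADIUS_M <- 6371000

#' Metres per arc-minute of great-circle arc
#' @keywords internal
ARCMIN_M <- EARTH_RADIUS_M * pi / (180 * 60)

#' Kilometres per degree of great-circle arc
#' @keywords internal
KM_PER_DEG <- EARTH_RADIUS_M * pi / 180 / 1000

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p1,p2 two-column matrices (lon, lat) or length-2 vectors; recycled
#'   row-wise as in [geosphere::distHaversine()].
#' @return distance(s) in metres.
#' @export
gc_dist <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
}

#' Maximum pairwise great-circle distance
#'
#' The longest inter-point distance over all pairs, used to scale the
#' spatial-thinning grid and the convex-hull buffer.
#'
#' @param points two-column matrix (lon, lat), at least 2 rows.
#' @return distance in kilometres.
#' @export
longest_interpoint_distance <- function(points) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 2) stop("insufficient points: need >= 2 distinct points")
  d <- geosphere::distm(points, fun = function(a, b) gc_dist(a, b))
  max(d) / 1000
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd rule in lon/lat coordinates. Points exactly on an edge may fall on
#' either side; callers that care use a distance buffer.
#'
#' @param lon,lat numeric vectors of query points.
#' @param ring two-column matrix of polygon vertices (closed or open).
#' @return logical vector.
#' @export
point_in_ring <- function(lon, lat, ring) {
  ring <- as.matrix(ring)
  # drop explicit closure; algorithm wraps
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  n <- nrow(ring)
  inside <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Point-in-polygon for multi-ring polygons
#'
#' @param lon,lat query coordinates.
#' @param rings list of two-column matrices (outer rings; holes unsupported).
#' @return logical vector: inside any ring.
#' @export
point_in_polygon <- function(lon, lat, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- logical(length(lon))
  for (r in rings) inside <- inside | point_in_ring(lon, lat, r)
  inside
}

# Nearest point on a great-circle segment, via a local equirectangular
# projection centred on the query point. Adequate for the arc-minute to
# few-degree scales used here.
.nearest_on_segment <- function(p, a, b) {
  k <- cos(p[2] * pi / 180)
  ax <- (a[1] - p[1]) * k; ay <- a[2] - p[2]
  bx <- (b[1] - p[1]) * k; by <- b[2] - p[2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else max(0, min(1, -(ax * dx + ay * dy) / len2))
  c(lon = p[1] + (ax + t * dx) / k, lat = p[2] + (ay + t * dy))
}

#' Nearest point on a polyline
#'
#' @param p length-2 vector (lon, lat).
#' @param line two-column matrix of polyline vertices.
#' @return list with `point` (lon, lat) and `dist_m`.
#' @export
nearest_on_line <- function(p, line) {
  line <- as.matrix(line)
  best <- NULL; best_d <- Inf
  for (i in seq_len(nrow(line) - 1)) {
    q <- .nearest_on_segment(p, line[i, ], line[i + 1, ])
    d <- gc_dist(p, q)
    if (d < best_d) { best_d <- d; best <- q }
  }
  list(point = best, dist_m = best_d)
}

#' Distance from many points to a polyline, vectorised
#'
#' Same local-equirectangular approximation as [nearest_on_line()], applied
#' to all points at once (loop over segments, vectorised over points).
#'
#' @param lon,lat query coordinates.
#' @param line two-column matrix of polyline vertices.
#' @return numeric vector of distances in metres.
#' @export
dist_to_line_m <- function(lon, lat, line) {
  line <- as.matrix(line)
  k <- cos(lat * pi / 180)
  best <- rep(Inf, length(lon))
  for (i in seq_len(nrow(line) - 1)) {
    ax <- (line[i, 1] - lon) * k;     ay <- line[i, 2] - lat
    bx <- (line[i + 1, 1] - lon) * k; by <- line[i + 1, 2] - lat
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- ifelse(len2 == 0, 0, pmax(0, pmin(1, -(ax * dx + ay * dy) / len2)))
    qlon <- lon + (ax + t * dx) / k
    qlat <- lat + (ay + t * dy)
    d <- gc_dist(cbind(lon, lat), cbind(qlon, qlat))
    best <- pmin(best, d)
  }
  best
}

#' Distance from a point to a polygon boundary
#'
#' Zero if the point lies inside the polygon.
#'
#' @param lon,lat query point.
#' @param rings list of rings (two-column matrices).
#' @return distance in metres.
#' @export
dist_to_polygon <- function(lon, lat, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  if (point_in_polygon(lon, lat, rings)) return(0)
  p <- c(lon, lat)
  best <- Inf
  for (r in rings) {
    r <- as.matrix(r)
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    best <- min(best, nearest_on_line(p, r)$dist_m)
  }
  best
}

#' Convex hull of points as a closed ring
#'
#' @param points two-column matrix (lon, lat).
#' @return two-column matrix, closed (first row repeated last), or the unique
#'   points themselves when fewer than 3 are distinct (degenerate hull).
#' @export
convex_hull_ring <- function(points) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 3) return(points)
  idx <- grDevices::chull(points)
  ring <- points[idx, , drop = FALSE]
  if (nrow(unique(ring)) < 3) return(unique(ring))  # collinear
  rbind(ring, ring[1, , drop = FALSE])
}
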