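# Planar and geodesic geometry primitives shared by the pipeline stages.
#
# Polygons are stored as lists of rings, each ring a list(x =, y =) of closed
# coordinate loops (last vertex NOT repeated), the native format of polyclip.
# Geographic polygons use x = longitude, y = latitude in decimal degrees
# (WGS84); planar work happens in Web Mercator metres (EPSG:3857).

# Mean Earth radius (km), used for all geodesic point distances.
EARTH_RADIUS_KM <- 6371.0088
# WGS84 semi-major axis (m), the Web Mercator sphere radius.
MERCATOR_R <- 6378137
# Web Mercator latitude of validity (degrees).
MERCATOR_MAX_LAT <- 85.06

#' Geodesic (haversine) distance in kilometres
#'
#' Great-circle distance on a spherical Earth of radius 6371.0088 km,
#' vectorised over point pairs.
#'
#' @param lon1,lat1 Numeric vectors, first point(s), decimal degrees (WGS84).
#' @param lon2,lat2 Numeric vectors, second point(s), recycled as needed.
#' @return Numeric vector of distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Full geodesic distance matrix (km) between two point sets, computed in
# column blocks to bound peak memory on larger cities.
dist_matrix_km <- function(lon, lat, lon2 = lon, lat2 = lat, block = 512L) {
  p1 <- cbind(lon, lat)
  n2 <- length(lon2)
  out <- matrix(NA_real_, nrow = length(lon), ncol = n2)
  for (start in seq(1L, n2, by = block)) {
    idx <- start:min(start + block - 1L, n2)
    out[, idx] <- geosphere::distm(p1, cbind(lon2[idx], lat2[idx]),
                                   fun = geosphere::distHaversine) *
      (EARTH_RADIUS_KM / 6378.137) / 1000
  }
  out
}

#' Forward Web Mercator (EPSG:3857) projection
#'
#' @param lon,lat Coordinates in decimal degrees (WGS84).
#' @return Two-column matrix of planar x, y in metres.
#' @export
mercator_project <- function(lon, lat) {
  if (any(abs(lat) >= MERCATOR_MAX_LAT, na.rm = TRUE))
    stop("latitude outside Web Mercator validity (|lat| >= ",
         MERCATOR_MAX_LAT, " degrees)")
  x <- MERCATOR_R * lon * pi / 180
  y <- MERCATOR_R * log(tan(pi / 4 + lat * pi / 360))
  cbind(x = x, y = y)
}

#' Inverse Web Mercator projection
#'
#' @param x,y Planar coordinates in metres (EPSG:3857).
#' @return Two-column matrix of lon, lat in decimal degrees.
#' @export
mercator_unproject <- function(x, y) {
  lon <- x / MERCATOR_R * 180 / pi
  lat <- (2 * atan(exp(y / MERCATOR_R)) - pi / 2) * 180 / pi
  cbind(lon = lon, lat = lat)
}

# Normalise a polygon argument to a list of rings.
as_rings <- function(poly) {
  if (is.list(poly) && !is.null(poly$x)) list(poly) else poly
}

# Signed shoelace area of one ring (positive = counter-clockwise).
ring_area_signed <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

ensure_ccw <- function(ring) {
  if (ring_area_signed(ring) < 0) list(x = rev(ring$x), y = rev(ring$y))
  else ring
}

#' Polygon area (planar units squared)
#'
#' Shoelace area summed over rings; holes (opposite orientation) subtract.
#'
#' @param poly A ring `list(x=, y=)` or list of rings.
#' @return Non-negative area in the square of the coordinate unit.
#' @export
polygon_area <- function(poly) {
  abs(sum(vapply(as_rings(poly), ring_area_signed, numeric(1))))
}

#' Area-weighted polygon centroid (planar)
#'
#' @param poly A ring or list of rings in planar coordinates.
#' @return Numeric `c(x, y)` centroid.
#' @export
polygon_centroid_planar <- function(poly) {
  rings <- as_rings(poly)
  atot <- 0; cx <- 0; cy <- 0
  for (ring in rings) {
    x <- ring$x; y <- ring$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- x * yn - xn * y
    a <- 0.5 * sum(cross)
    if (abs(a) < .Machine$double.xmin) next
    cx <- cx + sum((x + xn) * cross) / 6
    cy <- cy + sum((y + yn) * cross) / 6
    atot <- atot + a
  }
  if (atot == 0) stop("degenerate polygon: zero area, centroid undefined")
  c(x = cx / atot, y = cy / atot)
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' A point lying exactly on any ring boundary counts as inside: the
#' downstream exclusion rules target gross mislocations, so border contact
#' is never treated as evidence of error.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly A ring or list of rings in the same coordinate system.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  rings <- as_rings(poly)
  inside_count <- integer(length(px))
  on_edge <- logical(length(px))
  for (ring in rings) {
    code <- sp::point.in.polygon(px, py, ring$x, ring$y)
    on_edge <- on_edge | code >= 2
    inside_count <- inside_count + (code == 1)
  }
  on_edge | (inside_count %% 2L == 1L)
}

#' Intersection area of two polygons (planar)
#'
#' Exact boolean intersection via Vatti clipping (polyclip), then shoelace
#' area of the result.
#'
#' @param a,b Rings or lists of rings in the same planar coordinates.
#' @return Non-negative intersection area.
#' @export
intersection_area <- function(a, b) {
  inter <- polyclip::polyclip(as_rings(a), as_rings(b), op = "intersection")
  if (length(inter) == 0) return(0)
  abs(sum(vapply(inter, ring_area_signed, numeric(1))))
}

#' Intersection-over-union of two polygons (planar)
#'
#' @param a,b Rings or lists of rings in the same planar coordinates.
#' @return IoU in \[0, 1\]; 0 for disjoint polygons.
#' @export
polygon_iou <- function(a, b) {
  i <- intersection_area(a, b)
  u <- polygon_area(a) + polygon_area(b) - i
  if (u <= 0) return(0)
  i / u
}

#' Convex hull of planar points
#'
#' @param x,y Numeric coordinate vectors (at least 3 non-collinear points).
#' @return A single counter-clockwise ring whose vertices are input points.
#' @export
convex_hull <- function(x, y) {
  if (length(x) < 3) stop("convex hull needs at least 3 points")
  idx <- grDevices::chull(x, y)
  ring <- ensure_ccw(list(x = x[idx], y = y[idx]))
  if (ring_area_signed(ring) <= 0)
    stop("degenerate geometry: points are collinear")
  ring
}

# Circumradius of a triangle given vertex coordinates.
circumradius <- function(x, y) {
  a <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2)
  b <- sqrt((x[3] - x[2])^2 + (y[3] - y[2])^2)
  d <- sqrt((x[1] - x[3])^2 + (y[1] - y[3])^2)
  area2 <- abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1]))
  if (area2 == 0) return(Inf)
  a * b * d / (2 * area2)
}

#' Alpha shape of planar points
#'
#' Union of the Delaunay triangles whose circumradius does not exceed
#' `alpha` (same unit as the coordinates). With a large alpha this converges
#' to the convex hull; small alphas follow concavities.
#'
#' @param x,y Numeric coordinate vectors.
#' @param alpha Positive circumradius bound in coordinate units.
#' @return A ring or list of rings (the shape may be disconnected).
#' @export
alpha_shape <- function(x, y, alpha) {
  if (length(x) < 3) stop("alpha shape needs at least 3 points")
  stopifnot(is.numeric(alpha), alpha > 0)
  tri <- deldir::triang.list(deldir::deldir(x, y, suppressMsge = TRUE))
  keep <- Filter(function(t) circumradius(t$x, t$y) <= alpha, tri)
  if (length(keep) == 0)
    stop("alpha too small: no Delaunay triangle has circumradius <= alpha")
  acc <- list(ensure_ccw(list(x = keep[[1]]$x, y = keep[[1]]$y)))
  for (t in keep[-1]) {
    acc <- polyclip::polyclip(acc, list(ensure_ccw(list(x = t$x, y = t$y))),
                              op = "union")
  }
  acc
}

# Project a WGS84 polygon's rings to Web Mercator metres.
project_polygon <- function(poly) {
  lapply(as_rings(poly), function(ring) {
    m <- mercator_project(ring$x, ring$y)
    list(x = m[, "x"], y = m[, "y"])
  })
}

# Inverse-project a planar polygon back to WGS84 degrees.
unproject_polygon <- function(poly) {
  lapply(as_rings(poly), function(ring) {
    ll <- mercator_unproject(ring$x, ring$y)
    list(x = ll[, "lon"], y = ll[, "lat"])
  })
}
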