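# Independent oracles and small fixture builders. The oracles deliberately
# avoid the package's own code paths: distances are computed with a direct
# haversine formula, hulls by gift wrapping, quantiles by hand.

# direct haversine, spherical Earth radius 6371.0088 km
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180; R <- 6371.0088
  dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# all-pairs k nearest neighbours by double loop
oracle_knn <- function(lon, lat, k, tie = seq_along(lon)) {
  n <- length(lon)
  k <- min(k, n - 1)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- oracle_haversine_km(lon[i], lat[i],
                                                      lon[j], lat[j])
    d[i] <- Inf
    o <- order(d, tie)[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[o]
  }
  list(index = idx, dist_km = dst)
}

# Jarvis-march (gift wrapping) convex hull, returns vertex indices CCW
oracle_gift_wrap <- function(x, y) {
  n <- length(x)
  start <- order(x, y)[1]           # lowest x, ties by y
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p) next
      cross <- (x[q] - x[p]) * (y[r] - y[p]) - (y[q] - y[p]) * (x[r] - x[p])
      if (cross > 0 ||
          (cross == 0 && (x[r] - x[p])^2 + (y[r] - y[p])^2 >
                         (x[q] - x[p])^2 + (y[q] - y[p])^2))
        q <- r
    }
    p <- q
    if (p == start) break
  }
  hull
}

# linear interpolation quantile of a sorted list, by hand (type 7)
oracle_quantile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# compare two rings as the same cyclic vertex sequence (either direction)
same_ring <- function(a, b, tol = 1e-9) {
  n <- length(a$x)
  if (length(b$x) != n) return(FALSE)
  for (dir in list(seq_len(n), rev(seq_len(n)))) {
    bx <- b$x[dir]; by <- b$y[dir]
    for (s in seq_len(n)) {
      rot <- c(s:n, seq_len(s - 1))[seq_len(n)]
      if (all(abs(bx[rot] - a$x) < tol) && all(abs(by[rot] - a$y) < tol))
        return(TRUE)
    }
  }
  FALSE
}

# geocoded-points fixture around a mid-latitude anchor; offsets in km
make_points <- function(dx_km, dy_km, ed, lat0 = 39.95, lon0 = -75.16,
                        conf = 50, type = "address_like") {
  km_per_deg <- 6371.0088 * pi / 180
  data.frame(
    city = "X", county = "X", state = "XX",
    street_address = sprintf("%d TEST ST", seq_along(dx_km)),
    ed_id = as.character(ed),
    row_index = seq_along(dx_km),
    lon = lon0 + dx_km / (km_per_deg * cos(lat0 * pi / 180)),
    lat = lat0 + dy_km / km_per_deg,
    confidence_radius_m = rep(conf, length.out = length(dx_km)),
    result_type = rep(type, length.out = length(dx_km)),
    stringsAsFactors = FALSE)
}

# unit-square-ish rectangle ring helper (planar)
rect_ring <- function(x0, y0, x1, y1) {
  list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# address table fixture for io tests
write_addr_csv <- function(path, rows) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
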