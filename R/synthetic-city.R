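# Synthetic ground-truth cities: district tessellations, addresses, graded
# overlay zones, county bounds, and a noisy geocoder.
#
# The simulator targets the statistical structure the reconstruction
# pipeline assumes — compact districts tiling a city, addresses clustered
# inside their district, a geocoder that sometimes misses, mislabels or
# grossly mislocates — not cartographic realism. Every layer is emitted in
# the formats the real pipeline reads, so end-to-end runs need no
# special-casing.

# Evaluate with a local RNG state: deterministic in `seed`, no effect on
# the caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Geocoder noise model
#'
#' Error phenomena the pipeline's filters and trims exist for: addresses
#' the geocoder cannot match, matches snapped to a road or neighbourhood
#' rather than an address, gross mislocations (a confident match on the
#' wrong, faraway feature), and small positional jitter.
#'
#' @param p_no_result,p_road_type,p_gross_error Per-address probabilities
#'   (mutually exclusive events; must sum to at most 1).
#' @param gross_error_km Range (min, max) of gross displacement, km.
#' @param jitter_sd_m SD of Gaussian positional noise on good results, m.
#' @param confidence_range_m Uniform range of the confidence radius for
#'   address-like results, m.
#' @param road_confidence_range_m Same for road-type results, m.
#' @return A noise-model list. All-zero defaults give an identity geocoder.
#' @export
noise_model <- function(p_no_result = 0, p_road_type = 0, p_gross_error = 0,
                        gross_error_km = c(10, 20), jitter_sd_m = 0,
                        confidence_range_m = c(0, 100),
                        road_confidence_range_m = c(250, 1000)) {
  stopifnot(p_no_result >= 0, p_road_type >= 0, p_gross_error >= 0,
            p_no_result + p_road_type + p_gross_error <= 1)
  list(p_no_result = p_no_result, p_road_type = p_road_type,
       p_gross_error = p_gross_error, gross_error_km = gross_error_km,
       jitter_sd_m = jitter_sd_m, confidence_range_m = confidence_range_m,
       road_confidence_range_m = road_confidence_range_m)
}

#' Synthetic city configuration
#'
#' @param seed Integer seed; the city is a deterministic function of it.
#' @param n_districts Number of ground-truth districts.
#' @param addresses_per_district Addresses per district (scalar, or
#'   c(min, max) for a uniform draw per district).
#' @param city_extent_km Side length of the square city, km. The default
#'   (with the default district count) keeps each district's diameter
#'   under the 2 km urban trimming radius, as for dense 1940 cities.
#' @param tessellation `"grid"` (rectangular cells) or `"voronoi"`.
#' @param grade_proportions Named probabilities over grades A-D used to
#'   grade districts; default roughly mirrors large-city HOLC maps (C and
#'   D dominate).
#' @param aligned_overlay If TRUE (default), overlay zones are unions of
#'   whole districts, so each district lies wholly in one grade zone.
#' @param noise A [noise_model()]; default noiseless.
#' @param origin Named c(lon, lat) of the city's southwest corner; the
#'   default is a mid-latitude US location, so degree arithmetic and true
#'   ground distance differ materially.
#' @param county_buffer_km Buffer of the county rectangle around the city.
#' @param duplicate_rate Fraction of extra duplicated address rows emitted
#'   (exercises first-occurrence deduplication).
#' @return Config list for [generate_city()].
#' @export
synthetic_city_config <- function(seed = 1L, n_districts = 25L,
                                  addresses_per_district = 30L,
                                  city_extent_km = 6,
                                  tessellation = c("grid", "voronoi"),
                                  grade_proportions = c(A = 0.05, B = 0.15,
                                                        C = 0.40, D = 0.40),
                                  aligned_overlay = TRUE,
                                  noise = noise_model(),
                                  origin = c(lon = -75.16, lat = 39.95),
                                  county_buffer_km = 5,
                                  duplicate_rate = 0) {
  stopifnot(n_districts >= 1, all(addresses_per_district >= 1),
            city_extent_km > 0)
  list(seed = as.integer(seed), n_districts = as.integer(n_districts),
       addresses_per_district = addresses_per_district,
       city_extent_km = city_extent_km,
       tessellation = match.arg(tessellation),
       grade_proportions = grade_proportions,
       aligned_overlay = aligned_overlay, noise = noise, origin = origin,
       county_buffer_km = county_buffer_km,
       duplicate_rate = duplicate_rate)
}

# Local planar km offsets from the city origin -> WGS84, via Web Mercator
# anchored at the origin latitude (ground metres scaled by 1/cos(lat0)).
local_km_to_lonlat <- function(x_km, y_km, origin) {
  m0 <- mercator_project(origin[["lon"]], origin[["lat"]])
  s <- 1 / cos(origin[["lat"]] * pi / 180)
  ll <- mercator_unproject(m0[, "x"] + x_km * 1000 * s,
                           m0[, "y"] + y_km * 1000 * s)
  list(lon = unname(ll[, "lon"]), lat = unname(ll[, "lat"]))
}

local_ring_to_lonlat <- function(x_km, y_km, origin) {
  ll <- local_km_to_lonlat(x_km, y_km, origin)
  ensure_ccw(list(x = ll$lon, y = ll$lat))
}

# grid factorisation: rows x cols = n with rows the largest divisor <= sqrt
grid_dims <- function(n) {
  rows <- floor(sqrt(n))
  while (rows > 1 && n %% rows != 0) rows <- rows - 1
  c(rows = rows, cols = n %/% rows)
}

STREET_NAMES <- c("MAIN", "OAK", "ELM", "WALNUT", "CHESTNUT", "MARKET",
                  "SPRUCE", "PINE", "CEDAR", "LOCUST", "VINE", "RACE",
                  "ARCH", "CHERRY", "WILLOW", "POPLAR")

#' Generate a synthetic city
#'
#' Tessellates the city square into ground-truth district polygons, samples
#' addresses uniformly inside each district, grades districts and builds
#' overlay zones, and draws the county rectangle. Deterministic in
#' `cfg$seed`.
#'
#' @param cfg Configuration from [synthetic_city_config()].
#' @return A `synthetic_city` object: `config`, `districts` (data.frame
#'   ed_id, grade, n_addresses), `district_polygons` (named list, WGS84),
#'   `addresses` (GRF-style rows with true coordinates), `overlay`
#'   (geometry + grade), `county`, `county_name`, `ed_to_county`, `truth`
#'   (address key to true coordinate).
#' @export
generate_city <- function(cfg = synthetic_city_config()) {
  with_seed(cfg$seed, {
    ext <- cfg$city_extent_km
    n <- cfg$n_districts
    eds <- as.character(seq_len(n))
    polys_km <- vector("list", n)
    if (cfg$tessellation == "grid") {
      dims <- grid_dims(n)
      w <- ext / dims[["cols"]]; h <- ext / dims[["rows"]]
      k <- 0L
      for (r in seq_len(dims[["rows"]])) {
        for (cc in seq_len(dims[["cols"]])) {
          k <- k + 1L
          polys_km[[k]] <- list(x = c((cc - 1) * w, cc * w, cc * w, (cc - 1) * w),
                                y = c((r - 1) * h, (r - 1) * h, r * h, r * h))
        }
      }
    } else {
      sx <- stats::runif(n, 0, ext); sy <- stats::runif(n, 0, ext)
      dd <- deldir::deldir(sx, sy, rw = c(0, ext, 0, ext),
                           suppressMsge = TRUE)
      tiles <- deldir::tile.list(dd)
      for (k in seq_len(n)) polys_km[[k]] <- list(x = tiles[[k]]$x,
                                                  y = tiles[[k]]$y)
    }
    if (any(vapply(polys_km, function(p) abs(ring_area_signed(p)),
                   numeric(1)) <= 0))
      stop("infeasible config: zero-area district cell")

    # addresses uniform within each district (rejection from the bbox)
    napd <- cfg$addresses_per_district
    n_addr <- if (length(napd) == 2)
      sample(napd[1]:napd[2], n, replace = TRUE) else rep(napd, n)
    house <- 0L
    addr_rows <- vector("list", n)
    for (k in seq_len(n)) {
      p <- polys_km[[k]]
      got_x <- numeric(0); got_y <- numeric(0)
      while (length(got_x) < n_addr[k]) {
        m <- 4L * (n_addr[k] - length(got_x)) + 8L
        cx <- stats::runif(m, min(p$x), max(p$x))
        cy <- stats::runif(m, min(p$y), max(p$y))
        inside <- point_in_polygon(cx, cy, p)
        got_x <- c(got_x, cx[inside]); got_y <- c(got_y, cy[inside])
      }
      got_x <- got_x[seq_len(n_addr[k])]; got_y <- got_y[seq_len(n_addr[k])]
      street <- sample(STREET_NAMES, 1)
      nums <- house + seq_len(n_addr[k]); house <- house + n_addr[k]
      ll <- local_km_to_lonlat(got_x, got_y, cfg$origin)
      addr_rows[[k]] <- data.frame(
        city = "SIMVILLE", county = "SIM COUNTY", state = "SV",
        street_address = sprintf("%d %s ST", nums, street),
        ed_id = eds[k], true_lon = ll$lon, true_lat = ll$lat,
        stringsAsFactors = FALSE)
    }
    addresses <- do.call(rbind, addr_rows)
    if (cfg$duplicate_rate > 0) {
      ndup <- floor(cfg$duplicate_rate * nrow(addresses))
      if (ndup > 0)
        addresses <- rbind(addresses,
                           addresses[sample(nrow(addresses), ndup), ])
    }
    addresses$row_index <- seq_len(nrow(addresses))
    rownames(addresses) <- NULL

    # grades and overlay zones
    grades <- sample(names(cfg$grade_proportions), n, replace = TRUE,
                     prob = cfg$grade_proportions)
    district_polygons <- stats::setNames(
      lapply(polys_km, function(p)
        list(local_ring_to_lonlat(p$x, p$y, cfg$origin))), eds)
    if (cfg$aligned_overlay) {
      zg <- sort(unique(grades))
      geometry <- lapply(zg, function(g) {
        cells <- lapply(which(grades == g),
                        function(k) ensure_ccw(polys_km[[k]]))
        u <- Reduce(function(a, b) polyclip::polyclip(a, list(b), "union"),
                    cells[-1], list(cells[[1]]))
        lapply(u, function(r) local_ring_to_lonlat_raw(r, cfg$origin))
      })
      overlay <- list(geometry = geometry, grade = zg)
    } else {
      # vertical bands by grade proportion, independent of district lines
      pr <- cfg$grade_proportions / sum(cfg$grade_proportions)
      edges <- c(0, cumsum(pr)) * ext
      geometry <- lapply(seq_along(pr), function(i)
        list(local_ring_to_lonlat(
          c(edges[i], edges[i + 1], edges[i + 1], edges[i]),
          c(0, 0, ext, ext), cfg$origin)))
      overlay <- list(geometry = geometry, grade = names(pr))
    }

    b <- cfg$county_buffer_km
    county <- list(local_ring_to_lonlat(c(-b, ext + b, ext + b, -b),
                                        c(-b, -b, ext + b, ext + b),
                                        cfg$origin))
    districts <- data.frame(ed_id = eds, grade = grades,
                            n_addresses = n_addr, stringsAsFactors = FALSE)
    truth <- addresses[!duplicated(address_key(addresses)),
                       c("street_address", "true_lon", "true_lat")]
    structure(list(
      config = cfg, districts = districts,
      district_polygons = district_polygons, addresses = addresses,
      overlay = overlay, county = county, county_name = "SIM COUNTY",
      ed_to_county = stats::setNames(rep("SIM COUNTY", n), eds),
      truth = truth), class = "synthetic_city")
  })
}

# ring in local km -> WGS84 keeping vertex order (used on polyclip output,
# whose orientation already encodes holes)
local_ring_to_lonlat_raw <- function(ring, origin) {
  ll <- local_km_to_lonlat(ring$x, ring$y, origin)
  list(x = ll$lon, y = ll$lat)
}

#' Synthetic geocoder over a city's truth table
#'
#' Draws each address's fate once, up front, from the noise model:
#' no-result, road-type, gross mislocation (confident but far wrong), or a
#' good address-like result with optional jitter. Deterministic in `seed`
#' and independent of query order. The returned object counts queries
#' (`$n_queries()`), which the cache contract tests rely on.
#'
#' @param city A `synthetic_city`.
#' @param noise A [noise_model()]; defaults to the city's configured one.
#' @param seed Integer seed for the error draws.
#' @return A geocoder object with `query(address)`.
#' @export
make_geocoder <- function(city, noise = city$config$noise,
                          seed = city$config$seed + 1L) {
  truth <- city$truth
  n <- nrow(truth)
  res <- with_seed(seed, {
    u <- stats::runif(n)
    fate <- ifelse(u < noise$p_no_result, "no_result",
            ifelse(u < noise$p_no_result + noise$p_road_type, "road",
            ifelse(u < noise$p_no_result + noise$p_road_type +
                     noise$p_gross_error, "gross", "ok")))
    lat0 <- truth$true_lat
    km_per_deg <- EARTH_RADIUS_KM * pi / 180
    jit_lon <- stats::rnorm(n, 0, noise$jitter_sd_m / 1000) /
      (km_per_deg * cos(lat0 * pi / 180))
    jit_lat <- stats::rnorm(n, 0, noise$jitter_sd_m / 1000) / km_per_deg
    gmag <- stats::runif(n, noise$gross_error_km[1], noise$gross_error_km[2])
    gdir <- stats::runif(n, 0, 2 * pi)
    glon <- gmag * cos(gdir) / (km_per_deg * cos(lat0 * pi / 180))
    glat <- gmag * sin(gdir) / km_per_deg
    conf_ok <- stats::runif(n, noise$confidence_range_m[1],
                            noise$confidence_range_m[2])
    conf_rd <- stats::runif(n, noise$road_confidence_range_m[1],
                            noise$road_confidence_range_m[2])
    data.frame(
      key = normalize_street(truth$street_address),
      lon = ifelse(fate == "gross", truth$true_lon + glon,
                   truth$true_lon + jit_lon),
      lat = ifelse(fate == "gross", truth$true_lat + glat,
                   truth$true_lat + jit_lat),
      confidence_radius_m = ifelse(fate == "road", conf_rd, conf_ok),
      result_type = ifelse(fate == "no_result", "no_result",
                    ifelse(fate == "road", "road", "address_like")),
      stringsAsFactors = FALSE)
  })
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(res$key[i], res[i, ], envir = lookup)
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  structure(list(
    query = function(address) {
      counter$n <- counter$n + 1L
      hit <- get0(normalize_street(address), envir = lookup,
                  inherits = FALSE)
      if (is.null(hit) || hit$result_type == "no_result")
        return(no_result_row())
      list(lat = hit$lat, lon = hit$lon,
           confidence_radius_m = hit$confidence_radius_m,
           result_type = hit$result_type)
    },
    n_queries = function() counter$n), class = "geocoder")
}

#' Write a synthetic city's layers to disk
#'
#' Emits every layer in the formats the pipeline reads: the address table
#' as CSV, true districts / overlay / county as GeoJSON, and a geocode
#' cache (from running the city's geocoder over all addresses) so that a
#' later build can run fully offline with [cache_only_geocoder()].
#'
#' @param city A `synthetic_city`.
#' @param dir Output directory (created if needed).
#' @param geocoder Geocoder used to fill the cache; defaults to the city's.
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir, geocoder = make_geocoder(city)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  addr <- city$addresses[, c("city", "county", "state", "street_address",
                             "ed_id")]
  utils::write.csv(addr, file.path(dir, "addresses.csv"), row.names = FALSE)
  write_geojson(unname(city$district_polygons[city$districts$ed_id]),
                city$districts[, c("ed_id", "grade")],
                file.path(dir, "true_districts.geojson"))
  write_geojson(city$overlay$geometry,
                data.frame(grade = city$overlay$grade,
                           stringsAsFactors = FALSE),
                file.path(dir, "overlay.geojson"))
  write_geojson(list(city$county),
                data.frame(county = city$county_name,
                           stringsAsFactors = FALSE),
                file.path(dir, "county.geojson"))
  cache_path <- file.path(dir, "geocode_cache.tsv")
  if (file.exists(cache_path)) file.remove(cache_path)
  invisible(geocode_batch(city$addresses, geocoder,
                          cache_path = cache_path))
  invisible(dir)
}

#' Recovery of true district polygons by the reconstruction
#'
#' Per-district intersection-over-union between the true polygon and the
#' reconstructed virtual polygon (Web Mercator plane), with reasons for
#' districts the pipeline dropped.
#'
#' @param city A `synthetic_city`.
#' @param vd A `virtual_districts` object built from the city's addresses.
#' @return A list: `per_district` (ed_id, iou, reason), `mean_iou`,
#'   `median_iou` over recovered districts, `n_recovered`.
#' @export
evaluate_recovery <- function(city, vd) {
  eds <- city$districts$ed_id
  iou <- rep(NA_real_, length(eds))
  reason <- rep(NA_character_, length(eds))
  for (i in seq_along(eds)) {
    vp <- vd$polygons[[eds[i]]]
    if (is.null(vp)) {
      r <- vd$audit$drop_reason[vd$audit$ed_id == eds[i]]
      reason[i] <- if (length(r) == 1 && !is.na(r)) r else "not_built"
      next
    }
    iou[i] <- polygon_iou(project_polygon(city$district_polygons[[eds[i]]]),
                          project_polygon(vp))
  }
  rec <- iou[!is.na(iou)]
  list(per_district = data.frame(ed_id = eds, iou = iou, reason = reason,
                                 stringsAsFactors = FALSE),
       mean_iou = mean(rec), median_iou = stats::median(rec),
       n_recovered = length(rec))
}
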