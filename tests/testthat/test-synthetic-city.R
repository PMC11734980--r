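test_that("city generation is a deterministic function of the seed", {
  cfg <- synthetic_city_config(seed = 21, n_districts = 9,
                               addresses_per_district = 12,
                               city_extent_km = 3)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$addresses, b$addresses)
  expect_identical(a$district_polygons, b$district_polygons)
  expect_identical(a$districts$grade, b$districts$grade)
  c2 <- generate_city(synthetic_city_config(seed = 22, n_districts = 9,
                                            addresses_per_district = 12,
                                            city_extent_km = 3))
  expect_false(identical(a$addresses$street_address,
                         c2$addresses$street_address))
})

test_that("grid cities place every address inside its own district cell", {
  city <- generate_city(synthetic_city_config(seed = 2, n_districts = 9,
                                              addresses_per_district = 20,
                                              city_extent_km = 3))
  expect_equal(nrow(city$addresses), 180)
  expect_equal(length(city$district_polygons), 9)
  for (e in city$districts$ed_id) {
    rows <- city$addresses[city$addresses$ed_id == e, ]
    expect_true(all(point_in_polygon(rows$true_lon, rows$true_lat,
                                     city$district_polygons[[e]])))
  }
  # districts are non-overlapping: pairwise intersection areas vanish
  m <- lapply(city$district_polygons, function(p)
    lapply(p, function(r) {
      xy <- mercator_project(r$x, r$y)
      list(x = xy[, "x"], y = xy[, "y"])
    }))
  areas <- vapply(m, polygon_area, numeric(1))
  for (i in 1:8) for (j in (i + 1):9)
    expect_lt(intersection_area(m[[i]], m[[j]]), 1e-6 * min(areas))
})

test_that("voronoi tessellations are valid and cover their addresses", {
  city <- generate_city(synthetic_city_config(seed = 5, n_districts = 12,
                                              addresses_per_district = 8,
                                              city_extent_km = 4,
                                              tessellation = "voronoi"))
  expect_equal(length(city$district_polygons), 12)
  for (e in city$districts$ed_id) {
    rows <- city$addresses[city$addresses$ed_id == e, ]
    expect_true(all(point_in_polygon(rows$true_lon, rows$true_lat,
                                     city$district_polygons[[e]])))
  }
})

test_that("aligned overlays contain each district wholly in one grade zone", {
  city <- generate_city(synthetic_city_config(seed = 4, n_districts = 16,
                                              addresses_per_district = 5,
                                              city_extent_km = 4))
  for (i in seq_len(nrow(city$districts))) {
    e <- city$districts$ed_id[i]
    g <- city$districts$grade[i]
    zone <- city$overlay$geometry[[match(g, city$overlay$grade)]]
    dp <- project_polygon(city$district_polygons[[e]])
    a_d <- polygon_area(dp)
    a_i <- intersection_area(dp, project_polygon(zone))
    expect_equal(a_i / a_d, 1, tolerance = 1e-6)
  }
})

test_that("duplicate emission is exercised and deduplication undoes it", {
  city <- generate_city(synthetic_city_config(seed = 6, n_districts = 4,
                                              addresses_per_district = 10,
                                              city_extent_km = 2,
                                              duplicate_rate = 0.2))
  expect_equal(nrow(city$addresses), 48)
  expect_equal(nrow(deduplicate_first_occurrence(city$addresses)), 40)
})

test_that("noise-event frequencies match their probabilities binomially", {
  n <- 10000
  city <- generate_city(synthetic_city_config(
    seed = 13, n_districts = 100, addresses_per_district = 100,
    city_extent_km = 10,
    noise = noise_model(p_no_result = 0.05, p_road_type = 0.10,
                        p_gross_error = 0.08, jitter_sd_m = 15)))
  geo <- geocode_batch(city$addresses, make_geocoder(city))
  disp <- haversine_km(geo$lon, geo$lat,
                       city$addresses$true_lon, city$addresses$true_lat)
  obs <- c(no_result = sum(geo$result_type == "no_result"),
           road = sum(geo$result_type == "road"),
           gross = sum(!is.na(disp) & disp >= 10))
  p <- c(0.05, 0.10, 0.08)
  for (i in 1:3) {
    sd3 <- 3 * sqrt(n * p[i] * (1 - p[i]))
    expect_lt(abs(obs[i] - n * p[i]), sd3)
  }
  # gross displacements land in the configured magnitude range
  expect_true(all(disp[!is.na(disp) & disp >= 10] <= 20.5))
})

test_that("an all-gross geocoder displaces every point by at least 10 km", {
  city <- generate_city(synthetic_city_config(
    seed = 3, n_districts = 4, addresses_per_district = 10,
    city_extent_km = 2,
    noise = noise_model(p_gross_error = 1, gross_error_km = c(10, 20))))
  geo <- geocode_batch(city$addresses, make_geocoder(city))
  disp <- haversine_km(geo$lon, geo$lat,
                       city$addresses$true_lon, city$addresses$true_lat)
  expect_true(all(disp >= 9.9))
})

test_that("recovery scoring follows intersection-over-union arithmetic", {
  sq <- rect_ring(0, 0, 1, 1)
  expect_equal(polygon_iou(sq, sq), 1)
  expect_equal(polygon_iou(sq, rect_ring(3, 3, 4, 4)), 0)
  expect_equal(polygon_iou(sq, rect_ring(0, 0.5, 1, 1.5)), 1 / 3)
})

test_that("city layers written to disk feed the pipeline back unchanged", {
  city <- generate_city(synthetic_city_config(seed = 9, n_districts = 4,
                                              addresses_per_district = 10,
                                              city_extent_km = 2))
  dir <- withr::local_tempdir()
  write_city(city, dir)
  addr <- read_address_table(file.path(dir, "addresses.csv"))
  expect_equal(nrow(addr), nrow(city$addresses))
  ov <- read_geojson(file.path(dir, "overlay.geojson"))
  expect_setequal(ov$properties$grade, unique(city$districts$grade))
  geo <- geocode_batch(addr,
                       cache_only_geocoder(file.path(dir,
                                                     "geocode_cache.tsv")))
  expect_equal(geo$lat, city$addresses$true_lat, tolerance = 1e-12)
})
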