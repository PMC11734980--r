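test_that("Web Mercator projection matches its closed form and inverts", {
  expect_equal(as.numeric(mercator_project(0, 0)), c(0, 0))
  # one degree along the equator: 2 * pi * 6378137 / 360 metres
  m <- mercator_project(c(0, 1), c(0, 0))
  expect_equal(as.numeric(m[2, "x"] - m[1, "x"]), 111319.4908,
               tolerance = 1e-4)
  set.seed(1)
  lon <- runif(1000, -125, -66); lat <- runif(1000, 24, 49)
  m <- mercator_project(lon, lat)
  ll <- mercator_unproject(m[, "x"], m[, "y"])
  expect_equal(unname(ll[, "lon"]), lon, tolerance = 1e-9)
  expect_equal(unname(ll[, "lat"]), lat, tolerance = 1e-9)
  expect_error(mercator_project(0, 86), "Mercator")
})

test_that("convex hulls equal the gift-wrapping oracle vertex-for-vertex", {
  set.seed(9)
  for (n in c(5, 20, 100)) {
    x <- runif(n); y <- runif(n)
    ring <- convex_hull(x, y)
    idx <- oracle_gift_wrap(x, y)
    expect_true(same_ring(ring, list(x = x[idx], y = y[idx])))
  }
})

test_that("hulls contain their inputs and take the expected shapes", {
  tri <- convex_hull(c(0, 2, 1), c(0, 0, 2))
  expect_equal(length(tri$x), 3)
  expect_equal(polygon_area(tri), 2)
  # square corners plus centre: the square, centre strictly inside
  sq <- convex_hull(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  expect_equal(length(sq$x), 4)
  expect_equal(polygon_area(sq), 1)
  expect_true(point_in_polygon(0.5, 0.5, sq))
  # 50 random points in a disc: all inside, area below the disc's
  set.seed(3)
  th <- runif(50, 0, 2 * pi); r <- sqrt(runif(50))
  hull <- convex_hull(r * cos(th), r * sin(th))
  expect_true(all(point_in_polygon(r * cos(th), r * sin(th), hull)))
  expect_lt(polygon_area(hull), pi)
  expect_error(convex_hull(c(0, 1, 2), c(0, 1, 2)), "collinear")
})

test_that("hull area is invariant under point permutation", {
  set.seed(4)
  x <- runif(40); y <- runif(40)
  a0 <- polygon_area(convex_hull(x, y))
  for (rep in 1:5) {
    p <- sample(40)
    expect_equal(polygon_area(convex_hull(x[p], y[p])), a0)
  }
})

test_that("planar polygon centroids follow area-weighted decomposition", {
  expect_equal(polygon_centroid_planar(rect_ring(0, 0, 1, 1)),
               c(x = 0.5, y = 0.5))
  tri <- list(x = c(0, 3, 0), y = c(0, 0, 3))
  expect_equal(polygon_centroid_planar(tri), c(x = 1, y = 1))
  # L from a 2x1 base plus a 1x1 block: centroid (2.5/3, 2.5/3)
  ell <- list(x = c(0, 2, 2, 1, 1, 0), y = c(0, 0, 1, 1, 2, 2))
  expect_equal(polygon_centroid_planar(ell),
               c(x = 2.5 / 3, y = 2.5 / 3))
})

test_that("geographic hulls round-trip through the projection", {
  pts <- make_points(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5), "1")
  hull <- build_hull(pts$lon, pts$lat)
  ring <- hull[[1]]
  expect_equal(length(ring$x), 4)
  # containment up to the projection round-trip: test against the hull
  # dilated by a hair about its centroid
  ctr <- polygon_centroid(hull)
  grown <- list(list(x = ctr[["lon"]] + (ring$x - ctr[["lon"]]) * (1 + 1e-9),
                     y = ctr[["lat"]] + (ring$y - ctr[["lat"]]) * (1 + 1e-9)))
  expect_true(all(point_in_polygon(pts$lon, pts$lat, grown)))
  ctr <- polygon_centroid(hull)
  expect_true(point_in_polygon(ctr["lon"], ctr["lat"], hull))
  expect_error(build_hull(pts$lon[1:2], pts$lat[1:2]), "3 points")
})

test_that("alpha shapes nest inside the convex hull and follow concavity", {
  set.seed(12)
  # a C-shaped point cloud: annulus sector
  th <- runif(300, 0.4 * pi, 1.6 * pi)
  r <- runif(300, 0.7, 1)
  x <- r * cos(th); y <- r * sin(th)
  ch <- convex_hull(x, y)
  ash <- alpha_shape(x, y, 0.25)
  a_alpha <- polygon_area(ash)
  expect_lt(a_alpha, polygon_area(ch))
  # alpha shape roughly matches the sector's true area
  true_area <- 0.5 * (1.2 * pi) * (1^2 - 0.7^2)
  expect_lt(abs(a_alpha - true_area) / true_area, 0.25)
  expect_error(alpha_shape(x, y, 1e-6), "alpha")
})

test_that("intersection areas and IoU follow rectangle arithmetic", {
  a <- rect_ring(0, 0, 1, 1)
  b <- rect_ring(0.5, 0, 1.5, 1)       # overlap area 0.5, union 1.5
  expect_equal(intersection_area(a, b), 0.5)
  expect_equal(polygon_iou(a, b), 1 / 3)
  expect_equal(polygon_iou(a, a), 1)
  expect_equal(polygon_iou(a, rect_ring(5, 5, 6, 6)), 0)
})

test_that("noiseless reconstruction recovers true districts with IoU >= 0.5", {
  ious <- numeric(0)
  for (s in 1:3) {
    city <- generate_city(synthetic_city_config(
      seed = s, n_districts = 9, addresses_per_district = 25,
      city_extent_km = 3))
    res <- run_pipeline(city)
    ious <- c(ious, res$recovery$mean_iou)
  }
  expect_true(all(!is.na(ious)))
  expect_gte(mean(ious), 0.5)
})
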