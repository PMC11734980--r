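test_that("predominance assignment picks the largest intersected grade", {
  district <- rect_ring(-75.20, 39.90, -75.10, 39.95)
  overlay <- list(
    geometry = list(list(rect_ring(-75.20, 39.80, -75.13, 40.00)),  # 70%
                    list(rect_ring(-75.13, 39.80, -75.05, 40.00))), # 30%
    grade = c("C", "D"))
  expect_equal(assign_grade(district, overlay), "C")
  # fully inside one zone
  expect_equal(assign_grade(rect_ring(-75.18, 39.91, -75.17, 39.92),
                            overlay), "C")
  # intersecting nothing
  expect_true(is.na(assign_grade(rect_ring(-74, 40.5, -73.9, 40.6),
                                 overlay)))
})

test_that("exact area ties resolve to the more hazardous grade", {
  district <- rect_ring(-75.20, 39.90, -75.10, 39.95)
  zone <- list(rect_ring(-75.30, 39.80, -75.00, 40.00))
  # identical zone geometry under two grades: intersected areas exactly tie
  half <- list(geometry = list(zone, zone), grade = c("B", "C"))
  expect_equal(assign_grade(district, half), "C")
  half$grade <- c("D", "A")
  expect_equal(assign_grade(district, half), "D")
  # ungraded zones participate and can win
  half$grade <- c("D", "ungraded")
  expect_equal(assign_grade(district, half), "ungraded")
})

test_that("grade assignment is invariant to overlay polygon order", {
  district <- rect_ring(-75.20, 39.90, -75.10, 39.95)
  geom <- list(list(rect_ring(-75.20, 39.80, -75.16, 40.00)),
               list(rect_ring(-75.16, 39.80, -75.13, 40.00)),
               list(rect_ring(-75.13, 39.80, -75.05, 40.00)))
  grades <- c("A", "D", "B")
  g0 <- assign_grade(district, list(geometry = geom, grade = grades))
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(assign_grade(district, list(geometry = geom[p],
                                             grade = grades[p])), g0)
  }
})

test_that("virtual centroids pair with containing real polygons by name", {
  vd <- structure(list(
    districts = data.frame(
      ed_id = c("1", "2", "3"), city = "X", n_points = 5L,
      centroid_lon = c(-75.15, -75.05, -74.50),
      centroid_lat = c(39.92, 39.92, 39.92),
      grade = c("C", "D", "B"), stringsAsFactors = FALSE),
    polygons = list()), class = "virtual_districts")
  real <- list(
    geometry = list(list(rect_ring(-75.2, 39.9, -75.1, 39.95)),
                    list(rect_ring(-75.1, 39.9, -75.0, 39.95))),
    ed_id = c("1", "-2"), grade = c("C", "C"))
  pairs <- pair_virtual_to_real(vd, real)
  expect_equal(pairs$real_id, c("1", "2", NA))
  expect_equal(pairs$name_match, c(TRUE, TRUE, FALSE))
  # precedence: real grade wins where present, else virtual carried
  expect_equal(pairs$resolved_grade, c("C", "C", "B"))
  expect_length(attr(pairs, "unpaired_real"), 0)
})

test_that("overlapping reference polygons resolve by name then area", {
  vd <- structure(list(
    districts = data.frame(
      ed_id = "9", city = "X", n_points = 5L,
      centroid_lon = -75.15, centroid_lat = 39.92,
      grade = "C", stringsAsFactors = FALSE),
    polygons = list()), class = "virtual_districts")
  big <- list(rect_ring(-75.3, 39.8, -75.0, 40.0))
  small <- list(rect_ring(-75.2, 39.9, -75.1, 39.95))
  # name match present among the overlapping candidates
  real <- list(geometry = list(big, small), ed_id = c("8", "9"))
  expect_equal(pair_virtual_to_real(vd, real)$real_id, "9")
  # no name match: smallest area wins, with a warning
  real2 <- list(geometry = list(big, small), ed_id = c("7", "8"))
  expect_warning(p2 <- pair_virtual_to_real(vd, real2), "overlapping")
  expect_equal(p2$real_id, "8")
})

test_that("resolve_grade applies real-over-virtual binary precedence", {
  expect_equal(resolve_grade("C", "B"), "B")
  expect_equal(resolve_grade("D", NA), "D")
  expect_equal(resolve_grade("A", "A"), "A")
  expect_equal(resolve_grade(c("C", "D"), c("B", NA)), c("B", "D"))
})

test_that("concordance arithmetic on toy tables is exact", {
  m <- matrix(0L, 4, 4)
  m[1:2, 1:2] <- 1L                      # 2x2 block of ones: 50% concordant
  ct <- concordance_table(m)
  expect_equal(ct$total_pairs, 4)
  expect_equal(ct$pct_concordant, 50)
  expect_equal(unname(ct$grade_distance), c(2, 2, 0, 0))
  all_diag <- diag(c(3L, 4L, 5L, 6L))
  expect_equal(concordance_table(all_diag)$pct_concordant, 100)
  # pairs-frame route agrees with the matrix route
  pairs <- data.frame(virtual_grade = c("A", "A", "B", "B"),
                      real_grade = c("A", "B", "A", "B"))
  expect_equal(concordance_table(pairs)$counts, ct$counts)
  expect_error(concordance_table(
    data.frame(virtual_grade = NA_character_,
               real_grade = NA_character_)), "no pairs")
})

test_that("grade-distance histogram is conserved and traces the diagonal", {
  set.seed(8)
  m <- matrix(sample(0:50, 16), 4, 4)
  ct <- concordance_table(m)
  expect_equal(sum(ct$grade_distance), ct$total_pairs)
  expect_equal(unname(ct$grade_distance["0"]), sum(diag(m)))
})

test_that("marginal percentages recompute from frequencies", {
  gm <- grade_marginals(c(A = 10, B = 30, C = 40, D = 20))
  expect_equal(gm$percent, c(10, 30, 40, 20))
  gm2 <- grade_marginals(c("A", "B", "B", NA, "D"))
  expect_equal(gm2$frequency[gm2$grade == "B"], 2)
  expect_equal(sum(gm2$percent), 100)
})
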