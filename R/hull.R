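# Bounding polygons of trimmed districts.
#
# Points are projected to Web Mercator, the hull drawn in the plane
# (convex by default; an alpha shape when a finite circumradius bound is
# configured), and the ring inverse-projected to WGS84. Hull vertices are
# input points exactly — no buffering or smoothing — so the polygon is the
# minimum bounding polygon of the retained addresses.

#' Bounding polygon of a set of geographic points
#'
#' @param lon,lat Point coordinates, decimal degrees (WGS84); at least 3
#'   non-collinear points.
#' @param alpha `"convex"` for the convex hull (default; reproducible with
#'   no free parameter), or a positive number: the alpha-shape circumradius
#'   bound in metres (Web Mercator plane).
#' @return A polygon (ring or list of rings) in WGS84, exterior rings
#'   counter-clockwise.
#' @export
build_hull <- function(lon, lat, alpha = "convex") {
  if (length(lon) < 3) stop("degenerate geometry: fewer than 3 points")
  m <- mercator_project(lon, lat)
  planar <- if (identical(alpha, "convex")) {
    list(convex_hull(m[, "x"], m[, "y"]))
  } else {
    as_rings(alpha_shape(m[, "x"], m[, "y"], alpha))
  }
  unproject_polygon(planar)
}

#' Geometric centroid of a WGS84 polygon
#'
#' Area-weighted centroid computed in the Web Mercator plane and
#' inverse-projected.
#'
#' @param poly Polygon (ring or list of rings) in WGS84.
#' @return Named numeric `c(lon, lat)`.
#' @export
polygon_centroid <- function(poly) {
  ctr <- polygon_centroid_planar(project_polygon(poly))
  ll <- mercator_unproject(ctr["x"], ctr["y"])
  c(lon = unname(ll[, "lon"]), lat = unname(ll[, "lat"]))
}

# Assemble VirtualDistrict records from a trim result. Districts whose
# retained points are collinear (hull degenerate) are dropped here with a
# reason code, mirroring the upstream drop bookkeeping.
make_virtual_districts <- function(trimmed, city = "", alpha = "convex") {
  pts <- trimmed$points
  eds <- unique(normalize_ed_id(pts$ed_id))
  polys <- list()
  rows <- list()
  status <- trimmed$status
  audit <- trimmed$audit
  for (e in eds) {
    idx <- which(normalize_ed_id(pts$ed_id) == e)
    poly <- tryCatch(build_hull(pts$lon[idx], pts$lat[idx], alpha),
                     error = function(err) NULL)
    if (is.null(poly)) {
      r <- which(audit$ed_id == e)
      audit$valid[r] <- FALSE
      audit$drop_reason[r] <- "degenerate_hull"
      next
    }
    ctr <- polygon_centroid(poly)
    polys[[e]] <- poly
    rows[[e]] <- data.frame(
      ed_id = e, city = city, n_points = length(idx),
      centroid_lon = ctr["lon"], centroid_lat = ctr["lat"],
      stringsAsFactors = FALSE)
  }
  dropped_eds <- setdiff(eds, names(polys))
  if (length(dropped_eds) > 0) {
    drop_pts <- normalize_ed_id(pts$ed_id) %in% dropped_eds
    # reclassify those points in the conservation ledger
    retained_idx <- which(status == "retained")
    status[retained_idx[drop_pts]] <- "dropped_with_district"
    pts <- pts[!drop_pts, , drop = FALSE]
  }
  districts <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(ed_id = character(0), city = character(0),
               n_points = integer(0), centroid_lon = numeric(0),
               centroid_lat = numeric(0))
  rownames(districts) <- NULL
  list(districts = districts, polygons = polys, points = pts,
       status = status, audit = audit)
}
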