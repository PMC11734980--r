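# Weighted centroids and outlier trimming per putative district.
#
# Geocoding errors surface as points whose distance to the rest of their
# district's cluster is larger than expected. Each district is therefore
# reduced to the points near its weighted centroid through a fixed-order
# trimming pipeline: the IQR rule, then a hard 2 km radius, then a
# whole-district validity check on the minimum remaining distance. The
# centroid is computed once; there is no re-centring after trimming.

#' Weighted centroid of a point set
#'
#' Weight-weighted arithmetic mean of the coordinates, computed in Web
#' Mercator planar space and inverse-projected — at city scale this agrees
#' with spherical averaging to well below the trimming tolerances.
#'
#' @param lon,lat Coordinates in decimal degrees (WGS84).
#' @param weight Non-negative point weights; total must be positive.
#' @return Named numeric `c(lon, lat)`.
#' @export
weighted_centroid <- function(lon, lat, weight) {
  stopifnot(length(lon) == length(lat), length(lon) == length(weight),
            all(weight >= 0))
  w <- sum(weight)
  if (w <= 0) stop("total weight is zero: centroid undefined")
  m <- mercator_project(lon, lat)
  ll <- mercator_unproject(sum(m[, "x"] * weight) / w,
                           sum(m[, "y"] * weight) / w)
  c(lon = unname(ll[, "lon"]), lat = unname(ll[, "lat"]))
}

#' IQR-rule outlier trim on distances to centroid
#'
#' Retains points whose distance does not exceed Q3 + 1.5 * (Q3 - Q1),
#' with quartiles by linear interpolation between order statistics
#' (the standard type-7 convention).
#'
#' @param distances_km Per-point distances to the district centroid (km).
#' @return Logical keep-vector.
#' @export
iqr_trim <- function(distances_km) {
  if (length(distances_km) == 0) return(logical(0))
  q <- stats::quantile(distances_km, c(0.25, 0.75), names = FALSE, type = 7)
  distances_km <= q[2] + 1.5 * (q[2] - q[1])
}

#' Absolute-radius trim on distances to centroid
#'
#' Excludes points more than `max_km` from the centroid; a point at exactly
#' the radius is retained. The 2 km default is an urban-scale bound:
#' doubling the implied mean district area of the least dense large 1940
#' city gives roughly this radius.
#'
#' @param distances_km Per-point distances to the district centroid (km).
#' @param max_km Radius bound in kilometres.
#' @return Logical keep-vector.
#' @export
radius_trim <- function(distances_km, max_km = 2) {
  distances_km <= max_km
}

#' Whole-district validity check
#'
#' A district whose nearest retained point is further than the threshold
#' from the centroid (no address within a 1 km diameter, at defaults) is
#' judged a false cluster — typically a centroid stranded midway between
#' two erroneous sub-clusters — and dropped entirely.
#'
#' @param distances_km Post-trim distances to the centroid (km).
#' @param min_dist_threshold_m Threshold on the minimum distance, metres.
#' @return TRUE if the district is valid.
#' @export
district_validity <- function(distances_km, min_dist_threshold_m = 500) {
  length(distances_km) > 0 &&
    min(distances_km) <= min_dist_threshold_m / 1000
}

#' Trim all districts of a weighted point set
#'
#' Groups weighted points by district, computes each district's weighted
#' centroid and distance list, applies the IQR rule, then the radius rule,
#' then the validity check, and drops districts left with fewer than
#' `min_points` points (too few to bound a polygon). Every input point ends
#' in exactly one terminal category.
#'
#' @param weighted Geocoded data.frame with a `weight` column
#'   (see [add_weights()]).
#' @param max_radius_km Radius-trim bound (km).
#' @param validity_m Validity threshold on the minimum distance (m).
#' @param min_points Minimum retained points for a usable district.
#' @return A list with `points` (retained rows plus `dist_km` and
#'   district centroid columns), `status` (per input row: retained /
#'   trimmed_iqr / trimmed_radius / dropped_with_district), `audit`
#'   (per-district counts and drop reasons) and `centroids`.
#' @export
trim_districts <- function(weighted, max_radius_km = 2, validity_m = 500,
                           min_points = 3L) {
  stopifnot(!is.null(weighted$weight))
  n <- nrow(weighted)
  status <- rep(NA_character_, n)
  ed <- normalize_ed_id(weighted$ed_id)
  eds <- unique(ed)
  audit <- data.frame(ed_id = eds, n_input = NA_integer_,
                      n_after_iqr = NA_integer_,
                      n_after_radius = NA_integer_, valid = NA,
                      drop_reason = NA_character_,
                      centroid_lon = NA_real_, centroid_lat = NA_real_,
                      stringsAsFactors = FALSE)
  keep_rows <- integer(0)
  dist_keep <- numeric(0)
  for (r in seq_along(eds)) {
    idx <- which(ed == eds[r])
    audit$n_input[r] <- length(idx)
    if (sum(weighted$weight[idx]) <= 0) {
      status[idx] <- "dropped_with_district"
      audit$drop_reason[r] <- "zero_weight"
      audit$valid[r] <- FALSE
      next
    }
    ctr <- weighted_centroid(weighted$lon[idx], weighted$lat[idx],
                             weighted$weight[idx])
    audit$centroid_lon[r] <- ctr["lon"]; audit$centroid_lat[r] <- ctr["lat"]
    d <- haversine_km(weighted$lon[idx], weighted$lat[idx],
                      ctr["lon"], ctr["lat"])
    ki <- iqr_trim(d)
    status[idx[!ki]] <- "trimmed_iqr"
    audit$n_after_iqr[r] <- sum(ki)
    kr <- ki & radius_trim(d, max_radius_km)
    status[idx[ki & !kr]] <- "trimmed_radius"
    audit$n_after_radius[r] <- sum(kr)
    if (!district_validity(d[kr], validity_m)) {
      status[idx[kr]] <- "dropped_with_district"
      audit$valid[r] <- FALSE
      audit$drop_reason[r] <- "min_distance_exceeded"
      next
    }
    if (sum(kr) < min_points) {
      status[idx[kr]] <- "dropped_with_district"
      audit$valid[r] <- FALSE
      audit$drop_reason[r] <- "too_few_points"
      next
    }
    audit$valid[r] <- TRUE
    status[idx[kr]] <- "retained"
    keep_rows <- c(keep_rows, idx[kr])
    dist_keep <- c(dist_keep, d[kr])
  }
  ord <- order(keep_rows)           # restore input row order
  keep_rows <- keep_rows[ord]
  pts <- weighted[keep_rows, , drop = FALSE]
  pts$dist_km <- dist_keep[ord]
  list(points = pts, status = status, audit = audit,
       centroids = audit[!is.na(audit$centroid_lon),
                         c("ed_id", "centroid_lon", "centroid_lat")])
}
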