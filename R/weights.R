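# Same-district clustering weights from 10 nearest neighbours with
# exponential distance decay.
#
# Each geocoded address gets a weight in [0, n_neighbors]: the sum, over
# its nearest neighbours that carry the same enumeration-district marker,
# of exp(-k * distance_km). A point deep inside a dense same-ED cluster
# saturates near 10; a gross mislocation whose neighbours are all far or
# foreign scores near 0. The neighbour search is citywide — neighbours may
# come from other districts, which is what makes the same-ED proportion
# informative.

#' Weighting configuration
#'
#' @param k Exponential decay constant per kilometre. Default 5: a same-ED
#'   neighbour 200 m away contributes exp(-1) ~ 0.37, one 2 km away
#'   contributes exp(-10) ~ 4.5e-5.
#' @param n_neighbors Number of nearest neighbours considered. Default 10.
#' @return A weight configuration list.
#' @export
weight_config <- function(k = 5, n_neighbors = 10L) {
  stopifnot(k > 0, n_neighbors >= 1)
  list(k = k, n_neighbors = as.integer(n_neighbors))
}

#' k-nearest-neighbour sets by geodesic distance
#'
#' For every point, the `n_neighbors` nearest other points citywide by
#' haversine distance (spherical Earth, radius 6371.0088 km). With fewer
#' than `n_neighbors + 1` points, all other points are neighbours. Distance
#' ties are broken by ascending row order for determinism.
#'
#' @param geocoded Geocoded address data.frame with `lon`, `lat`, `ed_id`.
#' @param cfg Configuration from [weight_config()].
#' @return A list with matrices `index`, `dist_km`, `same_ed`
#'   (n x n_neighbors; NA-padded when fewer neighbours exist) plus the
#'   effective neighbour count `k_eff` per point.
#' @export
knn_neighbors <- function(geocoded, cfg = weight_config()) {
  n <- nrow(geocoded)
  if (n < 2) stop("need at least 2 points to define nearest neighbours")
  k <- min(cfg$n_neighbors, n - 1L)
  idx_mat <- matrix(NA_integer_, n, cfg$n_neighbors)
  dist_mat <- matrix(NA_real_, n, cfg$n_neighbors)
  tie <- if (!is.null(geocoded$row_index)) geocoded$row_index else seq_len(n)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d <- dist_matrix_km(geocoded$lon[rows], geocoded$lat[rows],
                        geocoded$lon, geocoded$lat)
    for (j in seq_along(rows)) {
      i <- rows[j]
      di <- d[j, ]
      di[i] <- Inf                      # a point is not its own neighbour
      ord <- order(di, tie)[seq_len(k)]
      idx_mat[i, seq_len(k)] <- ord
      dist_mat[i, seq_len(k)] <- di[ord]
    }
  }
  ed <- normalize_ed_id(geocoded$ed_id)
  same <- matrix(NA, n, cfg$n_neighbors)
  same[, seq_len(k)] <- matrix(ed[idx_mat[, seq_len(k)]], n, k) ==
    matrix(ed, n, k)
  list(index = idx_mat, dist_km = dist_mat, same_ed = same,
       k_eff = rep(k, n))
}

#' Clustering weight of a single point
#'
#' @param distances_km Ascending neighbour distances in kilometres.
#' @param same_ed Logical flags: neighbour shares the point's district.
#' @param cfg Configuration from [weight_config()].
#' @return Weight in \[0, n_neighbors\]: sum of exp(-k * d) over same-ED
#'   neighbours.
#' @export
compute_weight <- function(distances_km, same_ed, cfg = weight_config()) {
  stopifnot(length(distances_km) == length(same_ed),
            all(distances_km >= 0, na.rm = TRUE))
  sum(exp(-cfg$k * distances_km[which(same_ed)]))
}

#' Clustering weights for all points
#'
#' @param geocoded Geocoded address data.frame.
#' @param cfg Configuration from [weight_config()].
#' @return `geocoded` with a `weight` column appended.
#' @export
add_weights <- function(geocoded, cfg = weight_config()) {
  nn <- knn_neighbors(geocoded, cfg)
  contrib <- exp(-cfg$k * nn$dist_km)
  contrib[!nn$same_ed | is.na(nn$same_ed)] <- 0
  geocoded$weight <- rowSums(contrib, na.rm = TRUE)
  geocoded
}
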