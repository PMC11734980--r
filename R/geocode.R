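# Geocoding interface and the three address-level exclusion rules.
#
# Geocoders are pluggable: any list of class "geocoder" with a
# query(address) element returning list(lat, lon, confidence_radius_m,
# result_type). The pipeline never talks to a live service; the synthetic
# geocoder (see synthetic-city.R) and a cache-only replayer cover testing
# and resumable batch runs.

# Closed result-type vocabulary. Native geocoder taxonomies must be mapped
# onto these five values by the geocoder implementation.
RESULT_TYPES <- c("address_like", "road", "neighborhood",
                  "other_nonaddress", "no_result")

no_result_row <- function() {
  list(lat = NA_real_, lon = NA_real_, confidence_radius_m = NA_real_,
       result_type = "no_result")
}

#' Cache-only geocoder
#'
#' Replays results from a geocode cache file and returns `no_result` for
#' anything absent — useful for fully offline re-runs.
#'
#' @param cache_path Path to a cache written by [geocode_batch()].
#' @return A geocoder object.
#' @export
cache_only_geocoder <- function(cache_path) {
  cache <- read_geocode_cache(cache_path)
  structure(list(
    query = function(address) {
      hit <- get0(normalize_street(address), envir = cache,
                  inherits = FALSE)
      if (is.null(hit)) no_result_row() else hit
    }), class = "geocoder")
}

read_geocode_cache <- function(path) {
  cache <- new.env(parent = emptyenv())
  if (!is.null(path) && file.exists(path)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             quote = "", comment.char = "",
                             stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tab))) {
      assign(tab$key[i],
             list(lat = tab$lat[i], lon = tab$lon[i],
                  confidence_radius_m = tab$confidence_radius_m[i],
                  result_type = tab$result_type[i]),
             envir = cache)
    }
  }
  cache
}

append_geocode_cache <- function(path, key, res) {
  new <- !file.exists(path)
  line <- paste(key, res$lat, res$lon, res$confidence_radius_m,
                res$result_type, sep = "\t")
  if (new)
    line <- c(paste("key", "lat", "lon", "confidence_radius_m",
                    "result_type", sep = "\t"), line)
  cat(line, file = path, sep = "\n", append = !new)
}

#' Geocode a batch of address records
#'
#' One result row per input record, in input order. Results are cached to a
#' tab-separated file keyed by the normalised address so that a re-run with
#' a warm cache issues zero geocoder queries. A transport error from the
#' geocoder is retried up to `max_retries` times, then the record is marked
#' `no_result`.
#'
#' @param records Address data.frame (see [read_address_table()]).
#' @param geocoder A geocoder object with a `query(address)` function.
#' @param cache_path Optional path to the geocode cache file.
#' @param max_retries Bounded retry count on transport failure.
#' @return `records` with `lat`, `lon`, `confidence_radius_m` and
#'   `result_type` columns appended.
#' @export
geocode_batch <- function(records, geocoder, cache_path = NULL,
                          max_retries = 2L) {
  keys <- normalize_street(records$street_address)
  cache <- read_geocode_cache(cache_path)
  n <- nrow(records)
  lat <- lon <- conf <- rep(NA_real_, n)
  type <- rep("no_result", n)
  for (i in seq_len(n)) {
    cached <- get0(keys[i], envir = cache, inherits = FALSE)
    res <- if (!is.null(cached)) {
      cached
    } else {
      r <- NULL
      for (try in seq_len(max_retries + 1L)) {
        r <- tryCatch(geocoder$query(records$street_address[i]),
                      error = function(e) NULL)
        if (!is.null(r)) break
      }
      if (is.null(r)) {
        warning("geocoder failed after retries for: ",
                records$street_address[i])
        r <- no_result_row()
      }
      assign(keys[i], r, envir = cache)
      if (!is.null(cache_path)) append_geocode_cache(cache_path, keys[i], r)
      r
    }
    lat[i] <- res$lat; lon[i] <- res$lon
    conf[i] <- res$confidence_radius_m; type[i] <- res$result_type
  }
  stopifnot(all(type %in% RESULT_TYPES))
  out <- records
  out$lat <- lat; out$lon <- lon
  out$confidence_radius_m <- conf; out$result_type <- type
  out
}

#' Apply a user-supplied geocode override file
#'
#' Hand-corrected results (the workflow for the small tail of malformed
#' addresses a geocoder cannot match) supplied as a TSV with columns
#' street_address, lat, lon, confidence_radius_m, result_type.
#'
#' @param geocoded Output of [geocode_batch()].
#' @param overrides_path Path to the override TSV, or NULL for a no-op.
#' @return `geocoded` with matching rows replaced.
#' @export
apply_geocode_overrides <- function(geocoded, overrides_path) {
  if (is.null(overrides_path) || !file.exists(overrides_path))
    return(geocoded)
  ov <- utils::read.table(overrides_path, header = TRUE, sep = "\t",
                          quote = "", stringsAsFactors = FALSE)
  idx <- match(normalize_street(geocoded$street_address),
               normalize_street(ov$street_address))
  hit <- !is.na(idx)
  geocoded$lat[hit] <- ov$lat[idx[hit]]
  geocoded$lon[hit] <- ov$lon[idx[hit]]
  geocoded$confidence_radius_m[hit] <- ov$confidence_radius_m[idx[hit]]
  geocoded$result_type[hit] <- ov$result_type[idx[hit]]
  geocoded
}

#' Filter geocodes on the confidence radius
#'
#' Retains results whose distance confidence bound is strictly less than
#' `max_radius_m` metres (and that returned a result at all).
#'
#' @param geocoded Geocoded address data.frame.
#' @param max_radius_m Exclusion threshold in metres.
#' @return The retained subset, coordinates untouched.
#' @export
filter_confidence <- function(geocoded, max_radius_m = 500) {
  keep <- geocoded$result_type != "no_result" &
    !is.na(geocoded$confidence_radius_m) &
    geocoded$confidence_radius_m < max_radius_m
  geocoded[keep, , drop = FALSE]
}

#' Filter geocodes on the result type
#'
#' Excludes results whose target is a road or neighbourhood (or any other
#' non-address feature) rather than an address or address-like feature.
#'
#' @param geocoded Geocoded address data.frame.
#' @return The subset with `result_type == "address_like"`.
#' @export
filter_result_type <- function(geocoded) {
  geocoded[geocoded$result_type == "address_like", , drop = FALSE]
}

#' Filter geocodes on 1940 county bounds
#'
#' Excludes addresses located outside their enumeration district's county
#' polygon — the coarse guard against the address having moved on the
#' ground since 1940. Points on the county border are retained.
#'
#' @param geocoded Geocoded address data.frame.
#' @param counties Named list of county polygons (WGS84 rings).
#' @param ed_to_county Named character vector mapping normalised ed_id to a
#'   county name present in `counties`.
#' @return The retained subset.
#' @export
filter_county_bounds <- function(geocoded, counties, ed_to_county) {
  county_of <- ed_to_county[normalize_ed_id(geocoded$ed_id)]
  if (any(is.na(county_of))) {
    bad <- unique(geocoded$ed_id[is.na(county_of)])
    stop("no county mapping for enumeration district(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(unique(county_of) %in% names(counties)))
    stop("county polygon missing for: ",
         paste(setdiff(unique(county_of), names(counties)), collapse = ", "))
  keep <- logical(nrow(geocoded))
  for (cty in unique(county_of)) {
    idx <- which(county_of == cty)
    keep[idx] <- point_in_polygon(geocoded$lon[idx], geocoded$lat[idx],
                                  counties[[cty]])
  }
  geocoded[keep, , drop = FALSE]
}
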