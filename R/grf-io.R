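# Readers and writers for GRF-style address tables and GeoJSON layers.
#
# The Geographic Reference File (GRF) is a delimited table with one row per
# enumerated address in a 1940 city: city, county, state, street address and
# the enumeration-district (ED) identifier. Column names vary between
# extracts, so the mapping is configurable through a dialect object.

#' Column dialect for GRF-style address tables
#'
#' @param sep Field separator ("," or "\t"); `NULL` guesses from the header.
#' @param city,county,state,street_address,ed_id Column names in the file.
#' @return A dialect list used by [read_address_table()].
#' @export
grf_dialect <- function(sep = NULL, city = "city", county = "county",
                        state = "state", street_address = "street_address",
                        ed_id = "ed_id") {
  list(sep = sep, cols = c(city = city, county = county, state = state,
                           street_address = street_address, ed_id = ed_id))
}

#' Normalise an enumeration-district identifier
#'
#' ED names carry up to 4 numeric digits plus an optional one-letter suffix,
#' written with or without a leading dash. Normalisation strips the dash
#' prefix, trims whitespace and upper-cases the suffix so that "-24b" and
#' "24B" compare equal.
#'
#' @param ed_id Character vector of raw identifiers.
#' @return Character vector of normalised identifiers.
#' @export
normalize_ed_id <- function(ed_id) {
  out <- toupper(trimws(as.character(ed_id)))
  sub("^-+", "", out)
}

# Canonical street-address key: trimmed, internal runs of whitespace
# collapsed, upper-cased. GRF transcription is inconsistent on all three.
normalize_street <- function(street) {
  toupper(gsub("[[:space:]]+", " ", trimws(as.character(street))))
}

# Deduplication key: the address alone (city, state, normalised street),
# not address + ED — one dwelling belongs to one district, and keying on
# the ED too would let a single mistyped ED marker spawn a phantom cluster.
address_key <- function(records) {
  paste(toupper(trimws(records$city)), toupper(trimws(records$state)),
        normalize_street(records$street_address), sep = "|")
}

#' Read a GRF-style address table
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column mapping from [grf_dialect()].
#' @return A data.frame of address records (city, county, state,
#'   street_address, ed_id, row_index) in file order, with `ed_id`
#'   normalised. An empty file yields a zero-row frame.
#' @export
read_address_table <- function(path, dialect = grf_dialect()) {
  stopifnot(file.exists(path))
  sep <- dialect$sep
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(unname(dialect$cols), names(raw))
  if (length(missing) > 0)
    stop("address table is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(
    city = raw[[dialect$cols[["city"]]]],
    county = raw[[dialect$cols[["county"]]]],
    state = raw[[dialect$cols[["state"]]]],
    street_address = raw[[dialect$cols[["street_address"]]]],
    ed_id = normalize_ed_id(raw[[dialect$cols[["ed_id"]]]]),
    stringsAsFactors = FALSE)
  out$row_index <- seq_len(nrow(out))
  if (any(!nzchar(out$ed_id)))
    stop("empty enumeration-district identifier at row(s): ",
         paste(utils::head(which(!nzchar(out$ed_id)), 5), collapse = ", "))
  out
}

#' Write an address table
#'
#' @param records Address data.frame.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_address_table <- function(records, path, sep = ",") {
  utils::write.table(records[setdiff(names(records), "row_index")], path,
                     sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Collapse addresses to their first occurrence
#'
#' Keeps, for every distinct address (city, state, normalised street), the
#' record with the smallest row index — its attached ED marker rides along.
#' Output preserves file order. Idempotent.
#'
#' @param records Address data.frame ordered by `row_index`.
#' @return The deduplicated subset, still ordered by `row_index`.
#' @export
deduplicate_first_occurrence <- function(records) {
  if (nrow(records) == 0) return(records)
  records <- records[order(records$row_index), , drop = FALSE]
  keep <- !duplicated(address_key(records))
  records[keep, , drop = FALSE]
}

# ---- GeoJSON ----------------------------------------------------------------
#
# Minimal Polygon/MultiPolygon feature I/O over jsonlite. Rings follow the
# package's list(x=, y=) convention; on read, outer rings are oriented
# counter-clockwise and holes clockwise so that signed areas and even-odd
# containment behave.

geojson_coords_to_rings <- function(polys) {
  rings <- list()
  for (poly in polys) {
    for (i in seq_along(poly)) {
      pts <- poly[[i]]
      x <- vapply(pts, function(p) as.numeric(p[[1]]), numeric(1))
      y <- vapply(pts, function(p) as.numeric(p[[2]]), numeric(1))
      n <- length(x)
      if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
      ring <- list(x = x, y = y)
      # first ring of each part is the outer boundary, the rest are holes
      if (i == 1L) ring <- ensure_ccw(ring)
      else if (ring_area_signed(ring) > 0) ring <- list(x = rev(x), y = rev(y))
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

#' Read polygon features from a GeoJSON file
#'
#' @param path Path to a GeoJSON FeatureCollection of Polygon/MultiPolygon
#'   features in WGS84 (EPSG:4326).
#' @return A list with `properties` (data.frame, one row per feature) and
#'   `geometry` (list of polygons, each a list of rings).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  geometry <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    geom <- feats[[i]]$geometry
    if (!geom$type %in% c("Polygon", "MultiPolygon"))
      stop("unsupported geometry type: ", geom$type)
    geometry[[i]] <- geojson_coords_to_rings(
      if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates)
    p <- feats[[i]]$properties
    props[[i]] <- if (is.null(p) || length(p) == 0) list(.empty = NA)
                  else lapply(p, function(v) if (is.null(v)) NA else v)
  }
  keys <- unique(unlist(lapply(props, names)))
  pdf <- as.data.frame(
    stats::setNames(lapply(keys, function(k) {
      vapply(props, function(p) {
        v <- p[[k]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    }), keys), stringsAsFactors = FALSE, check.names = FALSE)
  pdf$.empty <- NULL
  list(properties = pdf, geometry = geometry)
}

# Group a flat ring list into GeoJSON MultiPolygon nesting: positive-area
# rings are outer boundaries; each negative ring becomes a hole of the outer
# ring that contains its first vertex.
rings_to_geojson_geometry <- function(rings) {
  rings <- as_rings(rings)
  signs <- vapply(rings, ring_area_signed, numeric(1))
  outers <- which(signs >= 0)
  if (length(outers) == 0) { outers <- seq_along(rings); signs[] <- 1 }
  parts <- lapply(outers, function(i) list(rings[[i]]))
  for (j in which(signs < 0)) {
    hole <- rings[[j]]
    host <- which(vapply(outers, function(i)
      point_in_polygon(hole$x[1], hole$y[1], rings[[i]]), logical(1)))[1]
    if (is.na(host)) next
    parts[[host]] <- c(parts[[host]], list(hole))
  }
  close_ring <- function(r) {
    m <- cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
    lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
  }
  coords <- lapply(parts, function(part) lapply(part, close_ring))
  if (length(coords) == 1)
    list(type = "Polygon", coordinates = coords[[1]])
  else
    list(type = "MultiPolygon", coordinates = coords)
}

#' Write polygon features to a GeoJSON file
#'
#' @param geometry List of polygons (each a ring or list of rings), WGS84.
#' @param properties data.frame with one row per polygon.
#' @param path Output path.
#' @export
write_geojson <- function(geometry, properties, path) {
  stopifnot(length(geometry) == nrow(properties))
  feats <- lapply(seq_along(geometry), function(i) {
    list(type = "Feature",
         properties = as.list(properties[i, , drop = FALSE]),
         geometry = rings_to_geojson_geometry(geometry[[i]]))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "urn:ogc:def:crs:EPSG::4326")),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}
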