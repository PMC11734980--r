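# HOLC grade assignment by areal predominance, virtual/real pairing,
# precedence resolution, and the concordance cross-tabulation.
#
# HOLC graded neighbourhoods A ("Best"), B ("Still Desirable"),
# C ("Definitely Declining") and D ("Hazardous", the redlined areas); some
# mapped polygons carry no grade ("ungraded"). A district polygon takes the
# grade whose overlay intersection area is largest; where a reference
# ("real") district polygon exists, its grade takes precedence over the
# reconstructed ("virtual") one.

HOLC_GRADES <- c("A", "B", "C", "D")
# Tie order for predominance: later = more hazardous wins an exact tie.
GRADE_ORDER <- c("A", "B", "C", "D", "ungraded")

#' Assign an overlay grade to one polygon by areal predominance
#'
#' Intersects the district polygon with every overlay zone in the Web
#' Mercator plane and returns the grade with the largest total intersected
#' area. Exact area ties go to the more hazardous grade (later letter);
#' ungraded overlay zones compete like any grade. A polygon touching no
#' overlay returns `NA`.
#'
#' @param polygon District polygon in WGS84 (ring or list of rings).
#' @param overlay A list with `geometry` (list of WGS84 polygons) and
#'   `grade` (character vector: "A".."D" or "ungraded"), e.g. from
#'   [read_geojson()] output.
#' @return A single grade string, or `NA_character_` when nothing
#'   intersects.
#' @export
assign_grade <- function(polygon, overlay) {
  poly_m <- project_polygon(polygon)
  areas <- stats::setNames(numeric(length(GRADE_ORDER)), GRADE_ORDER)
  for (i in seq_along(overlay$geometry)) {
    g <- overlay$grade[i]
    if (is.na(g) || !g %in% GRADE_ORDER)
      stop("overlay grade outside {A,B,C,D,ungraded}: ", g)
    a <- intersection_area(poly_m, project_polygon(overlay$geometry[[i]]))
    areas[g] <- areas[g] + a
  }
  if (all(areas == 0)) return(NA_character_)
  # which.max returns the first maximum; reversing makes later letters win
  rev_areas <- rev(areas)
  names(rev_areas)[which.max(rev_areas)]
}

#' Assign grades to all virtual districts
#'
#' @param vd A `virtual_districts` object (see [reconstruct_districts()]).
#' @param overlay Graded overlay layer: list with `geometry` and `grade`
#'   (or `NULL` for a city with no overlay map, e.g. one whose HOLC map was
#'   never drawn or was lost — grades come back `NA`, not errors).
#' @return `vd` with a `grade` column on its district table.
#' @export
assign_grades <- function(vd, overlay) {
  grades <- rep(NA_character_, nrow(vd$districts))
  if (!is.null(overlay)) {
    for (i in seq_len(nrow(vd$districts))) {
      grades[i] <- assign_grade(vd$polygons[[vd$districts$ed_id[i]]], overlay)
    }
  }
  vd$districts$grade <- grades
  vd
}

#' Pair virtual districts with real reference districts
#'
#' A virtual district pairs with the real district polygon containing its
#' geometric centroid. If overlapping real polygons both contain the
#' centroid, the one whose identifier matches wins, else the smallest by
#' area (logged via a warning). `name_match` records whether the
#' normalised identifiers agree — a final error check, not a join key.
#'
#' @param vd A `virtual_districts` object with grades assigned (the
#'   `grade` column may be absent or NA).
#' @param real Reference layer: list with `geometry` (WGS84 polygons),
#'   `ed_id`, and optionally `grade` per polygon.
#' @return data.frame with one row per virtual district: `ed_id`,
#'   `real_id`, `name_match`, `virtual_grade`, `real_grade`,
#'   `resolved_grade`; plus attribute `unpaired_real`, identifiers of real
#'   districts that captured no centroid.
#' @export
pair_virtual_to_real <- function(vd, real) {
  n <- nrow(vd$districts)
  real_ids <- normalize_ed_id(real$ed_id)
  real_areas <- vapply(real$geometry,
                       function(g) polygon_area(project_polygon(g)),
                       numeric(1))
  real_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cx <- vd$districts$centroid_lon[i]; cy <- vd$districts$centroid_lat[i]
    hits <- which(vapply(real$geometry,
                         function(g) point_in_polygon(cx, cy, g),
                         logical(1)))
    if (length(hits) == 0) next
    if (length(hits) > 1) {
      named <- hits[real_ids[hits] == normalize_ed_id(vd$districts$ed_id[i])]
      if (length(named) >= 1) hits <- named
      else {
        warning("centroid of district ", vd$districts$ed_id[i],
                " inside ", length(hits),
                " overlapping real polygons; smallest-area polygon used")
        hits <- hits[which.min(real_areas[hits])]
      }
    }
    real_id[i] <- real_ids[hits[1]]
  }
  virtual_grade <- if (!is.null(vd$districts$grade)) vd$districts$grade
                   else rep(NA_character_, n)
  real_grade <- rep(NA_character_, n)
  if (!is.null(real$grade)) {
    m <- match(real_id, real_ids)
    real_grade[!is.na(m)] <- real$grade[m[!is.na(m)]]
  }
  pairs <- data.frame(
    ed_id = vd$districts$ed_id, real_id = real_id,
    name_match = !is.na(real_id) &
      real_id == normalize_ed_id(vd$districts$ed_id),
    virtual_grade = virtual_grade, real_grade = real_grade,
    resolved_grade = resolve_grade(virtual_grade, real_grade),
    stringsAsFactors = FALSE)
  attr(pairs, "unpaired_real") <- setdiff(real_ids, real_id)
  pairs
}

#' Resolve the grade of a district with both sources
#'
#' Binary precedence: the real district's grade whenever one exists,
#' otherwise the virtual grade.
#'
#' @param virtual_grade,real_grade Character vectors (NA = absent).
#' @return Character vector of resolved grades.
#' @export
resolve_grade <- function(virtual_grade, real_grade) {
  ifelse(!is.na(real_grade), real_grade, virtual_grade)
}

#' Concordance cross-tabulation of virtual vs real grades
#'
#' Builds the 4x4 (A-D) table of paired grade assignments, the percent of
#' pairs on the diagonal, and the histogram of absolute grade distances.
#' Pairs missing either grade, and pairs involving an ungraded polygon,
#' are excluded.
#'
#' @param pairs Either a data.frame from [pair_virtual_to_real()] or a 4x4
#'   count matrix (rows = virtual grade A-D, columns = real grade A-D).
#' @return A `concordance_table` object: `counts`, `total_pairs`,
#'   `pct_concordant`, `grade_distance` (counts at distance 0..3).
#' @export
concordance_table <- function(pairs) {
  if (is.matrix(pairs)) {
    stopifnot(identical(dim(pairs), c(4L, 4L)))
    counts <- pairs
    dimnames(counts) <- list(virtual = HOLC_GRADES, real = HOLC_GRADES)
  } else {
    ok <- pairs$virtual_grade %in% HOLC_GRADES &
      pairs$real_grade %in% HOLC_GRADES
    eligible <- pairs[ok, , drop = FALSE]
    if (nrow(eligible) == 0)
      stop("no pairs with both a virtual and a real grade")
    counts <- table(factor(eligible$virtual_grade, HOLC_GRADES),
                    factor(eligible$real_grade, HOLC_GRADES))
    counts <- matrix(as.integer(counts), 4, 4,
                     dimnames = list(virtual = HOLC_GRADES,
                                     real = HOLC_GRADES))
  }
  total <- sum(counts)
  if (total == 0) stop("empty concordance table")
  dist_idx <- abs(row(counts) - col(counts))
  gd <- vapply(0:3, function(d) sum(counts[dist_idx == d]), numeric(1))
  structure(list(counts = counts, total_pairs = total,
                 pct_concordant = 100 * sum(diag(counts)) / total,
                 grade_distance = stats::setNames(gd, 0:3)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Virtual vs real HOLC grade concordance\n")
  cat("  paired districts:", x$total_pairs, "\n")
  cat(sprintf("  concordant: %.1f%%\n", x$pct_concordant))
  cat("  grade-distance counts (0..3):",
      paste(x$grade_distance, collapse = " / "), "\n\n")
  print(x$counts)
  invisible(x)
}

#' Grade frequency table with marginal percentages
#'
#' Frequencies and percent-of-total by grade, the summary printed for each
#' district layer (real and virtual) in published comparisons.
#'
#' @param grades Character vector of grades ("A".."D", "ungraded"; NA
#'   dropped), or a named numeric vector of precomputed frequencies.
#' @param total Layer total used as the percentage denominator; defaults
#'   to the sum of the frequencies, but a published layer total can be
#'   supplied when recomputing printed tables.
#' @return data.frame with `grade`, `frequency`, `percent` (of the layer
#'   total, unrounded).
#' @export
grade_marginals <- function(grades, total = NULL) {
  freq <- if (is.numeric(grades)) grades
          else table(factor(grades[!is.na(grades)],
                            c(HOLC_GRADES, "ungraded")))
  freq <- freq[freq > 0 | names(freq) %in% HOLC_GRADES]
  if (is.null(total)) total <- sum(freq)
  data.frame(grade = names(freq), frequency = as.numeric(freq),
             percent = 100 * as.numeric(freq) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}
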