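---
title: "Reconstructing enumeration districts from geocoded address clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing enumeration districts from geocoded address clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edreconstruct)
```

## The model

A 1940 enumeration district (ED) is approximated by the spatial cluster of
modern geocodes of the street addresses that carried its identifier. The
method rests on two assumptions: that street naming and house numbering have
not shifted appreciably since 1940, and that where they have, the resulting
geocodes look like *outliers* relative to the district's cluster — far from
the other points carrying the same identifier. Everything in the pipeline is
an operationalisation of those two ideas: addresses that geocode confidently
and near their same-district peers define the district; everything else is
filtered, down-weighted or trimmed.

The pipeline is, in order: first-occurrence deduplication; geocoding with
three exclusion rules; nearest-neighbour cluster weighting; weighted-centroid
outlier trimming; hull construction; grade assignment and concordance. Each
stage only ever removes or annotates points, and the per-address ledger
(`ledger_summary()`) proves conservation: every input row lands in exactly
one terminal category.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| confidence bound | < 500 | m | drop imprecise geocodes |
| result type | address-like only | — | drop road/neighbourhood matches |
| `n_neighbors` | 10 | points | neighbourhood size for weighting |
| decay `k` | 5 | per km | same-ED neighbour contribution `exp(-k d)` |
| IQR fence | Q3 + 1.5·IQR | km | relative outlier trim |
| radius trim | 2 | km | absolute urban-scale trim |
| validity | min distance ≤ 500 | m | whole-district false-cluster check |
| hull | convex | — | bounding polygon family |

The defaults are the published method's values and a bare run uses all of
them unchanged. The weight sums `exp(-k·d)` over the same-district subset of
the 10 nearest neighbours, so it ranges over [0, 10]: it combines the
same-district *proportion* (how many terms) with distance *decay* (how large
each term is). This is the only simple combination of the two ingredients
with that range; the alternative reading (proportion × mean decay) ranges
over [0, 1] and cannot saturate at 10. Distances enter in kilometres: with
k = 5/km, a same-district neighbour at 200 m contributes `exp(-1) ≈ 0.37`
and one at 2 km `exp(-10) ≈ 4.5e-5`, consistent with the 2 km urban trim
scale. The kNN search is citywide — restricting it to the district would
make the same-district share tautologically 1.

## Numerical choices

* **Distances** between points are haversine on a sphere of radius
  6371.0088 km; at city scale this is sub-metre accurate and is matched
  exactly by the brute-force oracle the tests compare against.
* **Planar work** (centroids, hulls, intersection areas) happens in Web
  Mercator (EPSG:3857), mirroring the GIS workflow this method grew out of.
  Mercator inflates areas by ≈ `1/cos²(lat)`, but both predominance and IoU
  are area *ratios* over small extents, so the factor cancels.
* **Quartiles** for the IQR fence use linear interpolation between order
  statistics (type 7, R's default), pinned for reproducibility.
* **Boundary conventions**: confidence strictly `< 500 m` ("less than");
  radius trim keeps exactly 2.0 km ("more than 2 km" excludes); validity
  keeps a minimum distance of exactly 500 m ("exceeds"); points on a county
  border are retained (the exclusion targets gross mislocation, and border
  contact is no evidence of error).
* **kNN ties** break toward the smaller row index; **predominance ties**
  go to the more hazardous grade (deterministic, conservative for exposure
  classification; exact floating-point area ties essentially never occur,
  but the rule must exist).
* **Degenerate inputs**: a district with zero total weight cannot be
  centred and is dropped with a reason code, as are districts trimmed below
  3 points or left collinear (no polygon is definable).
* The centroid is computed **once**; there is no re-centring after
  trimming. Iterated re-centring would be a different (and less
  reproducible) estimator.

## Design decisions

* **Deduplication key** is the address alone (city, state, normalised
  street), not address + ED: one dwelling belongs to one district, and
  keying on the ED too would let a single mistyped ED marker spawn a
  phantom one-point cluster. The first row's ED marker is retained.
* **Convex hull by default.** The alpha-shape family is exposed
  (`alpha` in metres of circumradius), but any finite alpha is a free
  parameter with no principled default, so the reproducible convex hull is
  the default; real districts can be concave, which the convex default
  cannot capture (a known limitation of the approach, not of the
  implementation). Virtual districts may overlap each other; no mutual
  exclusivity is imposed.
* **Real-over-virtual precedence** is binary: where a reference district
  polygon contains the virtual district's centroid, the reference grade is
  used. Identifier agreement (`name_match`) is recorded as an error check,
  not used as the join key.
* **Ungraded overlay polygons** compete in predominance like any grade and
  can win; they are excluded from the 4×4 concordance table.
* **Resumability** is provided where it matters — the geocode cache makes
  re-runs issue zero queries — rather than via per-stage manifest skipping,
  which would buy little for the cheap stages.
* The command-line entry point is a thin `Rscript` wrapper
  (`inst/cli/edreconstruct.R`); the package functions are the interface.

## What the simulator emulates — and what it does not

`generate_city()` builds a square city at a configurable mid-latitude US
origin, tessellated into districts (grid, or Voronoi from random seeds),
with addresses uniform inside their district, overlay grade zones that are
unions of whole districts (or independent vertical bands), a buffered
county rectangle, and optional duplicate address rows. `make_geocoder()`
draws each address's fate once from the noise model — no-result, road-type,
gross mislocation of 10–20 km, or a good result with Gaussian jitter — so
results are deterministic in the seed and independent of query order.

Defaults are chosen to represent the dense-urban study conditions: 25
districts of ~1.2 km cells (diameter below the 2 km trim radius), 30
addresses per district, noiseless geocoding; noise scenarios are always
explicit. What the simulator does **not** emulate: real street topology and
address grammar, spatially correlated geocoder failure (demolished
neighbourhoods fail together in reality — the published discussion of
non-random missingness), concave districts, and reference layers digitised
independently of the truth (here the "real" layer *is* the truth). Passing
tests therefore demonstrate that the algorithmic machinery is correct and
robust to the modelled error processes — not that any particular accuracy
will be attained on archival data.

## Problem sizes and empirical behaviour

The test suite and acceptance script run cities of 9–100 districts
(≈ 200–2500 address points), 20-seed noise sweeps at 25 districts × 30
addresses, and oracle comparisons at 100–200 points; these sizes keep the
whole suite under a minute while exercising every code path at realistic
densities.

Two empirical notes, both computed by the tests themselves. With zero
noise and compact districts, the 2 km radius rule never fires and no
district is ever dropped, but the IQR fence does occasionally clip a
legitimate sample point (~0.4% of points across seeds): an upper quantile
fence estimated from ~25 draws sometimes falls below the sample maximum.
That is a property of the IQR rule itself, and the trim rate is asserted
to stay below 2%. Second, convex hulls of interior samples systematically
undershoot true polygon boundaries, so intersection-over-union against the
true districts plateaus around 0.6–0.7 at 25–30 addresses per district;
the recovery test asserts the conservative ≥ 0.5 average. Neither effect
disturbs centroid pairing or grade concordance, which are the quantities
the method is consumed through.

## Known limitations

Convex hulls cannot represent concave districts; virtual polygons are
generally smaller than true ones (interior sampling); residential-only
address data under-covers districts zoned for other uses; and grade
assignment is areal predominance only — no population weighting, no
fractional multi-grade exposure. Whole-district drops are logged with
reason codes precisely because missingness of reconstructed districts is
unlikely to be random.
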