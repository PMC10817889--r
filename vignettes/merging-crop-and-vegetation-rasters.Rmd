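---
title: "Merging crop and natural-vegetation land-cover rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging crop and natural-vegetation land-cover rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanmerge)
```

## The problem

Thematic land-cover rasters for the conterminous US specialise: crop-type
products (CDL-style) resolve ~110 agricultural classes but lump natural
vegetation into a few broad classes, while vegetation products (NVC-style)
resolve hundreds of natural vegetation groups but only ~23 coarse
agricultural classes. Ecological applications — pollination services, pest
spillover, habitat configuration — need both at once. `spanmerge`
implements a categorical raster fusion: vegetation pixels keep their
detailed natural/developed classes, agricultural pixels take the specific
crop from an annual crop raster, and the disagreement between the two
sources is quantified rather than hidden.

## The model and its assumptions

Let $V$ and $C$ be co-registered integer rasters (vegetation and crop) on
the same grid, and let $\mathcal{A}$ be the set of agricultural vegetation
codes, partitioned into match groups $g$ with crop match sets $M(g)$.

**Step 1 (reclassify).** Per pixel $p$:

* $V_p \notin \mathcal{A}$: output $V_p$ (passthrough — natural vegetation,
  the four developed classes, and vegetation nodata).
* $V_p \in \mathcal{A}$ and $C_p \in M(g(V_p))$: output $-C_p$ (matched;
  negation keeps crop codes disjoint from vegetation codes).
* otherwise: mismatched. This includes non-agricultural and
  background/nodata crop-layer values at agricultural pixels — the
  workflow's definition of conflict deliberately covers both "not
  agriculture in the crop layer" and "a different kind of agriculture".

Match sets encode synonymy (Wheat ← wheat), subset relations (Orchard ←
almonds, apples, …) and crop rotation: one vegetation snapshot is merged
with many crop years, so the six row-crop-style groups (Row Crop - Close
Grown Crop, Row Crop, Close Grown Crop, Fallow/Idle, Pasture and hayland,
Wheat) share a single pooled match set of fallow, grass/pasture, hay and all
annual/rotation crops. A crop code may appear in several groups; vegetation
codes are unique to one group (validated on load). The packaged table
resolves name-only crop lists through the shipped CDL code registry
(`inst/extdata/cdl_codes.csv`), which reproduces every explicitly printed
code in the source material.

**Step 2 (resolve).** Every mismatched pixel takes the modal donor crop
within Chebyshev radius $r$ (default 3, the 7×7 / 90 m window), negated; if
the window holds no donor the pixel becomes the reserved unresolved code
(default −1001, which collides with no negated crop code and no vegetation
code). Donor eligibility is fixed by the *step-1* state, never updated as
pixels resolve — this makes the pass order-independent, idempotent, and
exactly decomposable into tiles.

### The donor policy

The default `donor_policy = "matched_only"` admits only step-1-matched
pixels as donors. The alternative `"any_cdl_ag"` admits any pixel whose
crop-layer class is agricultural (the focal pixel never donates to itself
under either policy, so a lone conflicting pixel cannot resolve from its own
crop value). `matched_only` is the default because it reproduces the
documented field-scale behaviour of the real product: a whole field whose
vegetation group conflicts with an *agricultural* crop class (e.g. orchard
over grass/pasture) stays unresolved — under `any_cdl_ag` such a field
would always resolve from its own crop pixels, and unresolved whole fields
could not occur.

### Tie-breaking

The mode over donor counts can tie. Ties are broken toward the smallest CDL
code (configurable to largest), which is deterministic and
platform-independent; the production implementation scans candidate codes in
tie-break order and accepts only strictly larger counts, which the
enumeration oracle in the test suite confirms is equivalent to "smallest
among the argmax set".

## Tiled processing

Production extents are processed as tiles of approximately 1000 km²
(side = ⌊√(10⁹)/30⌋ ≈ 1054 px at 30 m) with a 3-pixel overlap, laid out
row-major; core windows partition the grid, each tile is merged on its
padded window and only the core is written back. Because resolution depends
only on step-1 state within radius $r$ and the overlap is validated
≥ $r$, the mosaic is **bit-identical** to monolithic processing — asserted
in the tests over seeded fixtures up to 512×512 with conflicts planted on
tile seams. Window truncation at the true grid boundary contributes no
donors, and the padding reproduces exactly that behaviour at tile seams.

## Validation statistics

* **Mismatch accounting** (after step 1): per zone × vegetation group ×
  conflicting crop class, with the per-zone group pixel count as
  denominator; geographic/climatic group variants are pooled under one
  display name. Zero-count combinations emit no record (no 0/0 division).
* **Unresolved accounting** (after step 2): per zone, count and percent of
  *total zone area* — a deliberately different denominator than mismatch,
  matching the published table schemas.
* **Area-weighted accuracy**: over the classes present in a zone that have
  reference data, the weighted mean of per-class user's/producer's accuracy
  with class pixel areas as weights; classes lacking reference data (e.g.
  vegetation types with too few field plots) are excluded from both the mean
  and the with-reference area, and coverage is reported as the percent of
  focal area whose classes carry reference data. For the merged product,
  negative codes draw from the crop-layer records and positive codes from
  the vegetation records; unresolved pixels are excluded from the focal
  group. A class with no record at all is treated as lacking reference data
  (reported via a message), the reading most consistent with tying accuracy
  availability to reference coverage.
* **Jenks natural breaks** for mapping percentages: implemented as exact
  Fisher-style dynamic programming minimising within-class sum of squared
  deviations ($O(kn^2)$), not the common heuristic; verified against an
  exhaustive partition oracle for small $n$. Breaks are returned as the
  class minima/maxima vector; with duplicate-heavy inputs a class may be a
  single repeated value, which the classifier handles by assigning to the
  first class whose maximum covers the value.
* **Output verification**: every merged pixel value must appear in the
  attribute table, and extent/CRS must match expectations; a report object
  collects failures rather than stopping a batch.

## Zones

Accounting zones are a pre-rasterised integer grid (FIPS-like codes) rather
than polygons: the polygon→pixel rule is thereby explicit (a pixel belongs
to the zone its center was rasterised to) and testable. Optional
`zone_info` supplies display labels (state, county name, region).

## The fixture generator

`generate_pair()` emulates the features of real landscapes that the method
is sensitive to, and nothing more: axis-aligned rectangular fields (default
8×8 px) that are agricultural with probability 0.6; per-field vegetation
group and matching crop; year-to-year rotation *within* match sets (so
rotation alone never creates conflict); county-like vertical-band zones; and
planted disagreement of both kinds — crop-layer natural classes and
out-of-set agricultural classes — as whole conflicting fields, scattered
pixels at a 5.5 % rate (the disagreement level reported for the real
national products), plus 1 % isolated noise pixels. It returns exact ground
truth: the planted mismatch mask and per-zone counts, and the unresolvable
mask computed by a direct Chebyshev-distance scan that is implemented
independently of the merge engine's summed-area-table pass. It does **not**
emulate spatial autocorrelation of natural vegetation, realistic field-size
distributions, or classifier error structure — so passing tests demonstrate
algorithmic correctness (conservation, accounting, equivalence, recovery of
planted parameters), not thematic accuracy on real imagery.

## Numerical and implementation choices

* Window counts use summed-area tables per candidate donor code — exact
  integer arithmetic, $O(\text{cells} \times \text{codes})$, no floating
  point in the merge path.
* All grids are integer matrices; the merged product needs a signed type
  wide enough for −1001 and ~8000, and files are written as plain integers
  (32-bit range) accordingly.
* Raster I/O uses the ESRI ASCII grid text format with a `.prj` sidecar
  carrying the CRS identifier — a lossless round-trip for integer rasters
  verified in the tests — plus an optional sidecar attribute/color CSV.
* Degenerate inputs: 1×1 grids work (the window truncates to the grid); an
  empty match table is a load error; zones with no agricultural pixels emit
  no mismatch records; `weighted_accuracy` with all-absent reference yields
  `NA` accuracies and zero coverage rather than NaN.
* Problem sizes in the test suite (up to 512×512 fixtures, 50 random small
  grids for the oracle comparison, 100 random Jenks cases) were chosen so
  the full suite runs in well under a minute while still exercising
  multi-tile layouts and seam conflicts.

## Known limitations

* The real products' state-boundary buffering, county polygon acquisition
  and ownership-polygon zonal smoothing are out of scope; zones and aligned
  rasters are inputs.
* GeoTIFF is not read or written; the ASCII-grid/CSV interchange is
  GIS-standard but larger on disk. Converting to/from GeoTIFF is a one-line
  `gdal_translate` call outside this package.
* The merge assumes inputs already share grid and CRS; it refuses, rather
  than resamples, anything else.
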