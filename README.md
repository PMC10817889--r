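# spanmerge

Integrated land-cover maps for agriculture *and* nature. US land-cover
rasters split the thematic world in two: crop-type products (the USDA-NASS
Cropland Data Layer, CDL) carry ~110 agricultural classes but only a handful
of coarse natural classes, while vegetation products (the LANDFIRE National
Vegetation Classification raster, NVC) map hundreds of natural vegetation
groups but only ~23 broad agricultural classes. `spanmerge` fuses the two:
it keeps the vegetation raster's natural and developed classes and replaces
its agricultural pixels with the specific crop from an annual crop raster,
producing a single integrated product for landscape ecology, pollination and
ecosystem-service modelling.

## The method

Both inputs are co-registered 30 m integer rasters (no resampling is ever
performed; misalignment is an error). The merge runs in two steps per pixel:

1. **Reclassify.** For each NVC agricultural pixel, look up its match group
   (e.g. *Vineyard* ← {Grapes}; *Orchard* ← {Almonds, Apples, …}; the six
   row-crop-style groups share one pooled set covering fallow, grass/pasture,
   hay and all rotation crops). If the CDL class is in the group's match set
   the output value is the **negated CDL code** (negation keeps crop codes
   disjoint from vegetation codes). Non-agricultural NVC pixels pass through
   bit-identically.
2. **Resolve.** A conflicting ("mismatched") pixel receives the modal
   eligible donor crop within a 7×7 window (Chebyshev radius 3 = 90 m), ties
   broken deterministically by smallest code. Donors are the pixels that
   *matched in step 1* (configurable to any agricultural CDL pixel); donor
   status is frozen at step 1, so the pass is order-independent. With no
   donor in reach the pixel becomes **−1001, unresolved**.

Large extents are processed as ~1000 km² tiles with a 3-pixel overlap; the
overlap guarantees every core pixel sees a complete window, so the tiled
mosaic is bit-identical to monolithic processing. Validation mirrors the
product's technical-validation tables: per-county mismatch and unresolved
accounting, area-weighted user's/producer's accuracy
(`Acc = Σᵢ wᵢ·accᵢ / Σᵢ wᵢ` over classes *i* with reference data, weights =
class areas), reference-data coverage, and exact (Fisher) Jenks natural
breaks for mapping.

## Worked example

Everything is testable offline: the fixture generator plants fields, crop
rotations, county-like zones and known conflicts, and returns the ground
truth it planted.

```r
library(spanmerge)
tab <- default_match_table()
fx  <- generate_pair(fixture_spec(rows = 96, cols = 96, seed = 42), tab)
res <- span_merge(fx$nvc, fx$cdl_by_year[["2016"]], tab)
print(res)
#> merge_result (complete)
#> categorical_grid: 96 x 96 cells of 30 units | EPSG:5070
#>   origin (xmin, ymax): 0 0 | nodata: -9999
#>    15 distinct values
#>   counts: passthrough=4416, matched=4429, mismatched=371, resolved=355, unresolved=16
```

Of 9216 pixels, 4416 are natural/developed passthrough; 4429 agricultural
pixels agreed between the layers and now carry negated crop codes; 371
conflicted, of which 355 were resolved from neighbouring crops and 16 — a
planted whole-field conflict's interior, beyond 90 m of any matched pixel —
are −1001. Per-zone accounting:

```r
unresolved_stats(res, fx$zones, 2016, zone_info = fx$zone_info)
#>   FIPS             County NCells Pct_Unresolved
#> 1 1001 Synthetic County 1     16      0.5208333
#> 2 1003 Synthetic County 2      0      0.0000000
#> 3 1005 Synthetic County 3      0      0.0000000

head(mismatch_stats(fx$nvc, fx$cdl_by_year[["2016"]], fx$zones, tab, 2016)[,
     c("FIPS", "NVC_Name", "CDL_Name", "NCells_Mismatch", "Pct_Mismatch")], 4)
#>   FIPS               NVC_Name         CDL_Name NCells_Mismatch Pct_Mismatch
#> 1 1001 Bush fruit and berries             Corn              13     4.062500
#> 2 1001 Bush fruit and berries Deciduous Forest              13     4.062500
#> 3 1001            Fallow/Idle         Cherries               7     3.645833
#> 4 1001            Fallow/Idle Deciduous Forest               7     3.645833
```

`Pct_Mismatch` is per zone and NVC group: 13 of the 320 "Bush fruit and
berries" pixels in county 1001 conflicted with corn (an agricultural class
outside that group's match set) and another 13 with forest (a
non-agricultural class) — the two planted conflict kinds.

A command-line wrapper covers the same pipeline
(`Rscript inst/cli/span.R <synth|merge|stats|verify|plan-tiles> …`, or via
`span_cli()`); rasters travel as ESRI ASCII grids with a `.prj` sidecar and
statistics as CSVs with the product's canonical column headers.

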