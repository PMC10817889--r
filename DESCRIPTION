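Package: spanmerge
Title: Fuse Crop and Natural-Vegetation Land-Cover Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges an annual crop-type raster (Cropland Data Layer style
    integer codes) into the agricultural pixels of a natural-vegetation
    raster (LANDFIRE National Vegetation Classification style codes) to
    produce an integrated agriculture-plus-nature land-cover product.
    Agricultural pixels whose classes agree between the two inputs are
    reassigned to the (negated) crop code; conflicting pixels are resolved
    to the modal eligible crop within a 7x7 moving window, or flagged
    unresolved (-1001) when no donor crop pixel is in reach. Large extents
    are processed as overlapping tiles with exact equivalence to monolithic
    processing. Includes per-zone mismatch and unresolved accounting,
    area-weighted user's/producer's accuracy integration, reference-data
    coverage, exact (Fisher) Jenks natural-breaks classification, automated
    output verification, and a synthetic-fixture generator with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
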