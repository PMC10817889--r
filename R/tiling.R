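#' Plan overlapping tiles over a grid
#'
#' Splits a grid into square-ish tiles laid out row-major from the origin.
#' Core windows partition the grid exactly; each padded window is the core
#' expanded by `overlap` pixels and clipped to the grid. The default tile
#' side is derived from a target tile area (1000 km^2 in the production
#' workflow) at the grid's cell size; the overlap (90 m = 3 pixels at 30 m)
#' must be at least the merge window radius so every core pixel sees its
#' complete neighbourhood.
#'
#' @param grid_shape Integer length-2: rows, cols.
#' @param cell_size Cell edge length in CRS units.
#' @param target_area Target tile area in squared CRS units (default 1e9,
#'   i.e. 1000 km^2 with metre units).
#' @param overlap Overlap in pixels (default 3).
#' @param radius Merge window radius the plan must support (default 3).
#' @param tile_side Optional explicit tile side in pixels, overriding
#'   `target_area`.
#' @return A `tile_plan`: list with `tiles` (data frame of 1-based inclusive
#'   core and padded bounds), `overlap`, `grid_shape`, `tile_side`.
#' @export
plan_tiles <- function(grid_shape, cell_size = 30, target_area = 1e9,
                       overlap = 3L, radius = 3L, tile_side = NULL) {
  overlap <- as.integer(overlap)
  if (overlap < radius)
    stop("configuration error: overlap (", overlap,
         " px) must be >= merge radius (", radius, " px)")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  if (is.null(tile_side))
    tile_side <- max(1L, as.integer(floor(sqrt(target_area) / cell_size)))
  tile_side <- as.integer(tile_side)
  if (tile_side < 1) stop("tile side must be >= 1 pixel")
  row_starts <- seq.int(1L, nr, by = tile_side)
  col_starts <- seq.int(1L, nc, by = tile_side)
  tiles <- expand.grid(row0 = row_starts, col0 = col_starts,
                       KEEP.OUT.ATTRS = FALSE)
  tiles <- tiles[order(tiles$row0, tiles$col0), , drop = FALSE]  # row-major
  tiles$row1 <- pmin(tiles$row0 + tile_side - 1L, nr)
  tiles$col1 <- pmin(tiles$col0 + tile_side - 1L, nc)
  tiles$prow0 <- pmax(tiles$row0 - overlap, 1L)
  tiles$prow1 <- pmin(tiles$row1 + overlap, nr)
  tiles$pcol0 <- pmax(tiles$col0 - overlap, 1L)
  tiles$pcol1 <- pmin(tiles$col1 + overlap, nc)
  tiles <- data.frame(tile = seq_len(nrow(tiles)),
                      tiles[, c("row0", "row1", "col0", "col1",
                                "prow0", "prow1", "pcol0", "pcol1")])
  rownames(tiles) <- NULL
  structure(list(tiles = tiles, overlap = overlap,
                 grid_shape = c(nr, nc), tile_side = tile_side),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat("tile_plan:", nrow(x$tiles), "tiles of side", x$tile_side,
      "px, overlap", x$overlap, "px over a", x$grid_shape[1], "x",
      x$grid_shape[2], "grid\n")
  invisible(x)
}

#' @export
as.data.frame.tile_plan <- function(x, ...) x$tiles

#' Tiled merge with exact monolithic equivalence
#'
#' Runs [span_merge()] on each padded tile and writes back only the core
#' window, so every pixel is written exactly once. Because conflict
#' resolution uses the step-one state only and the overlap is at least the
#' window radius, the mosaic of cores is bit-identical to the monolithic
#' merge of the full grid.
#'
#' @inheritParams span_merge
#' @param plan A [plan_tiles()] plan for the grid shape; by default one is
#'   derived from the grid.
#' @param progress Function called with (tile index, n tiles) after each
#'   tile, or `NULL`.
#' @return A completed `merge_result` for the full grid.
#' @export
merge_tiled <- function(nvc, cdl, table, scheme = code_scheme(),
                        config = merge_config(), plan = NULL,
                        progress = NULL) {
  check_alignment(nvc, cdl)
  if (is.null(plan))
    plan <- plan_tiles(dim(nvc$values), nvc$cell_size, radius = config$radius)
  if (!identical(plan$grid_shape, as.integer(dim(nvc$values))))
    stop("tile plan shape ", paste(plan$grid_shape, collapse = "x"),
         " does not match grid ", paste(dim(nvc$values), collapse = "x"))
  if (plan$overlap < config$radius)
    stop("configuration error: plan overlap < merge radius")
  merged <- matrix(NA_integer_, nrow(nvc$values), ncol(nvc$values))
  mismatch <- matrix(FALSE, nrow(merged), ncol(merged))
  unres <- matrix(FALSE, nrow(merged), ncol(merged))
  tl <- plan$tiles
  for (i in seq_len(nrow(tl))) {
    pr <- tl$prow0[i]:tl$prow1[i]; pc <- tl$pcol0[i]:tl$pcol1[i]
    res <- span_merge(grid_crop(nvc, pr, pc), grid_crop(cdl, pr, pc),
                      table, scheme, config)
    # core window, in padded-tile coordinates
    cr <- (tl$row0[i] - tl$prow0[i] + 1L):(tl$row1[i] - tl$prow0[i] + 1L)
    cc <- (tl$col0[i] - tl$pcol0[i] + 1L):(tl$col1[i] - tl$pcol0[i] + 1L)
    gr <- tl$row0[i]:tl$row1[i]; gc <- tl$col0[i]:tl$col1[i]
    merged[gr, gc] <- res$merged$values[cr, cc]
    mismatch[gr, gc] <- res$mismatch_mask[cr, cc]
    unres[gr, gc] <- res$unresolved_mask[cr, cc]
    if (!is.null(progress)) progress(i, nrow(tl))
  }
  rel <- classify_relation(nvc$values, cdl$values, table)
  structure(list(merged = categorical_grid(merged, nvc$cell_size, nvc$origin,
                                           nvc$crs, nvc$nodata),
                 mismatch_mask = mismatch,
                 unresolved_mask = unres,
                 relation = rel,
                 counts = .merge_counts(rel, mismatch, unres),
                 stage = "complete"),
            class = "merge_result")
}
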