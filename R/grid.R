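#' Categorical land-cover grid
#'
#' An in-memory 2-D integer raster with just enough georeferencing to support
#' aligned merging: an upper-left origin, a square cell size, a CRS identifier
#' and a nodata code. Row 1 is the northernmost row, matching the on-disk
#' layout of the ASCII-grid files read and written by [read_raster()] /
#' [write_raster()].
#'
#' @param values Integer matrix (rows x cols). Numeric input is accepted if it
#'   holds whole numbers.
#' @param cell_size Cell edge length in CRS units (default 30, the resolution
#'   of the national crop and vegetation products).
#' @param origin Numeric length-2: x of the left edge and y of the top edge.
#' @param crs CRS identifier, e.g. `"EPSG:5070"`.
#' @param nodata Integer nodata code stored in `values` where data is missing.
#' @return An object of class `categorical_grid`.
#' @examples
#' g <- categorical_grid(matrix(7292L, 4, 5))
#' dim(g$values)
#' @export
categorical_grid <- function(values, cell_size = 30, origin = c(0, 0),
                             crs = "EPSG:5070", nodata = -9999L) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.double(values)) {
    if (any(values != round(values), na.rm = TRUE))
      stop("`values` must hold integer codes")
    storage.mode(values) <- "integer"
  }
  if (!is.integer(values)) stop("`values` must be an integer matrix")
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid must be at least 1 x 1")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a positive number")
  if (length(origin) != 2 || !is.numeric(origin))
    stop("`origin` must be numeric length 2 (xmin, ymax)")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), crs = as.character(crs),
                 nodata = as.integer(nodata)),
            class = "categorical_grid")
}

#' @export
print.categorical_grid <- function(x, ...) {
  cat("categorical_grid:", nrow(x$values), "x", ncol(x$values),
      "cells of", x$cell_size, "units |", x$crs, "\n")
  cat("  origin (xmin, ymax):", x$origin[1], x$origin[2],
      "| nodata:", x$nodata, "\n")
  vals <- unique(as.vector(x$values))
  cat("  ", length(vals), "distinct values\n")
  invisible(x)
}

#' @export
dim.categorical_grid <- function(x) dim(x$values)

#' Spatial extent of a grid
#'
#' @param grid A [categorical_grid()].
#' @return Named numeric vector `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "categorical_grid"))
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + ncol(grid$values) * grid$cell_size,
    ymin = grid$origin[2] - nrow(grid$values) * grid$cell_size,
    ymax = grid$origin[2])
}

#' Check that two grids share shape, geotransform and CRS
#'
#' The merge never resamples, so inputs must sit on the identical grid.
#'
#' @param a,b [categorical_grid()] objects.
#' @param label Name used in the error message (e.g. a year).
#' @return Invisibly `TRUE`; stops with an alignment error otherwise.
#' @export
check_alignment <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "categorical_grid"), inherits(b, "categorical_grid"))
  tag <- if (is.null(label)) "" else paste0(" [", label, "]")
  if (!identical(dim(a$values), dim(b$values)))
    stop("alignment error", tag, ": grid shapes differ (",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), ")")
  if (!isTRUE(all.equal(a$cell_size, b$cell_size)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("alignment error", tag, ": geotransforms differ; resampling is not performed")
  if (!identical(a$crs, b$crs))
    stop("alignment error", tag, ": CRS differ (", a$crs, " vs ", b$crs, ")")
  invisible(TRUE)
}

#' Crop a grid to a row/column window
#'
#' The origin is shifted so the cropped grid stays correctly georeferenced.
#'
#' @param grid A [categorical_grid()].
#' @param rows,cols Integer ranges (1-based, inclusive) to keep.
#' @return A [categorical_grid()].
#' @export
grid_crop <- function(grid, rows, cols) {
  stopifnot(inherits(grid, "categorical_grid"))
  r0 <- min(rows); c0 <- min(cols)
  categorical_grid(grid$values[rows, cols, drop = FALSE],
                   cell_size = grid$cell_size,
                   origin = c(grid$origin[1] + (c0 - 1) * grid$cell_size,
                              grid$origin[2] - (r0 - 1) * grid$cell_size),
                   crs = grid$crs, nodata = grid$nodata)
}
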