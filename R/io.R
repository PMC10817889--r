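#' Write a categorical grid as an ESRI ASCII grid
#'
#' Writes the text AAIGrid format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by rows north to south), which is
#' lossless for integer rasters and readable by every GIS stack. The CRS
#' identifier is written to a `.prj` sidecar. Optionally a sidecar attribute/
#' color CSV is written next to the raster.
#'
#' @param grid A [categorical_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param attribute_table Optional data frame (`Value`, `Class_Name`, `Red`,
#'   `Green`, `Blue`) written to `<path>.vat.csv`.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(grid, path, attribute_table = NULL) {
  stopifnot(inherits(grid, "categorical_grid"))
  ext <- grid_extent(grid)
  hdr <- c(paste("ncols", ncol(grid$values)),
           paste("nrows", nrow(grid$values)),
           paste("xllcorner", format(ext["xmin"], digits = 15)),
           paste("yllcorner", format(ext["ymin"], digits = 15)),
           paste("cellsize", format(grid$cell_size, digits = 15)),
           paste("NODATA_value", grid$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(grid$values, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  writeLines(grid$crs, sub("\\.[^./]*$", "", path) %.% ".prj")
  if (!is.null(attribute_table))
    utils::write.csv(attribute_table, paste0(path, ".vat.csv"),
                     row.names = FALSE)
  invisible(path)
}

`%.%` <- function(a, b) paste0(a, b)

#' Read an ESRI ASCII grid
#'
#' Parses the header case-insensitively and requires a `.prj` sidecar with
#' the CRS identifier (pass `require_crs = FALSE` to accept rasters without
#' one). Values are read as integers; lossless round-trip with
#' [write_raster()].
#'
#' @param path Path to the `.asc` file.
#' @param require_crs Error if the `.prj` sidecar is missing (default).
#' @return A [categorical_grid()].
#' @export
read_raster <- function(path, require_crs = TRUE) {
  if (!file.exists(path)) stop("I/O error: raster not found: ", path)
  lines <- readLines(path, n = 6, warn = FALSE)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(vapply(kv, `[[`, "", 2), tolower(vapply(kv, `[[`, "", 1)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("I/O error: malformed ASCII grid header in ", path)
  nc <- as.integer(hdr["ncols"]); nr <- as.integer(hdr["nrows"])
  nodata <- if ("nodata_value" %in% names(hdr))
    as.integer(hdr["nodata_value"]) else -9999L
  n_hdr <- if ("nodata_value" %in% names(hdr)) 6L else 5L
  vals <- scan(path, what = integer(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("I/O error: expected ", nr * nc, " values in ", path, ", found ",
         length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  prj <- sub("\\.[^./]*$", "", path) %.% ".prj"
  if (!file.exists(prj)) {
    if (require_crs) stop("I/O error: CRS sidecar missing for ", path,
                          " (expected ", prj, ")")
    crs <- NA_character_
  } else crs <- readLines(prj, n = 1, warn = FALSE)
  cell <- as.numeric(hdr["cellsize"])
  categorical_grid(m, cell,
                   origin = c(as.numeric(hdr["xllcorner"]),
                              as.numeric(hdr["yllcorner"]) + nr * cell),
                   crs = crs, nodata = nodata)
}

.stats_schemas <- list(
  pixel_mismatch = c("FIPS", "State", "CDL_Year", "CDL_Class", "CDL_Name",
                     "NVC_Name", "NCells_Mismatch",
                     "NCells_NVCClass_perCounty", "NVC_CDL_Pair",
                     "Pct_Mismatch"),
  unresolved_conflict = c("FIPS", "State", "CDL_Year", "County",
                          "LF2010_Region", "MergedRaster_Class",
                          "MergedRaster_ClassName", "NCells",
                          "Pct_Unresolved"),
  accuracy_datacoverage = c("FIPS", "State", "CDL_Year", "County",
                            "FocalGroup", "Dataset_Name", "NCells_County",
                            "NCells_FocalGroup", "FocalGroup_PctCounty",
                            "WithData_PctFocalGroup", "WtdProdAcc",
                            "WtdUserAcc"),
  attribute_table = c("Value", "Class_Name", "Red", "Green", "Blue"))

#' Write a validation-statistics CSV with its canonical header
#'
#' Schemas: `"pixel_mismatch"`, `"unresolved_conflict"`,
#' `"accuracy_datacoverage"`, `"attribute_table"`. The record columns must
#' be exactly the schema columns (any order); the file is written with the
#' canonical column order and names.
#'
#' @param records Data frame of one schema.
#' @param schema_name One of the schema names above.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stats_csv <- function(records, schema_name, path) {
  schema_name <- match.arg(schema_name, names(.stats_schemas))
  cols <- .stats_schemas[[schema_name]]
  if (!setequal(names(records), cols))
    stop("validation error: records do not match schema `", schema_name,
         "`; expected columns ", paste(cols, collapse = ", "))
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read back a statistics CSV
#'
#' @param path Path to a CSV written by [write_stats_csv()].
#' @return Data frame.
#' @export
read_stats_csv <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
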