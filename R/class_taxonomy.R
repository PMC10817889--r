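#' CDL class code registry
#'
#' The standard published legend of Cropland Data Layer integer codes and
#' class names, shipped as package metadata. It is used to expand name-only
#' crop lists in match tables into codes, and to attach class names in the
#' validation statistics.
#'
#' @return Data frame with columns `code` (integer) and `name` (character).
#' @export
cdl_code_registry <- function() {
  path <- system.file("extdata", "cdl_codes.csv", package = "spanmerge",
                      mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  reg$code <- as.integer(reg$code)
  reg
}

#' Look up CDL class names for codes
#'
#' @param codes Integer CDL codes (positive, as in the source raster).
#' @param registry Registry data frame, defaults to [cdl_code_registry()].
#' @return Character vector of names; unknown codes yield `"CDL <code>"`.
#' @export
cdl_class_name <- function(codes, registry = cdl_code_registry()) {
  i <- match(codes, registry$code)
  out <- registry$name[i]
  out[is.na(i)] <- paste0("CDL ", codes[is.na(i)])
  out
}

.parse_int_list <- function(x, row, field) {
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  vals <- suppressWarnings(as.integer(parts))
  if (length(vals) == 0 || anyNA(vals))
    stop("parse error in match table row ", row, ": field `", field,
         "` is not a ;-delimited integer list: ", x)
  vals
}

#' Load a vegetation-to-crop class match table
#'
#' Reads a CSV with columns `group_name`, `nvc_values`, `cdl_names`,
#' `cdl_values` where the list-valued cells are semicolon delimited. Each row
#' is one agricultural vegetation group (e.g. Vineyard) with its geographic /
#' climatic NVC code variants and the set of CDL crop codes considered a
#' match. A CDL code may legitimately appear in several groups; NVC codes may
#' not.
#'
#' @param path Path to the CSV.
#' @param strict If `TRUE` (default), reject duplicate NVC codes across groups
#'   and non-positive codes.
#' @return A `class_match_table`: list with `groups` (list of match groups),
#'   `nvc_ag_set`, `cdl_ag_set` and an `nvc_lookup` (named integer vector
#'   mapping NVC code to group index).
#' @export
load_match_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("match table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("group_name", "nvc_values", "cdl_names", "cdl_values")
  if (!all(need %in% names(raw)))
    stop("parse error: match table must have columns ",
         paste(need, collapse = ", "))
  if (nrow(raw) == 0) stop("parse error: match table has no rows: ", path)
  groups <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    nvc <- .parse_int_list(raw$nvc_values[i], i, "nvc_values")
    cdl <- .parse_int_list(raw$cdl_values[i], i, "cdl_values")
    nms <- trimws(strsplit(raw$cdl_names[i], ";", fixed = TRUE)[[1]])
    if (length(nms) != length(cdl))
      stop("parse error in match table row ", i,
           ": cdl_names and cdl_values lengths differ")
    if (strict && any(c(nvc, cdl) <= 0))
      stop("validation error in match table row ", i,
           ": codes must be positive integers")
    groups[[i]] <- list(group_name = raw$group_name[i], nvc_values = nvc,
                        cdl_values = cdl, cdl_names = nms)
  }
  all_nvc <- unlist(lapply(groups, `[[`, "nvc_values"))
  if (strict && anyDuplicated(all_nvc)) {
    dup <- unique(all_nvc[duplicated(all_nvc)])
    stop("validation error: NVC code(s) ", paste(dup, collapse = ", "),
         " appear in more than one group")
  }
  lookup <- rep(seq_along(groups), vapply(groups, function(g)
    length(g$nvc_values), integer(1)))
  names(lookup) <- as.character(all_nvc)
  structure(list(groups = groups,
                 nvc_ag_set = sort(unique(all_nvc)),
                 cdl_ag_set = sort(unique(unlist(lapply(groups, `[[`, "cdl_values")))),
                 nvc_lookup = lookup),
            class = "class_match_table")
}

#' @export
print.class_match_table <- function(x, ...) {
  cat("class_match_table:", length(x$groups), "groups,",
      length(x$nvc_ag_set), "NVC codes,", length(x$cdl_ag_set),
      "distinct CDL crop codes\n")
  for (g in x$groups)
    cat("  ", g$group_name, ": NVC {", paste(g$nvc_values, collapse = ","),
        "} <- ", length(g$cdl_values), " CDL classes\n", sep = "")
  invisible(x)
}

#' The packaged default match table
#'
#' Ten agricultural vegetation groups: Vineyard; Bush fruit and berries;
#' Orchard; Aquaculture; and six groups (Row Crop - Close Grown Crop, Row
#' Crop, Close Grown Crop, Fallow/Idle, Pasture and hayland, Wheat) sharing a
#' pooled match set of fallow, grass/pasture, hay and all annual/rotation
#' crops. The pooling reflects crop rotation: a single vegetation map year is
#' combined with many crop years, so any rotation crop is accepted on
#' row-crop-type pixels.
#'
#' @return A `class_match_table`.
#' @export
default_match_table <- function() {
  load_match_table(system.file("extdata", "nvc_cdl_matches.csv",
                               package = "spanmerge", mustWork = TRUE))
}

#' Find the match group of an NVC code
#'
#' @param nvc Integer NVC code(s).
#' @param table A `class_match_table`.
#' @return Character group names (`NA` for non-agricultural codes).
#' @export
nvc_group_name <- function(nvc, table) {
  idx <- table$nvc_lookup[as.character(nvc)]
  nm <- vapply(table$groups, `[[`, character(1), "group_name")
  out <- nm[idx]
  out[is.na(idx)] <- NA_character_
  out
}

#' Classify a vegetation/crop pixel pair
#'
#' Total over all integer pairs: `PASSTHROUGH` when the vegetation code is not
#' an agricultural class (natural vegetation, the developed classes, nodata);
#' `MATCHED` when the crop code is in the focal group's match set;
#' `MISMATCHED` otherwise — including crop-layer background/nodata and
#' non-agricultural crop-layer classes, which the workflow treats as conflict,
#' not as an error.
#'
#' @param nvc,cdl Integer code vectors (recycled to a common length).
#' @param table A `class_match_table`.
#' @return Factor with levels `PASSTHROUGH`, `MATCHED`, `MISMATCHED`.
#' @examples
#' tab <- default_match_table()
#' classify_pair(7961, 69, tab)   # Vineyard over Grapes -> MATCHED
#' classify_pair(7961, 242, tab)  # Vineyard over Blueberries -> MISMATCHED
#' @export
classify_pair <- function(nvc, cdl, table) {
  rel <- classify_relation(nvc, cdl, table)
  factor(c("PASSTHROUGH", "MATCHED", "MISMATCHED")[rel + 1L],
         levels = c("PASSTHROUGH", "MATCHED", "MISMATCHED"))
}

#' Vectorised pair classification as integer codes
#'
#' Workhorse behind [classify_pair()] and the merge: returns `0` for
#' passthrough, `1` for matched, `2` for mismatched, preserving the shape of
#' the input.
#'
#' @inheritParams classify_pair
#' @return Integer vector/matrix shaped like `nvc`.
#' @export
classify_relation <- function(nvc, cdl, table) {
  stopifnot(inherits(table, "class_match_table"))
  n <- length(nvc)
  if (length(cdl) != n) stop("`nvc` and `cdl` must have equal length")
  gi <- table$nvc_lookup[as.character(nvc)]          # NA for non-ag
  rel <- integer(n)                                  # 0 = passthrough
  ag <- !is.na(gi)
  if (any(ag)) {
    # membership key: group index * offset + cdl code (codes < 1000)
    key <- unlist(lapply(seq_along(table$groups), function(i)
      i * 100000L + table$groups[[i]]$cdl_values))
    hit <- (gi[ag] * 100000L + as.integer(cdl[ag])) %in% key
    rel[ag] <- ifelse(hit, 1L, 2L)
  }
  if (is.matrix(nvc)) dim(rel) <- dim(nvc)
  rel
}

#' Merged-raster code scheme
#'
#' Output value conventions of the merged product: crop classes carry negated
#' CDL codes (to avoid colliding with vegetation codes), vegetation and
#' developed classes pass through unchanged, and a reserved code marks pixels
#' whose conflict could not be resolved.
#'
#' @param unresolved_code Integer, default `-1001`.
#' @param table Optional `class_match_table`; when given, the scheme is
#'   checked for collisions against its code sets.
#' @return A `code_scheme` list with fields `unresolved_code`, `encode`
#'   (crop code -> merged value) and `decode` (merged value -> crop code).
#' @export
code_scheme <- function(unresolved_code = -1001L, table = NULL) {
  unresolved_code <- as.integer(unresolved_code)
  if (!is.null(table)) {
    if ((-unresolved_code) %in% table$cdl_ag_set ||
        unresolved_code %in% table$nvc_ag_set)
      stop("unresolved code ", unresolved_code,
           " collides with a class code in the match table")
  }
  structure(list(unresolved_code = unresolved_code,
                 encode = function(cdl) -as.integer(cdl),
                 decode = function(v) -as.integer(v)),
            class = "code_scheme")
}

#' Build the merged-raster attribute table
#'
#' Combines vegetation-layer attribute rows (passed through unchanged), the
#' crop-layer rows for every matchable crop code (with `Value` negated), and
#' one row for the unresolved code. Source rows must cover all codes the
#' merge can produce.
#'
#' @param table A `class_match_table`.
#' @param nvc_attributes,cdl_attributes Data frames with columns `Value`,
#'   `Class_Name`, `Red`, `Green`, `Blue` describing the source rasters.
#'   `cdl_attributes` uses original (positive) crop codes.
#' @param scheme A [code_scheme()].
#' @param unresolved_name Class name for the unresolved row.
#' @return Data frame in the same schema; `Value` is unique.
#' @export
build_attribute_table <- function(table, nvc_attributes, cdl_attributes,
                                  scheme = code_scheme(),
                                  unresolved_name = "Unresolved land cover") {
  need <- c("Value", "Class_Name", "Red", "Green", "Blue")
  for (d in list(nvc_attributes, cdl_attributes))
    if (!all(need %in% names(d)))
      stop("attribute rows must have columns ", paste(need, collapse = ", "))
  missing_cdl <- setdiff(table$cdl_ag_set, cdl_attributes$Value)
  if (length(missing_cdl))
    stop("completeness error: no attribute row for CDL code(s) ",
         paste(missing_cdl, collapse = ", "))
  cdl_rows <- cdl_attributes[cdl_attributes$Value %in% table$cdl_ag_set, need]
  cdl_rows$Value <- scheme$encode(cdl_rows$Value)
  unres <- data.frame(Value = scheme$unresolved_code,
                      Class_Name = unresolved_name,
                      Red = 128L, Green = 128L, Blue = 128L)
  out <- rbind(nvc_attributes[, need], cdl_rows, unres)
  if (anyDuplicated(out$Value))
    stop("attribute table Values are not unique: ",
         paste(unique(out$Value[duplicated(out$Value)]), collapse = ", "))
  rownames(out) <- NULL
  out
}
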