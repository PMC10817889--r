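#' Per-zone mismatch accounting after step one
#'
#' Counts, for every accounting zone (county-like unit), vegetation group and
#' conflicting crop-layer class, the number of step-one mismatched pixels,
#' with the per-zone pixel count of the vegetation group as denominator.
#' Group names pool the geographic/climatic code variants of each
#' agricultural vegetation class. Zones with no agricultural pixels, and
#' zero-count combinations, emit no record.
#'
#' @param nvc,cdl Aligned [categorical_grid()]s.
#' @param zones A zone [categorical_grid()] (e.g. FIPS codes), same shape.
#' @param table A `class_match_table`.
#' @param year Year label written to `CDL_Year`.
#' @param variant_grouping Optional named character vector mapping NVC code
#'   to display group; defaults to the match-table group names.
#' @param zone_info Optional data frame with columns `FIPS` and `State` (and
#'   optionally `County`, `LF2010_Region`) to label zones.
#' @param registry CDL registry for class names.
#' @return Data frame with columns `FIPS`, `State`, `CDL_Year`, `CDL_Class`,
#'   `CDL_Name`, `NVC_Name`, `NCells_Mismatch`, `NCells_NVCClass_perCounty`,
#'   `NVC_CDL_Pair`, `Pct_Mismatch`.
#' @export
mismatch_stats <- function(nvc, cdl, zones, table, year,
                           variant_grouping = NULL, zone_info = NULL,
                           registry = cdl_code_registry()) {
  check_alignment(nvc, cdl)
  check_alignment(nvc, zones, "zones")
  rel <- classify_relation(nvc$values, cdl$values, table)
  keep <- zones$values != zones$nodata & rel > 0L       # agricultural pixels
  if (!any(keep)) return(.empty_mismatch_df())
  if (is.null(variant_grouping)) {
    variant_grouping <- stats::setNames(
      nvc_group_name(table$nvc_ag_set, table), as.character(table$nvc_ag_set))
  }
  zone <- zones$values[keep]
  grp <- unname(variant_grouping[as.character(nvc$values[keep])])
  # denominator: zone x group pixel counts over all agricultural pixels
  denom <- stats::aggregate(list(NCells_NVCClass_perCounty = rep(1L, sum(keep))),
                            by = list(FIPS = zone, NVC_Name = grp), FUN = sum)
  mis <- rel[keep] == 2L
  if (!any(mis)) return(.empty_mismatch_df())
  num <- stats::aggregate(list(NCells_Mismatch = rep(1L, sum(mis))),
                          by = list(FIPS = zone[mis], NVC_Name = grp[mis],
                                    CDL_Class = cdl$values[keep][mis]),
                          FUN = sum)
  out <- base::merge(num, denom, by = c("FIPS", "NVC_Name"))
  out$CDL_Name <- cdl_class_name(out$CDL_Class, registry)
  out$CDL_Year <- year
  out$NVC_CDL_Pair <- paste(out$NVC_Name, out$CDL_Name, sep = "_")
  out$Pct_Mismatch <- 100 * out$NCells_Mismatch / out$NCells_NVCClass_perCounty
  out$State <- .zone_label(out$FIPS, zone_info, "State")
  out <- out[order(out$FIPS, out$NVC_Name, out$CDL_Class),
             c("FIPS", "State", "CDL_Year", "CDL_Class", "CDL_Name",
               "NVC_Name", "NCells_Mismatch", "NCells_NVCClass_perCounty",
               "NVC_CDL_Pair", "Pct_Mismatch")]
  rownames(out) <- NULL
  out
}

.empty_mismatch_df <- function() {
  data.frame(FIPS = integer(), State = character(), CDL_Year = integer(),
             CDL_Class = integer(), CDL_Name = character(),
             NVC_Name = character(), NCells_Mismatch = integer(),
             NCells_NVCClass_perCounty = integer(),
             NVC_CDL_Pair = character(), Pct_Mismatch = numeric())
}

.zone_label <- function(fips, zone_info, col, default = NA_character_) {
  if (is.null(zone_info) || !col %in% names(zone_info))
    return(rep(default, length(fips)))
  as.character(zone_info[[col]][match(fips, zone_info$FIPS)])
}

#' Per-zone unresolved accounting after step two
#'
#' For every zone, the number of merged pixels carrying the unresolved code
#' and the percent of the zone's pixel count. Every zone present in the zone
#' grid gets one record, including zero-count zones.
#'
#' @param result A completed `merge_result`.
#' @param zones A zone [categorical_grid()].
#' @param year Year label.
#' @param zone_info Optional zone labels (`FIPS`, `State`, `County`,
#'   `LF2010_Region`).
#' @param unresolved_code Integer code to count (default `-1001`).
#' @param class_name Display name of the unresolved class.
#' @return Data frame with columns `FIPS`, `State`, `CDL_Year`, `County`,
#'   `LF2010_Region`, `MergedRaster_Class`, `MergedRaster_ClassName`,
#'   `NCells`, `Pct_Unresolved`.
#' @export
unresolved_stats <- function(result, zones, year, zone_info = NULL,
                             unresolved_code = -1001L,
                             class_name = "Unresolved land cover") {
  stopifnot(inherits(result, "merge_result"))
  if (result$stage != "complete")
    stop("merge result is not complete; run resolve_step2() first")
  check_alignment(result$merged, zones, "zones")
  keep <- zones$values != zones$nodata
  zone <- zones$values[keep]
  un <- result$merged$values[keep] == unresolved_code
  tot <- tapply(rep(1L, length(zone)), zone, sum)
  cnt <- tapply(as.integer(un), zone, sum)
  fips <- as.integer(names(tot))
  out <- data.frame(FIPS = fips,
                    State = .zone_label(fips, zone_info, "State"),
                    CDL_Year = year,
                    County = .zone_label(fips, zone_info, "County"),
                    LF2010_Region = .zone_label(fips, zone_info, "LF2010_Region"),
                    MergedRaster_Class = as.integer(unresolved_code),
                    MergedRaster_ClassName = class_name,
                    NCells = as.integer(cnt),
                    Pct_Unresolved = 100 * as.integer(cnt) / as.integer(tot))
  out <- out[order(out$FIPS), ]
  rownames(out) <- NULL
  out
}

#' Area-weighted accuracy over classes with reference data
#'
#' Weighted mean of per-class user's and producer's accuracy, weights being
#' class pixel areas, restricted to classes that have reference data (and
#' non-missing accuracy values). Also returns the percent of the focal area
#' covered by reference data. With no covered class at all the accuracies
#' are `NA` and the coverage is 0.
#'
#' @param class_areas Named numeric vector: pixel count (or area) per class
#'   value.
#' @param records Data frame with columns `class_value`, `users_acc`,
#'   `producers_acc`, `has_reference`.
#' @return List with `WtdUserAcc`, `WtdProdAcc`, `WithData_Pct`.
#' @examples
#' rec <- data.frame(class_value = c(1, 2), users_acc = c(40, 60),
#'                   producers_acc = c(40, 60), has_reference = TRUE)
#' weighted_accuracy(c(`1` = 10, `2` = 10), rec)$WtdUserAcc  # 50
#' @export
weighted_accuracy <- function(class_areas, records) {
  if (length(class_areas) == 0) stop("at least one class is required")
  if (any(class_areas < 0)) stop("validation error: negative class area")
  need <- c("class_value", "users_acc", "producers_acc", "has_reference")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  cls <- as.numeric(names(class_areas))
  i <- match(cls, records$class_value)
  has <- !is.na(i) & records$has_reference[i] &
    !is.na(records$users_acc[i]) & !is.na(records$producers_acc[i])
  total <- sum(class_areas)
  w <- class_areas[has]
  if (!any(has) || sum(w) == 0 || total == 0)
    return(list(WtdUserAcc = NA_real_, WtdProdAcc = NA_real_,
                WithData_Pct = 0))
  list(WtdUserAcc = sum(w * records$users_acc[i[has]]) / sum(w),
       WtdProdAcc = sum(w * records$producers_acc[i[has]]) / sum(w),
       WithData_Pct = 100 * sum(w) / total)
}

#' Per-zone accuracy of the merged product
#'
#' For each zone, combines the per-class accuracy of the two source layers
#' weighted by the class areas in the merged raster: negative-coded classes
#' draw from the crop-layer records (by decoded code), positive-coded classes
#' from the vegetation-layer records. Unresolved pixels are excluded from the
#' focal group. Classes lacking any accuracy record are treated as having no
#' reference data (and reported via a message).
#'
#' @param merged Merged [categorical_grid()] using the package code scheme.
#' @param zones Zone [categorical_grid()].
#' @param cdl_records,nvc_records Accuracy data frames (`class_value` uses
#'   original positive codes), see [weighted_accuracy()].
#' @param scheme A [code_scheme()].
#' @param year Year label.
#' @param zone_info Optional zone labels.
#' @param dataset_name Value for `Dataset_Name` (default `"SPAN"`).
#' @param focal_group Value for `FocalGroup`.
#' @return Data frame with columns `FIPS`, `State`, `CDL_Year`, `County`,
#'   `FocalGroup`, `Dataset_Name`, `NCells_County`, `NCells_FocalGroup`,
#'   `FocalGroup_PctCounty`, `WithData_PctFocalGroup`, `WtdProdAcc`,
#'   `WtdUserAcc`.
#' @export
span_accuracy <- function(merged, zones, cdl_records, nvc_records,
                          scheme = code_scheme(), year = NA,
                          zone_info = NULL, dataset_name = "SPAN",
                          focal_group = "Agricultural and natural classes") {
  check_alignment(merged, zones, "zones")
  keep <- zones$values != zones$nodata & merged$values != merged$nodata
  zone <- zones$values[keep]
  val <- merged$values[keep]
  fips <- sort(unique(zone))
  # one combined record table on the merged code scale
  comb <- rbind(
    if (nrow(cdl_records))
      data.frame(class_value = scheme$encode(cdl_records$class_value),
                 users_acc = cdl_records$users_acc,
                 producers_acc = cdl_records$producers_acc,
                 has_reference = cdl_records$has_reference),
    if (nrow(nvc_records))
      nvc_records[, c("class_value", "users_acc", "producers_acc",
                      "has_reference")])
  missing_classes <- integer(0)
  rows <- lapply(fips, function(f) {
    v <- val[zone == f]
    ncell <- length(v)
    v <- v[v != scheme$unresolved_code]
    nfoc <- length(v)
    if (nfoc == 0) {
      acc <- list(WtdUserAcc = NA_real_, WtdProdAcc = NA_real_,
                  WithData_Pct = 0)
    } else {
      areas <- table(v)
      cls <- as.numeric(names(areas))
      missing_classes <<- union(missing_classes,
                                cls[!cls %in% comb$class_value])
      acc <- weighted_accuracy(stats::setNames(as.numeric(areas),
                                               names(areas)), comb)
    }
    data.frame(FIPS = f, State = .zone_label(f, zone_info, "State"),
               CDL_Year = year, County = .zone_label(f, zone_info, "County"),
               FocalGroup = focal_group, Dataset_Name = dataset_name,
               NCells_County = ncell, NCells_FocalGroup = nfoc,
               FocalGroup_PctCounty = 100 * nfoc / ncell,
               WithData_PctFocalGroup = acc$WithData_Pct,
               WtdProdAcc = acc$WtdProdAcc, WtdUserAcc = acc$WtdUserAcc)
  })
  if (length(missing_classes))
    message("span_accuracy: no accuracy record for class(es) ",
            paste(sort(missing_classes), collapse = ", "),
            "; treated as lacking reference data")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jenks natural breaks (exact Fisher optimal classification)
#'
#' Partitions values into `k` contiguous classes minimising the total
#' within-class sum of squared deviations, by dynamic programming over the
#' sorted values (exact, deterministic; first-optimum tie-break).
#'
#' @param values Numeric vector.
#' @param k Number of classes, `1 <= k <=` number of distinct values.
#' @return Numeric vector of `k + 1` breaks: the minimum followed by the
#'   maximum of each class. Values `v` fall in class `j` when
#'   `breaks[j] < v <= breaks[j + 1]` (lowest class closed on the left).
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)  # 1 3 12
#' @export
jenks_breaks <- function(values, k) {
  if (k < 1) stop("validation error: k must be >= 1")
  x <- sort(as.numeric(values))
  n <- length(x)
  if (length(unique(x)) < k)
    stop("validation error: k (", k, ") exceeds the number of distinct values (",
         length(unique(x)), ")")
  if (k == 1) return(c(x[1], x[n]))
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  ssd <- function(i, j) {   # vectorised over i, SSD of x[i..j]
    s <- cx[j + 1] - cx[i]; q <- cx2[j + 1] - cx2[i]
    pmax(q - s^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, k, n)        # D[m, j]: best cost of x[1..j] in m classes
  B <- matrix(1L, k, n)         # start index of the last class
  D[1, ] <- vapply(seq_len(n), function(j) ssd(1, j), numeric(1))
  for (m in 2:k) {
    for (j in m:n) {
      i <- m:j                   # last class is x[i..j]
      cost <- D[m - 1, i - 1] + ssd(i, j)
      b <- which.min(cost)
      D[m, j] <- cost[b]
      B[m, j] <- i[b]
    }
  }
  # recover class boundaries
  uppers <- numeric(k)
  j <- n
  for (m in k:1) {
    uppers[m] <- x[j]
    j <- B[m, j] - 1L
  }
  c(x[1], uppers)
}

#' Assign values to Jenks classes
#'
#' @param values Numeric vector.
#' @param breaks Breaks from [jenks_breaks()].
#' @return Integer class index per value (1-based).
#' @export
jenks_classify <- function(values, breaks) {
  uppers <- breaks[-1]          # class maxima; may repeat the overall min
  k <- length(uppers)
  vapply(as.numeric(values), function(v) {
    i <- which(uppers >= v)[1]
    if (is.na(i)) k else i      # values above the top break fall in class k
  }, integer(1))
}

#' Verify a merged raster against expectations
#'
#' Automated output checks: every pixel value must appear in the attribute
#' table (or be the nodata code), the spatial extent must match, and the CRS
#' must match. Returns a report rather than stopping, so a batch run can
#' collect failures.
#'
#' @param merged A [categorical_grid()].
#' @param attribute_table Data frame with a `Value` column.
#' @param expected_extent Named numeric (`xmin`, `xmax`, `ymin`, `ymax`) or
#'   `NULL` to skip.
#' @param expected_crs CRS string or `NULL` to skip.
#' @return A `verification_report`: list with `pass` flag and per-check
#'   results.
#' @export
verify_output <- function(merged, attribute_table, expected_extent = NULL,
                          expected_crs = NULL) {
  stopifnot(inherits(merged, "categorical_grid"))
  vals <- unique(as.vector(merged$values))
  unknown <- sort(setdiff(vals, c(attribute_table$Value, merged$nodata)))
  checks <- list(values = list(pass = length(unknown) == 0,
                               unknown_values = unknown))
  if (!is.null(expected_extent)) {
    ext <- grid_extent(merged)
    ok <- isTRUE(all.equal(unname(ext[names(expected_extent)]),
                           unname(expected_extent)))
    checks$extent <- list(pass = ok, actual = ext, expected = expected_extent)
  }
  if (!is.null(expected_crs))
    checks$crs <- list(pass = identical(merged$crs, expected_crs),
                       actual = merged$crs, expected = expected_crs)
  structure(list(pass = all(vapply(checks, `[[`, logical(1), "pass")),
                 checks = checks),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("verification:", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks)) {
    ck <- x$checks[[nm]]
    cat("  ", nm, ": ", if (ck$pass) "ok" else "FAIL", "\n", sep = "")
    if (nm == "values" && !ck$pass)
      cat("    unknown values: ", paste(ck$unknown_values, collapse = ", "),
          "\n", sep = "")
  }
  invisible(x)
}
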