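#' Specification for a synthetic landscape fixture
#'
#' Describes an aligned vegetation/crop grid pair with planted-field
#' structure: the grid is tessellated into axis-aligned rectangular fields,
#' each field is agricultural or natural, agricultural fields carry one
#' vegetation group and a matching crop, and disagreement is planted as (a)
#' whole conflicting fields, (b) a fixed fraction of scattered conflicting
#' pixels, and (c) isolated noise pixels — mirroring the two conflict kinds
#' seen in real data (non-agricultural crop-layer classes, and agricultural
#' classes outside the focal match set). Crop rotation across years stays
#' within match sets so it creates no conflict. Defaults reflect the
#' observed national conditions: about 5.5% of agricultural pixels in
#' conflict, plus a small noise rate.
#'
#' @param rows,cols Grid shape in pixels.
#' @param cell_size Cell size (default 30).
#' @param n_zones Number of county-like zones (vertical bands).
#' @param field_size Field side length in pixels.
#' @param ag_fraction Fraction of fields that are agricultural.
#' @param crop_pool Integer CDL crop codes available for planting; must be
#'   drawn from the match table's crop set.
#' @param natural_pool Integer vegetation codes for natural fields
#'   (synthetic codes, outside the agricultural set).
#' @param natural_cdl_pool Crop-layer codes for natural land (forest,
#'   shrubland, wetland style codes).
#' @param years Integer vector of crop years to generate.
#' @param conflict_rate Fraction of agricultural pixels (outside whole
#'   conflict fields) given a conflicting crop-layer class.
#' @param whole_field_conflict_count Number of agricultural fields whose
#'   every pixel conflicts.
#' @param noise_rate Rate of additional isolated conflicting pixels.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(rows = 96, cols = 96, cell_size = 30, n_zones = 3,
                         field_size = 8, ag_fraction = 0.6,
                         crop_pool = c(1L, 5L, 24L, 36L, 61L, 69L, 75L,
                                       92L, 176L, 242L),
                         natural_pool = c(7125L, 7192L, 7292L, 7311L),
                         natural_cdl_pool = c(141L, 142L, 152L, 190L),
                         years = 2016:2018, conflict_rate = 0.055,
                         whole_field_conflict_count = 1L, noise_rate = 0.01,
                         seed = 1L) {
  rates <- c(ag_fraction, conflict_rate, noise_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (rows < 1 || cols < 1 || field_size < 1) stop("invalid shape")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, n_zones = as.integer(n_zones),
                 field_size = as.integer(field_size),
                 ag_fraction = ag_fraction,
                 crop_pool = as.integer(crop_pool),
                 natural_pool = as.integer(natural_pool),
                 natural_cdl_pool = as.integer(natural_cdl_pool),
                 years = as.integer(years),
                 conflict_rate = conflict_rate,
                 whole_field_conflict_count = as.integer(whole_field_conflict_count),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Deterministic conflicting crop-layer code for a group: alternates between a
# natural code and the smallest agricultural code outside the group's match
# set, driven by `kind`.
.conflict_code <- function(group, table, spec, kind) {
  if (kind == "natural") return(spec$natural_cdl_pool[1])
  out <- setdiff(table$cdl_ag_set, group$cdl_values)
  if (length(out) == 0) return(spec$natural_cdl_pool[1])
  min(out)
}

#' Generate an aligned fixture pair with planted ground truth
#'
#' Builds the vegetation grid, one crop grid per year, a zone grid, zone
#' labels, synthetic attribute tables, and exact planted truth: the
#' mismatch mask, per-zone/per-group/per-crop-class mismatch counts, and the
#' per-zone unresolvable pixel counts. Unresolvability is computed here by a
#' direct Chebyshev-distance scan against the matched-pixel mask (independent
#' of the merge engine's summed-area-table implementation).
#'
#' @param spec A [fixture_spec()].
#' @param table A `class_match_table` (default the packaged table).
#' @param radius Window radius used for the unresolvable-truth computation
#'   (matches the default merge configuration).
#' @return List with elements `nvc`, `cdl_by_year` (named list), `zones`,
#'   `zone_info`, `nvc_attributes`, `cdl_attributes`, and `truth` (list:
#'   `mismatch_mask`, `mismatch` data frame, `unresolved_mask`, `unresolved`
#'   data frame, identical for every year by construction).
#' @export
generate_pair <- function(spec, table = default_match_table(), radius = 3L) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!all(spec$crop_pool %in% table$cdl_ag_set))
    stop("validation error: crop_pool codes ",
         paste(setdiff(spec$crop_pool, table$cdl_ag_set), collapse = ", "),
         " are not in the match table")
  if (any(spec$natural_pool %in% table$nvc_ag_set))
    stop("validation error: natural_pool contains agricultural codes")
  set.seed(spec$seed)
  nr <- spec$rows; nc <- spec$cols; fs <- spec$field_size

  # field tessellation
  frow <- (seq_len(nr) - 1L) %/% fs
  fcol <- (seq_len(nc) - 1L) %/% fs
  field_id <- outer(frow, fcol, function(a, b) a * (max(fcol) + 1L) + b + 1L)
  n_fields <- max(field_id)

  # groups usable with this crop pool
  g_ok <- which(vapply(table$groups, function(g)
    any(g$cdl_values %in% spec$crop_pool), logical(1)))
  if (length(g_ok) == 0)
    stop("validation error: crop_pool matches no group in the table")

  field_ag <- stats::runif(n_fields) < spec$ag_fraction
  field_grp <- rep(NA_integer_, n_fields)
  field_crop <- rep(NA_integer_, n_fields)
  field_nvc <- rep(NA_integer_, n_fields)
  for (f in which(field_ag)) {
    gi <- if (length(g_ok) == 1) g_ok else sample(g_ok, 1)
    g <- table$groups[[gi]]
    pool <- intersect(spec$crop_pool, g$cdl_values)
    field_grp[f] <- gi
    field_crop[f] <- if (length(pool) == 1) pool else sample(pool, 1)
    field_nvc[f] <- if (length(g$nvc_values) == 1) g$nvc_values else
      sample(g$nvc_values, 1)
  }
  field_nvc[!field_ag] <- sample(spec$natural_pool, sum(!field_ag),
                                 replace = TRUE)
  field_nat_cdl <- sample(spec$natural_cdl_pool, n_fields, replace = TRUE)

  nvc_vals <- matrix(field_nvc[field_id], nr, nc)
  cdl_base <- matrix(ifelse(field_ag[field_id], field_crop[field_id],
                            field_nat_cdl[field_id]), nr, nc)
  ag_mask <- matrix(field_ag[field_id], nr, nc)

  # plant whole-field conflicts
  conflict <- matrix(FALSE, nr, nc)
  wf <- integer(0)
  ag_fields <- which(field_ag)
  if (spec$whole_field_conflict_count > 0) {
    if (length(ag_fields) < spec$whole_field_conflict_count)
      stop("validation error: fewer agricultural fields than requested ",
           "whole-field conflicts")
    wf <- if (length(ag_fields) == 1) ag_fields else
      sample(ag_fields, spec$whole_field_conflict_count)
    for (f in wf) {
      px <- field_id == f
      kind <- if (f %% 2 == 0) "natural" else "ag"
      cdl_base[px] <- .conflict_code(table$groups[[field_grp[f]]], table,
                                     spec, kind)
      conflict[px] <- TRUE
    }
  }

  # scattered pixel conflicts + noise over the remaining agricultural pixels
  open <- which(ag_mask & !conflict)
  n_scatter <- floor(spec$conflict_rate * length(open))
  n_noise <- floor(spec$noise_rate * length(open))
  pick <- if (length(open)) sample(open, min(length(open),
                                             n_scatter + n_noise)) else integer(0)
  for (p in pick) {
    f <- field_id[p]
    kind <- if (p %% 2 == 0) "natural" else "ag"
    cdl_base[p] <- .conflict_code(table$groups[[field_grp[f]]], table, spec,
                                  kind)
    conflict[p] <- TRUE
  }

  # annual crop grids: rotate matched crops within the group's match set,
  # conflicts stay fixed across years
  cdl_by_year <- list()
  for (yi in seq_along(spec$years)) {
    cy <- cdl_base
    if (yi > 1) {
      for (f in setdiff(ag_fields, wf)) {
        g <- table$groups[[field_grp[f]]]
        pool <- intersect(spec$crop_pool, g$cdl_values)
        if (length(pool) > 1) {
          rot <- pool[1L + (match(field_crop[f], pool) - 1L + yi - 1L) %%
                        length(pool)]
          px <- field_id == f & !conflict
          cy[px] <- rot
        }
      }
    }
    cdl_by_year[[as.character(spec$years[yi])]] <-
      categorical_grid(cy, spec$cell_size, crs = "EPSG:5070", nodata = 0L)
  }

  # zones: vertical bands with FIPS-like codes
  zone_code <- 1001L + 2L * (pmin(floor((seq_len(nc) - 1L) /
                                          (nc / spec$n_zones)),
                                  spec$n_zones - 1L))
  zones_vals <- matrix(rep(as.integer(zone_code), each = nr), nr, nc)
  zone_info <- data.frame(FIPS = sort(unique(as.integer(zone_code))),
                          State = "ZZ",
                          County = paste("Synthetic County",
                                         seq_len(spec$n_zones)),
                          LF2010_Region = "SYN")

  nvc <- categorical_grid(nvc_vals, spec$cell_size, crs = "EPSG:5070",
                          nodata = -9999L)
  zones <- categorical_grid(zones_vals, spec$cell_size, crs = "EPSG:5070",
                            nodata = -1L)

  # planted truth: mismatch accounting per zone x group x conflicting class
  truth_mis <- .truth_mismatch(nvc_vals, cdl_base, zones_vals, conflict,
                               ag_mask, field_grp, field_id, table)
  # unresolvable truth: no matched pixel within Chebyshev distance `radius`
  matched_mask <- ag_mask & !conflict
  unres_mask <- .truth_unresolved(conflict, matched_mask, radius)
  zl <- zones_vals[unres_mask]
  un_cnt <- table(factor(zl, levels = zone_info$FIPS))
  truth_un <- data.frame(FIPS = zone_info$FIPS,
                         NCells = as.integer(un_cnt),
                         NCells_Zone = as.integer(table(factor(zones_vals,
                                          levels = zone_info$FIPS))))
  truth_un$Pct_Unresolved <- 100 * truth_un$NCells / truth_un$NCells_Zone

  list(nvc = nvc, cdl_by_year = cdl_by_year, zones = zones,
       zone_info = zone_info,
       nvc_attributes = synth_attribute_rows(sort(unique(as.vector(nvc_vals))),
                                             "NVC class"),
       cdl_attributes = synth_attribute_rows(table$cdl_ag_set, NULL),
       truth = list(mismatch_mask = conflict, mismatch = truth_mis,
                    unresolved_mask = unres_mask, unresolved = truth_un))
}

.truth_mismatch <- function(nvc_vals, cdl_base, zones_vals, conflict, ag_mask,
                            field_grp, field_id, table) {
  if (!any(conflict)) {
    return(data.frame(FIPS = integer(), NVC_Name = character(),
                      CDL_Class = integer(), NCells_Mismatch = integer(),
                      NCells_NVCClass_perCounty = integer()))
  }
  gname <- vapply(table$groups, `[[`, character(1), "group_name")
  grp_all <- gname[field_grp[field_id]]
  denom <- stats::aggregate(
    list(NCells_NVCClass_perCounty = rep(1L, sum(ag_mask))),
    by = list(FIPS = zones_vals[ag_mask], NVC_Name = grp_all[ag_mask]),
    FUN = sum)
  num <- stats::aggregate(
    list(NCells_Mismatch = rep(1L, sum(conflict))),
    by = list(FIPS = zones_vals[conflict], NVC_Name = grp_all[conflict],
              CDL_Class = cdl_base[conflict]), FUN = sum)
  out <- base::merge(num, denom, by = c("FIPS", "NVC_Name"))
  out <- out[order(out$FIPS, out$NVC_Name, out$CDL_Class), ]
  rownames(out) <- NULL
  out
}

# Direct per-pixel window scan: TRUE where a conflicting pixel has no matched
# pixel within Chebyshev distance r. Intentionally naive (independent of the
# merge engine's summed-area tables).
.truth_unresolved <- function(conflict, matched_mask, r) {
  nr <- nrow(conflict); nc <- ncol(conflict)
  out <- matrix(FALSE, nr, nc)
  idx <- which(conflict, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    win <- matched_mask[max(1, i - r):min(nr, i + r),
                        max(1, j - r):min(nc, j + r)]
    out[i, j] <- !any(win)
  }
  out
}

#' Synthetic attribute rows for a code set
#'
#' Deterministic names and colors, for building attribute tables in tests
#' and fixtures. For crop codes (when `prefix` is `NULL`) names come from
#' the packaged CDL registry.
#'
#' @param codes Integer codes.
#' @param prefix Name prefix, or `NULL` to use CDL registry names.
#' @return Data frame with `Value`, `Class_Name`, `Red`, `Green`, `Blue`.
#' @export
synth_attribute_rows <- function(codes, prefix = NULL) {
  nm <- if (is.null(prefix)) cdl_class_name(codes) else paste(prefix, codes)
  data.frame(Value = as.integer(codes), Class_Name = nm,
             Red = as.integer(codes * 37L %% 256L),
             Green = as.integer(codes * 59L %% 256L),
             Blue = as.integer(codes * 83L %% 256L))
}

#' Generate synthetic per-class accuracy records
#'
#' Reproducible user's/producer's accuracy records with a stated fraction of
#' classes lacking reference data (as with vegetation types that have too few
#' field plots to be assessed).
#'
#' @param classes Integer class codes (original positive codes).
#' @param seed Integer seed.
#' @param range Accuracy range (percent) to draw from.
#' @param frac_without_reference Fraction of classes with no reference data.
#' @return Data frame with `class_value`, `users_acc`, `producers_acc`,
#'   `has_reference`.
#' @export
generate_accuracy_records <- function(classes, seed = 1L, range = c(40, 95),
                                      frac_without_reference = 0.2) {
  if (length(classes) == 0) stop("`classes` must be nonempty")
  set.seed(seed)
  n <- length(classes)
  has <- stats::runif(n) >= frac_without_reference
  ua <- round(stats::runif(n, range[1], range[2]), 1)
  pa <- round(stats::runif(n, range[1], range[2]), 1)
  ua[!has] <- NA_real_; pa[!has] <- NA_real_
  data.frame(class_value = as.integer(classes), users_acc = ua,
             producers_acc = pa, has_reference = has)
}
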