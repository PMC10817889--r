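#' Merge configuration
#'
#' Parameters of the conflict-resolution step. The window is square with
#' Chebyshev radius `radius` (default 3, i.e. a 7x7 window = 90 m at 30 m
#' cells). `donor_policy` selects which neighbours may supply the modal crop:
#' `"matched_only"` (default) restricts donors to pixels that matched in step
#' one — this reproduces the observed behaviour that a wholly conflicting
#' field stays unresolved even when the crop layer there is agricultural —
#' while `"any_cdl_ag"` accepts any neighbour whose crop-layer class is
#' agricultural (the focal pixel itself never donates). Ties in the mode are
#' broken deterministically by CDL code.
#'
#' @param radius Integer window radius in pixels, >= 1.
#' @param donor_policy `"matched_only"` or `"any_cdl_ag"`.
#' @param tie_break `"smallest_code"` (default) or `"largest_code"`.
#' @param unresolved_code Integer code for unresolvable pixels.
#' @return A `merge_config` list.
#' @export
merge_config <- function(radius = 3L,
                         donor_policy = c("matched_only", "any_cdl_ag"),
                         tie_break = c("smallest_code", "largest_code"),
                         unresolved_code = -1001L) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1) stop("`radius` must be an integer >= 1")
  structure(list(radius = radius,
                 donor_policy = match.arg(donor_policy),
                 tie_break = match.arg(tie_break),
                 unresolved_code = as.integer(unresolved_code)),
            class = "merge_config")
}

#' Read a merge configuration from a key = value file
#'
#' Recognised keys: `radius`, `donor_policy`, `tie_break`, `unresolved_code`.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return A [merge_config()].
#' @export
read_merge_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("config parse error at line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  known <- c("radius", "donor_policy", "tie_break", "unresolved_code")
  if (any(!keys %in% known))
    stop("unknown config key(s): ", paste(setdiff(keys, known), collapse = ", "))
  args <- list()
  if ("radius" %in% keys) args$radius <- as.integer(vals[keys == "radius"])
  if ("donor_policy" %in% keys) args$donor_policy <- vals[keys == "donor_policy"]
  if ("tie_break" %in% keys) args$tie_break <- vals[keys == "tie_break"]
  if ("unresolved_code" %in% keys)
    args$unresolved_code <- as.integer(vals[keys == "unresolved_code"])
  do.call(merge_config, args)
}

# Counts of TRUE within the (2r+1)^2 Chebyshev window around every cell,
# truncated at the grid boundary, via a summed-area table.
.box_count <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  S <- matrix(0L, nr + 1L, nc + 1L)
  cs <- apply(mask, 2, cumsum)                 # over rows
  if (nr == 1L) cs <- matrix(cs, nrow = 1L)
  cs <- t(apply(cs, 1, cumsum))                # then over cols
  if (nc == 1L) cs <- matrix(cs, ncol = 1L)
  S[-1, -1] <- cs
  lo_r <- pmax(seq_len(nr) - r, 1L); hi_r <- pmin(seq_len(nr) + r, nr)
  lo_c <- pmax(seq_len(nc) - r, 1L); hi_c <- pmin(seq_len(nc) + r, nc)
  S[hi_r + 1L, hi_c + 1L, drop = FALSE] + S[lo_r, lo_c, drop = FALSE] -
    S[lo_r, hi_c + 1L, drop = FALSE] - S[hi_r + 1L, lo_c, drop = FALSE]
}

.merge_counts <- function(rel, mismatch_mask, unresolved_mask) {
  mm <- sum(mismatch_mask)
  un <- if (is.null(unresolved_mask)) 0L else sum(unresolved_mask)
  c(passthrough = sum(rel == 0L),
    matched = sum(rel == 1L),
    mismatched = mm,
    resolved = mm - un,
    unresolved = un)
}

#' Step one: reclassify matched agricultural pixels
#'
#' Pixels whose vegetation class is non-agricultural copy their vegetation
#' value unchanged. Agricultural pixels whose crop-layer class is in the
#' focal group's match set receive the negated crop code. Conflicting pixels
#' are flagged in `mismatch_mask` and left as `NA` placeholders for
#' [resolve_step2()].
#'
#' @param nvc,cdl Aligned [categorical_grid()]s (vegetation and crop layer).
#' @param table A `class_match_table`.
#' @param scheme A [code_scheme()].
#' @return A `merge_result`: list with `merged` (grid), `mismatch_mask`,
#'   `unresolved_mask` (logical matrices), `counts` and `stage = "step1"`.
#' @export
merge_step1 <- function(nvc, cdl, table, scheme = code_scheme()) {
  check_alignment(nvc, cdl)
  rel <- classify_relation(nvc$values, cdl$values, table)
  merged <- nvc$values
  merged[rel == 1L] <- scheme$encode(cdl$values[rel == 1L])
  merged[rel == 2L] <- NA_integer_
  mismatch_mask <- rel == 2L
  unresolved_mask <- matrix(FALSE, nrow(rel), ncol(rel))
  structure(list(merged = categorical_grid(merged, nvc$cell_size, nvc$origin,
                                           nvc$crs, nvc$nodata),
                 mismatch_mask = mismatch_mask,
                 unresolved_mask = unresolved_mask,
                 relation = rel,
                 counts = .merge_counts(rel, mismatch_mask, NULL),
                 stage = "step1"),
            class = "merge_result")
}

#' Step two: resolve conflicts by the modal neighbouring crop
#'
#' Every still-unassigned conflicting pixel receives the negated modal donor
#' crop code within Chebyshev distance `config$radius`; if no donor lies in
#' the window it receives `config$unresolved_code`. Donor eligibility is
#' fixed by the step-one state (a resolved pixel never becomes a donor), so
#' the pass is order-independent and re-running it on its own output is a
#' no-op.
#'
#' Internally the per-crop window counts are computed with summed-area
#' tables, one pass per distinct donor crop code, scanning codes in
#' tie-break order so the first maximal count wins.
#'
#' @param step1 A `merge_result` from [merge_step1()].
#' @param cdl The crop-layer [categorical_grid()] used in step one.
#' @param table A `class_match_table`.
#' @param config A [merge_config()].
#' @return A completed `merge_result` (`stage = "complete"`).
#' @export
resolve_step2 <- function(step1, cdl, table, config = merge_config()) {
  stopifnot(inherits(step1, "merge_result"))
  m <- step1$merged$values
  pending <- step1$mismatch_mask & is.na(m)
  r <- config$radius
  donor <- switch(config$donor_policy,
    matched_only = step1$relation == 1L,
    any_cdl_ag   = matrix(cdl$values %in% table$cdl_ag_set,
                          nrow(cdl$values), ncol(cdl$values)))
  unresolved_mask <- step1$unresolved_mask
  if (any(pending)) {
    codes <- sort(unique(cdl$values[donor]),
                  decreasing = (config$tie_break == "largest_code"))
    best_n <- matrix(0L, nrow(m), ncol(m))
    best_code <- matrix(NA_integer_, nrow(m), ncol(m))
    for (cc in codes) {
      mk <- donor & cdl$values == cc
      cnt <- .box_count(mk, r) - mk    # focal pixel never donates to itself
      upd <- pending & cnt > best_n
      if (any(upd)) { best_n[upd] <- cnt[upd]; best_code[upd] <- cc }
    }
    ok <- pending & best_n > 0L
    m[ok] <- -best_code[ok]
    un <- pending & best_n == 0L
    m[un] <- config$unresolved_code
    unresolved_mask <- unresolved_mask | un
  }
  structure(list(merged = categorical_grid(m, step1$merged$cell_size,
                                           step1$merged$origin,
                                           step1$merged$crs,
                                           step1$merged$nodata),
                 mismatch_mask = step1$mismatch_mask,
                 unresolved_mask = unresolved_mask,
                 relation = step1$relation,
                 counts = .merge_counts(step1$relation, step1$mismatch_mask,
                                        unresolved_mask),
                 stage = "complete"),
            class = "merge_result")
}

#' Two-step merge of a crop raster into a vegetation raster
#'
#' Composition of [merge_step1()] and [resolve_step2()]: reclassify matched
#' agricultural pixels to negated crop codes, then resolve conflicts by the
#' modal eligible crop in the moving window, else mark unresolved.
#' Deterministic for fixed inputs and configuration.
#'
#' @inheritParams merge_step1
#' @param config A [merge_config()].
#' @return A completed `merge_result`.
#' @examples
#' tab <- default_match_table()
#' nvc <- categorical_grid(matrix(c(7961L, 7292L, 7292L, 7292L), 2, 2))
#' cdl <- categorical_grid(matrix(c(69L, 141L, 141L, 141L), 2, 2))
#' res <- span_merge(nvc, cdl, tab)
#' res$merged$values[1, 1]   # -69: Vineyard pixel reassigned to Grapes
#' @export
span_merge <- function(nvc, cdl, table, scheme = code_scheme(),
                       config = merge_config()) {
  if (scheme$unresolved_code != config$unresolved_code)
    stop("scheme and config disagree on the unresolved code")
  resolve_step2(merge_step1(nvc, cdl, table, scheme), cdl, table, config)
}

#' @export
print.merge_result <- function(x, ...) {
  cat("merge_result (", x$stage, ")\n", sep = "")
  print(x$merged)
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Merge one vegetation raster with a series of annual crop rasters
#'
#' One independent merge per year; the vegetation passthrough pixels are
#' identical across years by construction.
#'
#' @inheritParams span_merge
#' @param cdl_by_year Named list of crop-layer grids, names are years.
#' @return Named list of `merge_result`, one per year.
#' @export
merge_annual_series <- function(nvc, cdl_by_year, table,
                                scheme = code_scheme(),
                                config = merge_config()) {
  if (is.null(names(cdl_by_year)) || any(!nzchar(names(cdl_by_year))))
    stop("`cdl_by_year` must be a named list (names are years)")
  for (yr in names(cdl_by_year)) check_alignment(nvc, cdl_by_year[[yr]], yr)
  lapply(cdl_by_year, function(cdl)
    span_merge(nvc, cdl, table, scheme, config))
}
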