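# Independent reference implementations used to cross-check the package.
# These deliberately use naive enumeration, not the production code paths.

# Full two-step merge by per-pixel window enumeration: relation by direct
# group search, donors counted cell by cell, mode via table(), smallest code
# on ties.
oracle_merge <- function(nvc_vals, cdl_vals, table, radius = 3L,
                         policy = "matched_only", unresolved = -1001L) {
  nr <- nrow(nvc_vals); nc <- ncol(nvc_vals)
  group_of <- function(v) {
    for (i in seq_along(table$groups))
      if (v %in% table$groups[[i]]$nvc_values) return(i)
    NA_integer_
  }
  rel <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gi <- group_of(nvc_vals[i, j])
    if (!is.na(gi))
      rel[i, j] <- if (cdl_vals[i, j] %in% table$groups[[gi]]$cdl_values)
        1L else 2L
  }
  donor <- if (policy == "matched_only") rel == 1L else
    matrix(cdl_vals %in% table$cdl_ag_set, nr, nc)
  out <- nvc_vals
  out[rel == 1L] <- -cdl_vals[rel == 1L]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (rel[i, j] != 2L) next
    vals <- integer(0)
    for (a in max(1, i - radius):min(nr, i + radius))
      for (b in max(1, j - radius):min(nc, j + radius))
        if (!(a == i && b == j) && donor[a, b])
          vals <- c(vals, cdl_vals[a, b])
    out[i, j] <- if (length(vals) == 0) unresolved else {
      tb <- table(vals)
      -min(as.integer(names(tb)[tb == max(tb)]))
    }
  }
  list(merged = out, relation = rel)
}

# Exhaustive optimal 1-D classification: tries every contiguous partition of
# the sorted values into k classes.
oracle_jenks <- function(values, k) {
  x <- sort(as.numeric(values)); n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(list(breaks = c(x[1], x[n]), objective = ssd(x)))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; bestb <- NULL
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    tot <- sum(vapply(seq_len(k), function(m)
      ssd(x[(b[m] + 1):b[m + 1]]), numeric(1)))
    if (tot < best - 1e-12) { best <- tot; bestb <- b }
  }
  list(breaks = c(x[1], x[bestb[-1]]), objective = best)
}

jenks_objective <- function(values, breaks) {
  cls <- jenks_classify(values, breaks)
  sum(vapply(split(as.numeric(values), cls), function(v)
    sum((v - mean(v))^2), numeric(1)))
}

# Random small grid pair mixing agricultural and natural codes on both
# layers; returns plain matrices.
random_pair <- function(nr, nc, table, seed) {
  set.seed(seed)
  nvc_codes <- c(table$nvc_ag_set, 7292L, 7125L, -9999L)
  cdl_codes <- c(1L, 5L, 61L, 69L, 75L, 176L, 242L, 141L, 152L, 0L)
  list(nvc = matrix(sample(nvc_codes, nr * nc, replace = TRUE), nr, nc),
       cdl = matrix(sample(cdl_codes, nr * nc, replace = TRUE), nr, nc))
}

# Wrap matrices as aligned grids with default georeferencing.
as_pair <- function(nvc_vals, cdl_vals, cell = 30) {
  list(nvc = categorical_grid(nvc_vals, cell),
       cdl = categorical_grid(cdl_vals, cell, nodata = 0L))
}

# TRUE where any TRUE cell of `mask` lies within Chebyshev distance r,
# by brute-force dilation (independent of the merge engine).
.donor_reach <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    out[max(1, i - r):min(nr, i + r), max(1, j - r):min(nc, j + r)] <- TRUE
  }
  out
}

# Conservation / accounting assertions shared by several tests.
expect_merge_invariants <- function(res, nvc, cdl, table,
                                    unresolved = -1001L) {
  ag <- matrix(nvc$values %in% table$nvc_ag_set, nrow(nvc$values))
  # non-agricultural pixels pass through bit-identically
  expect_identical(res$merged$values[!ag], nvc$values[!ag])
  # codomain: negated crop codes, vegetation codes present in input, unresolved
  out_vals <- unique(as.vector(res$merged$values))
  allowed <- c(-table$cdl_ag_set, unique(nvc$values[!ag]), unresolved)
  expect_length(setdiff(out_vals, allowed), 0)
  # accounting identities
  cnt <- res$counts
  expect_identical(unname(cnt["matched"] + cnt["mismatched"]), sum(ag))
  expect_identical(unname(cnt["resolved"] + cnt["unresolved"]),
                   unname(cnt["mismatched"]))
  expect_lte(cnt["unresolved"], cnt["mismatched"])
  expect_identical(sum(res$mismatch_mask), unname(cnt["mismatched"]))
  expect_identical(sum(res$unresolved_mask), unname(cnt["unresolved"]))
  invisible(res)
}
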