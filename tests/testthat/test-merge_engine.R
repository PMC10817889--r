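tab <- default_match_table()

test_that("step one reassigns matched pixels and flags conflicts", {
  nv <- matrix(7292L, 4, 4)
  nv[1, 1] <- 7961L   # Vineyard over Grapes -> matched
  nv[2, 2] <- 7968L   # Wheat over Fallow/Idle Cropland -> pooled match
  nv[3, 3] <- 7961L   # Vineyard over Corn -> conflict
  cd <- matrix(1L, 4, 4)
  cd[1, 1] <- 69L; cd[2, 2] <- 61L
  p <- as_pair(nv, cd)
  s1 <- merge_step1(p$nvc, p$cdl, tab)
  expect_identical(s1$merged$values[1, 1], -69L)
  expect_identical(s1$merged$values[2, 2], -61L)
  expect_true(is.na(s1$merged$values[3, 3]))
  expect_true(s1$mismatch_mask[3, 3])
  expect_identical(s1$merged$values[4, 4], 7292L)  # passthrough
  expect_identical(unname(s1$counts[c("passthrough", "matched", "mismatched")]),
                   c(13L, 2L, 1L))
  expect_identical(s1$stage, "step1")
})

test_that("misaligned inputs raise an alignment error, never resample", {
  a <- categorical_grid(matrix(7292L, 4, 4))
  expect_error(merge_step1(a, categorical_grid(matrix(1L, 4, 5)), tab),
               "alignment error")
  expect_error(merge_step1(a, categorical_grid(matrix(1L, 4, 4), origin = c(30, 0)), tab),
               "alignment error")
  expect_error(merge_step1(a, categorical_grid(matrix(1L, 4, 4), crs = "EPSG:4326"), tab),
               "alignment error")
})

test_that("conflicts resolve to the modal donor crop, smallest code on ties", {
  # row-crop field of corn with one conflicting focal pixel
  nv <- matrix(7964L, 7, 7)
  cd <- matrix(1L, 7, 7)
  cd[4, 4] <- 141L                      # forest at the focal pixel
  p <- as_pair(nv, cd)
  res <- span_merge(p$nvc, p$cdl, tab)
  expect_identical(res$merged$values[4, 4], -1L)
  expect_identical(unname(res$counts["resolved"]), 1L)

  # exact 5 vs 5 tie between corn (1) and soybeans (5) donors
  nv <- matrix(7292L, 5, 11)
  cd <- matrix(141L, 5, 11)
  nv[3, 6] <- 7961L; cd[3, 6] <- 176L   # vineyard over grass -> conflict
  nv[3, 1:5] <- 7964L; cd[3, 1:5] <- 1L  # but only cols 3:5 are in reach
  nv[3, 7:11] <- 7964L; cd[3, 7:9] <- 5L
  nv[1, 4:8] <- 7964L; cd[1, 4:8] <- c(1L, 1L, 5L, 5L, 141L)
  p <- as_pair(nv, cd)
  s1 <- merge_step1(p$nvc, p$cdl, tab)
  res <- resolve_step2(s1, p$cdl, tab, merge_config())
  # count donors by hand within radius 3 of (3, 6)
  win_r <- 1:5; win_c <- 3:9
  donor <- s1$relation == 1L
  vals <- cd[win_r, win_c][donor[win_r, win_c]]
  expect_identical(sum(vals == 1L), sum(vals == 5L))  # a true tie
  expect_identical(res$merged$values[3, 6], -1L)      # smallest code wins
  res_hi <- resolve_step2(s1, p$cdl, tab,
                          merge_config(tie_break = "largest_code"))
  expect_identical(res_hi$merged$values[3, 6], -5L)
})

test_that("no eligible donor within the window yields the unresolved code", {
  nv <- matrix(7292L, 9, 9); nv[5, 5] <- 7961L
  cd <- matrix(141L, 9, 9); cd[5, 5] <- 176L
  p <- as_pair(nv, cd)
  res <- span_merge(p$nvc, p$cdl, tab)
  expect_identical(res$merged$values[5, 5], -1001L)
  expect_true(res$unresolved_mask[5, 5])
  # a matched donor 3 cells away (Chebyshev) resolves it
  nv2 <- nv; cd2 <- cd
  nv2[2, 2] <- 7964L; cd2[2, 2] <- 5L
  p2 <- as_pair(nv2, cd2)
  res2 <- span_merge(p2$nvc, p2$cdl, tab)
  expect_identical(res2$merged$values[5, 5], -5L)
  # 4 cells away is out of reach
  nv3 <- nv; cd3 <- cd
  nv3[1, 1] <- 7964L; cd3[1, 1] <- 5L
  p3 <- as_pair(nv3, cd3)
  res3 <- span_merge(p3$nvc, p3$cdl, tab)
  expect_identical(res3$merged$values[5, 5], -1001L)
})

test_that("donor policies differ exactly on non-matched agricultural donors", {
  # focal vineyard conflict surrounded by agricultural CDL under natural NVC:
  # matched_only finds no donor, any_cdl_ag resolves
  nv <- matrix(7292L, 7, 7); nv[4, 4] <- 7961L
  cd <- matrix(1L, 7, 7); cd[4, 4] <- 176L
  p <- as_pair(nv, cd)
  res_m <- span_merge(p$nvc, p$cdl, tab, config = merge_config())
  res_a <- span_merge(p$nvc, p$cdl, tab,
                      config = merge_config(donor_policy = "any_cdl_ag"))
  expect_identical(res_m$merged$values[4, 4], -1001L)
  expect_identical(res_a$merged$values[4, 4], -1L)
  # the focal pixel's own agricultural CDL value never donates to itself
  nv2 <- matrix(7292L, 3, 3); nv2[2, 2] <- 7961L
  cd2 <- matrix(141L, 3, 3); cd2[2, 2] <- 176L
  p2 <- as_pair(nv2, cd2)
  res_self <- span_merge(p2$nvc, p2$cdl, tab,
                         config = merge_config(donor_policy = "any_cdl_ag"))
  expect_identical(res_self$merged$values[2, 2], -1001L)
})

test_that("resolution is idempotent and donors are fixed at step one", {
  fx <- generate_pair(fixture_spec(rows = 48, cols = 48, seed = 11), tab)
  res <- span_merge(fx$nvc, fx$cdl_by_year[[1]], tab)
  again <- resolve_step2(res, fx$cdl_by_year[[1]], tab, merge_config())
  expect_identical(again$merged$values, res$merged$values)
  expect_identical(again$counts, res$counts)
})

test_that("increasing the radius never increases the unresolved count", {
  fx <- generate_pair(fixture_spec(rows = 64, cols = 64, seed = 3,
                                   whole_field_conflict_count = 2L), tab)
  un <- vapply(1:5, function(r) {
    res <- span_merge(fx$nvc, fx$cdl_by_year[[1]], tab,
                      config = merge_config(radius = r))
    unname(res$counts["unresolved"])
  }, integer(1))
  expect_true(all(diff(un) <= 0))
})

test_that("an annual series merges independently with constant passthrough", {
  fx <- generate_pair(fixture_spec(rows = 48, cols = 48, seed = 5), tab)
  series <- merge_annual_series(fx$nvc, fx$cdl_by_year, tab)
  expect_named(series, names(fx$cdl_by_year))
  ag <- matrix(fx$nvc$values %in% tab$nvc_ag_set, 48)
  for (res in series)
    expect_identical(res$merged$values[!ag], fx$nvc$values[!ag])
  # rotation stays within match sets: mismatch masks identical across years
  for (res in series[-1])
    expect_identical(res$mismatch_mask, series[[1]]$mismatch_mask)
  # identical CDL grids give identical outputs
  dup <- merge_annual_series(fx$nvc, list(a = fx$cdl_by_year[[1]],
                                          b = fx$cdl_by_year[[1]]), tab)
  expect_identical(dup$a$merged$values, dup$b$merged$values)
  # misaligned year is named in the error
  bad <- fx$cdl_by_year
  bad[[2]] <- categorical_grid(bad[[2]]$values[1:10, 1:10, drop = FALSE])
  expect_error(merge_annual_series(fx$nvc, bad, tab), names(bad)[2])
})

test_that("merge configuration files round-trip and validate", {
  f <- tempfile()
  writeLines(c("radius = 2", "donor_policy = any_cdl_ag",
               "# comment", "tie_break = smallest_code",
               "unresolved_code = -1001"), f)
  cfg <- read_merge_config(f)
  expect_identical(cfg$radius, 2L)
  expect_identical(cfg$donor_policy, "any_cdl_ag")
  writeLines("nonsense = 1", f)
  expect_error(read_merge_config(f), "unknown config key")
  expect_error(merge_config(radius = 0), "radius")
})
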