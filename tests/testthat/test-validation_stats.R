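tab <- default_match_table()

make_zone_grid <- function(vals, nodata = -1L)
  categorical_grid(vals, nodata = nodata)

test_that("mismatch accounting uses per-zone group denominators", {
  # one zone, 10 vineyard pixels, 2 conflicting with the crop layer
  nv <- matrix(7292L, 5, 10)
  nv[1, ] <- c(rep(7961L, 5), rep(7971L, 5))   # two Vineyard variants
  cd <- matrix(141L, 5, 10)
  cd[1, ] <- 69L; cd[1, 3] <- 1L; cd[1, 8] <- 176L
  zones <- make_zone_grid(matrix(1001L, 5, 10))
  p <- as_pair(nv, cd)
  out <- mismatch_stats(p$nvc, p$cdl, zones, tab, 2017)
  expect_identical(nrow(out), 2L)   # one record per conflicting CDL class
  expect_true(all(out$NVC_Name == "Vineyard"))   # variants pooled
  expect_identical(sum(out$NCells_Mismatch), 2L)
  expect_true(all(out$NCells_NVCClass_perCounty == 10L))
  expect_equal(out$Pct_Mismatch, c(10, 10))
  expect_identical(out$CDL_Name[out$CDL_Class == 1], "Corn")
  expect_identical(out$NVC_CDL_Pair[out$CDL_Class == 1], "Vineyard_Corn")
  # totals per zone equal the step-one mismatched count
  s1 <- merge_step1(p$nvc, p$cdl, tab)
  expect_identical(sum(out$NCells_Mismatch), unname(s1$counts["mismatched"]))
})

test_that("zones without agricultural or conflicting pixels emit no record", {
  nv <- matrix(7292L, 4, 4)
  cd <- matrix(141L, 4, 4)
  zones <- make_zone_grid(matrix(1001L, 4, 4))
  p <- as_pair(nv, cd)
  out <- mismatch_stats(p$nvc, p$cdl, zones, tab, 2017)
  expect_identical(nrow(out), 0L)
  # agricultural but fully matched: still no record
  nv[2, ] <- 7961L; cd[2, ] <- 69L
  p <- as_pair(nv, cd)
  out2 <- mismatch_stats(p$nvc, p$cdl, zones, tab, 2017)
  expect_identical(nrow(out2), 0L)
})

test_that("unresolved accounting reports every zone including zeros", {
  nv <- matrix(7292L, 10, 20); cd <- matrix(141L, 10, 20)
  nv[5, 3] <- 7961L; cd[5, 3] <- 176L     # unresolvable conflict in zone A
  zones <- make_zone_grid(cbind(matrix(1001L, 10, 10), matrix(1003L, 10, 10)))
  p <- as_pair(nv, cd)
  res <- span_merge(p$nvc, p$cdl, tab)
  out <- unresolved_stats(res, zones, 2017,
                          zone_info = data.frame(FIPS = c(1001L, 1003L),
                                                 State = "ZZ",
                                                 County = c("A", "B"),
                                                 LF2010_Region = "SYN"))
  expect_identical(out$FIPS, c(1001L, 1003L))
  expect_identical(out$NCells, c(1L, 0L))
  expect_equal(out$Pct_Unresolved, c(1, 0))
  expect_true(all(out$MergedRaster_Class == -1001L))
  expect_identical(out$County, c("A", "B"))
  expect_error(unresolved_stats(merge_step1(p$nvc, p$cdl, tab), zones, 2017),
               "not complete")
})

test_that("weighted accuracy honours areas and reference coverage", {
  rec <- function(cls, ua, pa, has = TRUE)
    data.frame(class_value = cls, users_acc = ua, producers_acc = pa,
               has_reference = has)
  # single class identity
  one <- weighted_accuracy(c(`7` = 12), rec(7, 80, 70))
  expect_equal(one$WtdUserAcc, 80)
  expect_equal(one$WtdProdAcc, 70)
  expect_equal(one$WithData_Pct, 100)
  # equal-weight symmetry
  two <- weighted_accuracy(c(`1` = 10, `2` = 10),
                           rec(c(1, 2), c(40, 60), c(40, 60)))
  expect_equal(two$WtdUserAcc, 50)
  # permutation invariance in class order
  twoswap <- weighted_accuracy(c(`2` = 10, `1` = 10),
                               rec(c(2, 1), c(60, 40), c(60, 40)))
  expect_equal(twoswap$WtdUserAcc, two$WtdUserAcc)
  # 3:1 areas, one class without reference data
  cov <- weighted_accuracy(c(`1` = 30, `2` = 10),
                           rbind(rec(1, 80, 75), rec(2, NA, NA, FALSE)))
  expect_equal(cov$WtdUserAcc, 80)
  expect_equal(cov$WithData_Pct, 75)
  # weighted mean bounded by contributing accuracies; 3:1 weighting
  mix <- weighted_accuracy(c(`1` = 30, `2` = 10),
                           rec(c(1, 2), c(80, 40), c(70, 50)))
  expect_equal(mix$WtdUserAcc, 70)
  expect_equal(mix$WtdProdAcc, 65)
  # all classes without reference
  none <- weighted_accuracy(c(`1` = 5), rec(1, NA, NA, FALSE))
  expect_true(is.na(none$WtdUserAcc))
  expect_equal(none$WithData_Pct, 0)
  expect_error(weighted_accuracy(c(`1` = -3), rec(1, 50, 50)), "negative")
  expect_error(weighted_accuracy(numeric(0), rec(1, 50, 50)), "at least one")
})

test_that("merged-product accuracy composes the source-layer records", {
  # zone of 20 pixels: 10 crop (corn, acc 80) and 10 natural (acc 40)
  merged <- categorical_grid(matrix(c(rep(-1L, 10), rep(7292L, 10)), 4, 5))
  zones <- make_zone_grid(matrix(1001L, 4, 5))
  cdl_rec <- data.frame(class_value = 1L, users_acc = 80, producers_acc = 80,
                        has_reference = TRUE)
  nvc_rec <- data.frame(class_value = 7292L, users_acc = 40,
                        producers_acc = 40, has_reference = TRUE)
  out <- span_accuracy(merged, zones, cdl_rec, nvc_rec, year = 2017)
  expect_equal(out$WtdUserAcc, 60)
  expect_equal(out$WtdProdAcc, 60)
  expect_equal(out$WithData_PctFocalGroup, 100)
  expect_identical(out$Dataset_Name, "SPAN")
  # zone entirely natural equals the vegetation-only accuracy
  mnat <- categorical_grid(matrix(7292L, 4, 5))
  nat <- span_accuracy(mnat, zones, cdl_rec, nvc_rec, year = 2017)
  expect_equal(nat$WtdUserAcc, 40)
  # unresolved pixels are excluded from the focal group
  mun <- categorical_grid(matrix(-1001L, 4, 5))
  un <- span_accuracy(mun, zones, cdl_rec, nvc_rec, year = 2017)
  expect_true(is.na(un$WtdUserAcc))
  expect_equal(un$WithData_PctFocalGroup, 0)
  expect_identical(un$NCells_FocalGroup, 0L)
  # classes without records are treated as lacking reference, with a message
  mmix <- categorical_grid(matrix(c(rep(-1L, 10), rep(7999L, 10)), 4, 5))
  expect_message(out2 <- span_accuracy(mmix, zones, cdl_rec, nvc_rec,
                                       year = 2017), "7999")
  expect_equal(out2$WtdUserAcc, 80)
  expect_equal(out2$WithData_PctFocalGroup, 50)
})

test_that("Jenks breaks minimise within-class variance", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), 2), c(1, 3, 12))
  expect_equal(jenks_breaks(c(5, 1, 9), 1), c(1, 9))
  # k equal to the number of distinct values: zero within-class variance
  b <- jenks_breaks(c(4, 8, 15, 16), 4)
  expect_equal(jenks_objective(c(4, 8, 15, 16), b), 0)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "validation error")
  expect_error(jenks_breaks(1:5, 0), "validation error")
  # objective never increases with k
  set.seed(9)
  x <- stats::rnorm(40)
  obj <- vapply(1:6, function(k) jenks_objective(x, jenks_breaks(x, k)),
                numeric(1))
  expect_true(all(diff(obj) <= 1e-9))
  # classification assigns every value to exactly one class
  cls <- jenks_classify(x, jenks_breaks(x, 4))
  expect_false(anyNA(cls))
  expect_identical(sort(unique(cls)), 1:4)
})

test_that("output verification flags stray values, extent and CRS drift", {
  fx <- generate_pair(fixture_spec(rows = 32, cols = 32, seed = 2,
                                   years = 2016L), tab)
  res <- span_merge(fx$nvc, fx$cdl_by_year[[1]], tab)
  attr_tab <- build_attribute_table(tab, fx$nvc_attributes, fx$cdl_attributes)
  rep <- verify_output(res$merged, attr_tab,
                       expected_extent = grid_extent(res$merged),
                       expected_crs = "EPSG:5070")
  expect_true(rep$pass)
  bad <- res$merged
  bad$values[1, 1] <- 99999L
  rep2 <- verify_output(bad, attr_tab)
  expect_false(rep2$pass)
  expect_true(99999 %in% rep2$checks$values$unknown_values)
  shifted <- categorical_grid(res$merged$values, origin = c(500, 0))
  rep3 <- verify_output(shifted, attr_tab,
                        expected_extent = grid_extent(res$merged))
  expect_false(rep3$checks$extent$pass)
  rep4 <- verify_output(res$merged, attr_tab, expected_crs = "EPSG:4326")
  expect_false(rep4$checks$crs$pass)
})
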