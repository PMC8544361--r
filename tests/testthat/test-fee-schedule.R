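test_that("the diagnostic category fee reproduces the published derivation", {
  fee <- derive_category_fee(published_diagnostic_items())
  expect_identical(fee$fee_per_visit, 51.66) # 206.65 / 4, rounded to cents
  expect_identical(fee$category, "Diagnostic")
  expect_identical(fee$provenance, "derived_from_items")
})

test_that("the alternative denominator reading folds per-exposure adjuncts", {
  fee <- derive_category_fee(published_diagnostic_items(),
                             denominator_rule = "per_distinct_item")
  expect_identical(fee$fee_per_visit, 68.88) # 206.65 / 3
})

test_that("a single item of weight one is its own category fee", {
  one <- tibble::tibble(item_number = "511", description = "x",
                        category = "Restorative", mean_fee = 187.35,
                        frequency_weight = 1L)
  expect_identical(derive_category_fee(one)$fee_per_visit, 187.35)
  # per_distinct_item with only multi-exposure lines falls back to distinct items
  multi <- tibble::tibble(item_number = "022", description = "x",
                          category = "Diagnostic", mean_fee = 38.80,
                          frequency_weight = 2L)
  expect_identical(
    derive_category_fee(multi, "per_distinct_item")$fee_per_visit, 77.60)
})

test_that("empty or mixed-category item lists are rejected", {
  expect_error(derive_category_fee(published_diagnostic_items()[0, ]), "empty")
  mixed <- published_diagnostic_items()
  mixed$category[1] <- "Preventive"
  expect_error(derive_category_fee(mixed), "multiple categories")
})

test_that("derived fees are homogeneous of degree one in item fees", {
  items <- published_diagnostic_items()
  base <- derive_category_fee(items)$fee_per_visit
  for (c_scale in c(2, 10)) {
    scaled <- items
    scaled$mean_fee <- scaled$mean_fee * c_scale
    got <- derive_category_fee(scaled)$fee_per_visit
    # cent rounding of both sides allows at most a cent of slack
    expect_equal(got, base * c_scale, tolerance = 0.01)
  }
})

test_that("adding an above-average item raises the per-line-entry average", {
  items <- published_diagnostic_items()
  avg <- derive_category_fee(items)$fee_per_visit
  richer <- dplyr::bind_rows(items, tibble::tibble(
    item_number = "037", description = "high-fee item",
    category = "Diagnostic", mean_fee = avg + 100, frequency_weight = 1L))
  expect_gt(derive_category_fee(richer)$fee_per_visit, avg)
})

test_that("implied-fee calibration is the cost/visits quotient", {
  fee <- calibrate_implied_fee(246e6, 227198.794, "Prosthodontics")
  expect_equal(fee$fee_per_visit, 1082.752226, tolerance = 1e-9)
  expect_identical(fee$provenance, "calibrated")
  expect_identical(calibrate_implied_fee(0, 100)$fee_per_visit, 0)
  expect_error(calibrate_implied_fee(100, 0), "visits")
})

test_that("fee -> cost -> calibrated fee round-trips to machine precision", {
  for (f in c(51.66, 203, 1083, 0.01)) {
    v <- 227198.794
    back <- calibrate_implied_fee(f * v, v)$fee_per_visit
    expect_identical(back, f * v / v)
    expect_equal(back, f, tolerance = 1e-15)
  }
})

test_that("the default schedule covers all nine areas at published anchors", {
  fees <- load_fee_schedule()
  expect_identical(nrow(fees), 9L)
  expect_setequal(fees$category, service_areas())
  expect_identical(fees$fee_per_visit[fees$category == "Periodontics"], 203)
  expect_identical(fees$fee_per_visit[fees$category == "Prosthodontics"], 1083)
  expect_identical(fees$fee_per_visit[fees$category == "Diagnostic"], 51.66)
  prov <- setNames(fees$provenance, fees$category)
  expect_identical(unname(prov["Diagnostic"]), "derived_from_items")
  expect_identical(unname(prov["Restorative"]), "calibrated")
})

test_that("schedules missing a category or with bad fees are rejected", {
  conf <- tempfile(fileext = ".conf")
  fees8 <- default_fee_schedule()
  fees8 <- fees8[fees8$category != "Prosthodontics", ]
  writeLines(sprintf("%s = %f", fees8$category, fees8$fee_per_visit), conf)
  expect_error(load_fee_schedule(category_path = conf), "Prosthodontics")

  neg <- tempfile(fileext = ".csv")
  items <- published_diagnostic_items()
  items$mean_fee[2] <- -1
  readr::write_csv(tibble::as_tibble(items), neg)
  expect_error(load_fee_schedule(items_path = neg), "mean_fee must be >= 0")
})

test_that("an itemised file covering all areas loads into a full schedule", {
  path <- tempfile(fileext = ".csv")
  generate_fixture_fees(path, seed = 42)
  fees <- load_fee_schedule(items_path = path)
  expect_identical(nrow(fees), 9L)
  expect_true(all(fees$provenance == "derived_from_items"))
  expect_identical(fees$fee_per_visit[fees$category == "Diagnostic"], 51.66)
})
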