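test_that("published per-cell worked examples price and display correctly", {
  vt <- tibble::tibble(
    unit_id = "WA", jurisdiction = "WA",
    total_visits = 884042,
    area = c("Prosthodontics", "Periodontics"),
    visits = c(227198.794, 14144.672)
  )
  fees <- category_fees(tibble::tibble(
    category = c("Prosthodontics", "Periodontics"),
    fee_per_visit = c(1083, 203)), areas = NULL)
  ct <- compute_costs(vt, fees)
  expect_equal(ct$cost, c(246056293.902, 2871368.416), tolerance = 1e-12)
  expect_identical(format_aud(ct$cost), c("$246", "$3"))
})

test_that("the scenario multiplier scales every cell linearly", {
  pop <- generate_population(synthetic_spec(n_units = 100, seed = 2))
  mix <- service_mix()
  vt <- split_by_service(project_visits(pop, mix), mix)
  fees <- default_fee_schedule()
  base <- compute_costs(vt, fees)
  dva <- compute_costs(vt, fees, scenario_spec(0.79))
  expect_equal(dva$cost, base$cost * 0.79, tolerance = 1e-12)
  expect_identical(attr(dva, "multiplier"), 0.79)
  expect_error(scenario_spec(0), "> 0")
})

test_that("summing printed jurisdiction cells reproduces printed row totals", {
  printed <- published_cost_table()
  ct <- tibble::tibble(jurisdiction = printed$jurisdiction,
                       area = printed$area,
                       cost = printed$cost_millions * 1e6)
  rows <- aggregate_costs(ct, by = character())
  expect_identical(rows$cost[rows$area == "Prosthodontics"] / 1e6, 2612)
  expect_identical(rows$cost[rows$area == "Restorative"] / 1e6, 1295)
})

test_that("aggregation conserves totals, honours margins, ignores row order", {
  pop <- generate_population(synthetic_spec(n_units = 500, seed = 9))
  mix <- service_mix()
  vt <- split_by_service(project_visits(pop, mix), mix)
  ct <- compute_costs(vt, default_fee_schedule())
  grand <- sum(ct$cost)
  for (keys in list(character(), "decile", c("jurisdiction", "remoteness"))) {
    agg <- aggregate_costs(ct, by = keys)
    expect_equal(sum(agg$cost), grand, tolerance = 1e-12)
  }
  marg <- aggregate_costs(ct, by = "jurisdiction", margins = TRUE)
  inner <- marg[marg$jurisdiction != "Total" & marg$area != "Total", ]
  total_col <- marg[marg$jurisdiction == "Total" & marg$area != "Total", ]
  for (a in unique(inner$area)) {
    expect_equal(total_col$cost[total_col$area == a],
                 sum(inner$cost[inner$area == a]), tolerance = 1e-12)
  }
  grand_cell <- marg$cost[marg$jurisdiction == "Total" & marg$area == "Total"]
  expect_equal(grand_cell, grand, tolerance = 1e-12)

  shuffled <- ct[rev(seq_len(nrow(ct))), ]
  expect_equal(
    dplyr::arrange(aggregate_costs(shuffled, "jurisdiction"), jurisdiction, area),
    dplyr::arrange(aggregate_costs(ct, "jurisdiction"), jurisdiction, area),
    tolerance = 1e-12)

  one <- ct[ct$unit_id == ct$unit_id[1], ]
  agg1 <- aggregate_costs(one, by = c("jurisdiction", "decile", "remoteness"))
  expect_equal(sort(agg1$cost), sort(one$cost), tolerance = 1e-12)
})

test_that("missing fees and non-finite visits are rejected before computing", {
  vt <- tibble::tibble(unit_id = "u", area = "Prosthodontics", visits = 10)
  fees <- category_fees(tibble::tibble(category = "Periodontics",
                                       fee_per_visit = 203), areas = NULL)
  expect_error(compute_costs(vt, fees), "Prosthodontics")
  vt$visits <- NaN
  fees2 <- category_fees(tibble::tibble(category = "Prosthodontics",
                                        fee_per_visit = 1083), areas = NULL)
  expect_error(compute_costs(vt, fees2), "non-finite")
})

test_that("per-person costs divide group cost by group population", {
  pop <- tiny_pop(pops = c(600, 400), decile = c(1L, 2L))
  ct <- tibble::tibble(unit_id = c("u1", "u2"), decile = c(1L, 2L),
                       area = "General", cost = c(600000, 400000))
  pp <- per_person_cost(ct, pop, by = "decile")
  expect_equal(pp$cost_per_person, c(1000, 1000), tolerance = 1e-12)
  # proportionality: equal populations, costs C and 3C
  ct$cost <- c(1e6, 3e6)
  pop2 <- tiny_pop(pops = c(500, 500), decile = c(1L, 2L))
  pp2 <- per_person_cost(ct, pop2, by = "decile")
  expect_equal(pp2$cost_per_person[2] / pp2$cost_per_person[1], 3,
               tolerance = 1e-12)
})

test_that("zero-population groups are flagged undefined, not zero", {
  pop <- tiny_pop(pops = c(100, 0), decile = c(1L, 2L))
  ct <- tibble::tibble(unit_id = c("u1", "u2"), decile = c(1L, 2L),
                       area = "General", cost = c(1000, 50))
  pp <- per_person_cost(ct, pop, by = "decile")
  expect_true(pp$undefined[pp$decile == 2])
  expect_true(is.na(pp$cost_per_person[pp$decile == 2]))
})

test_that("decile averages weighted by population recover the national mean", {
  pop <- generate_population(synthetic_spec(n_units = 1000, seed = 13))
  mix <- service_mix()
  ct <- compute_costs(split_by_service(project_visits(pop, mix), mix),
                      default_fee_schedule())
  by_dec <- per_person_cost(ct, pop, by = "decile")
  national <- per_person_cost(ct, pop)$cost_per_person
  weighted <- sum(by_dec$cost_per_person * by_dec$pop_65plus) /
    sum(by_dec$pop_65plus)
  expect_equal(weighted, national, tolerance = 1e-9)
})

test_that("unit-level aggregation equals direct jurisdiction-level computation", {
  pop <- generate_population(synthetic_spec(n_units = 800, seed = 21))
  mix <- service_mix()
  fees <- default_fee_schedule()
  unit_ct <- compute_costs(split_by_service(project_visits(pop, mix), mix), fees)
  by_jur <- aggregate_costs(unit_ct, by = "jurisdiction")

  jur_pop <- total_population(pop, by = "jurisdiction")
  jur_tab <- population_table(tibble::tibble(
    unit_id = jur_pop$jurisdiction, jurisdiction = jur_pop$jurisdiction,
    decile = 5L, remoteness = "Unclassified",
    pop_65plus = jur_pop$pop_65plus))
  direct <- aggregate_costs(
    compute_costs(split_by_service(project_visits(jur_tab, mix), mix), fees),
    by = "jurisdiction")
  cmp <- dplyr::inner_join(by_jur, direct, by = c("jurisdiction", "area"))
  expect_identical(nrow(cmp), nrow(by_jur))
  expect_true(all(abs(cmp$cost.x - cmp$cost.y) <=
                    1e-9 * pmax(cmp$cost.x, 1)))
})

test_that("the millions display style matches the published convention", {
  expect_identical(format_aud(2871368.4), "$3")
  expect_identical(format_aud(412000), "$0.4")
  expect_identical(format_aud(0), "$0")
  expect_identical(format_aud(246056293.9), "$246")
  expect_identical(format_aud(2612e6), "$2612")
  expect_match(format_aud(412000, style = "whole_aud"), "^\\$412,000$")
})

test_that("the wide report lays out areas by descending national cost", {
  rep_ <- format_report(compute_costs(
    split_by_service(project_visits(published_population_table(), service_mix()),
                     service_mix()),
    default_fee_schedule()))
  expect_identical(names(rep_)[1], "area")
  expect_true(all(jurisdictions() %in% names(rep_)))
  expect_identical(rep_$area[1], "Prosthodontics")
  expect_identical(rep_$WA[rep_$area == "Prosthodontics"], "$246")
  expect_identical(rep_$WA[rep_$area == "Periodontics"], "$3")
})
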