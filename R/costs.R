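#' Scenario specification
#'
#' A scenario is a flat positive multiplier applied to every cost cell.
#' The default 1 is the private-practice fee baseline; 0.79 models pricing
#' the same services off the government veterans'-affairs schedule, which is
#' about 21% below the private survey means in aggregate.
#'
#' @param multiplier single positive number.
#' @return a list of class `agecost_scenario`.
#' @export
scenario_spec <- function(multiplier = 1) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 ||
      is.na(multiplier) || multiplier <= 0) {
    abort("Scenario multiplier must be a single number > 0.")
  }
  structure(list(multiplier = as.double(multiplier)),
            class = "agecost_scenario")
}

#' Price a visit table into an expenditure table
#'
#' Each (stratum, service area) visit count is multiplied by the area's
#' per-visit fee and the scenario multiplier:
#' `cost = visits * fee_per_visit * multiplier`, exactly, before any display
#' rounding. All areas appearing in the visit table must have a fee; missing
#' areas are rejected by name before any computation.
#'
#' @param vt an `agecost_visits` tibble from [split_by_service()].
#' @param fees an `agecost_fees` tibble (see [load_fee_schedule()]).
#' @param scenario an `agecost_scenario` (see [scenario_spec()]).
#' @return a tibble of class `agecost_cost`: the visit table plus
#'   `fee_per_visit` and `cost` (AUD/year) columns. Fee provenance and the
#'   multiplier are carried in attributes `fee_provenance` and `multiplier`.
#' @examples
#' vt <- split_by_service(884042, service_mix())
#' ct <- compute_costs(vt, default_fee_schedule())
#' format_report(ct, by = character())
#' @export
compute_costs <- function(vt, fees, scenario = scenario_spec()) {
  stopifnot(inherits(scenario, "agecost_scenario"))
  fees <- category_fees(fees, areas = NULL)
  vt <- tibble::as_tibble(vt)
  if (!all(c("area", "visits") %in% names(vt))) {
    abort("`vt` must be a long visit table with area and visits columns.")
  }
  if (any(!is.finite(vt$visits))) {
    abort("Visit table contains non-finite visit counts.")
  }
  missing_fee <- setdiff(unique(vt$area), fees$category)
  if (length(missing_fee) > 0) {
    abort(sprintf("No fee for area(s): %s.", paste(missing_fee, collapse = ", ")))
  }
  fee_map <- setNames(fees$fee_per_visit, fees$category)
  out <- vt
  out$fee_per_visit <- unname(fee_map[out$area])
  out$cost <- out$visits * out$fee_per_visit * scenario$multiplier
  attr(out, "multiplier") <- scenario$multiplier
  attr(out, "fee_provenance") <- setNames(fees$provenance, fees$category)
  class(out) <- c("agecost_cost", class(out))
  out
}

#' Aggregate an expenditure table over grouping keys
#'
#' Sums cost cells per service area over any combination of `jurisdiction`,
#' `decile` and `remoteness`. Group sums conserve the grand total exactly up
#' to floating-point associativity, and are invariant to the input row order.
#' With `margins = TRUE`, margin rows are appended: per area summed over all
#' groups (grouping columns set to `"Total"`), per group summed over areas
#' (`area = "Total"`), and the grand total.
#'
#' @param ct an `agecost_cost` tibble from [compute_costs()].
#' @param by character vector of grouping keys.
#' @param margins logical; append margin rows.
#' @return a tibble with the grouping columns, `area` and summed `cost`.
#' @export
aggregate_costs <- function(ct, by = character(), margins = FALSE) {
  check_by(by)
  ct <- tibble::as_tibble(ct)
  grouped <- ct |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "area")))) |>
    dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
  if (!margins) return(grouped)
  as_margin <- function(df, over) {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(c(by, "area"), over)))) |>
      dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
    for (col in over) df[[col]] <- "Total"
    df[c(by, "area", "cost")]
  }
  pieces <- list(grouped)
  if (length(by) > 0) pieces <- c(pieces, list(as_margin(grouped, by)))
  pieces <- c(pieces, list(as_margin(grouped, "area")))
  if (length(by) > 0) pieces <- c(pieces, list(as_margin(grouped, c(by, "area"))))
  out <- dplyr::bind_rows(pieces)
  if ("decile" %in% by) out$decile <- as.character(out$decile)
  out
}

#' Average annual cost per 65+ person, by group
#'
#' Divides each group's total expenditure (summed over service areas) by its
#' 65+ population. Groups with zero population are reported with an
#' `undefined` flag and `NA` cost per person -- never as zero.
#'
#' @param ct an `agecost_cost` tibble.
#' @param pt the `agecost_population` table the costs were computed from.
#' @param by character vector of grouping keys.
#' @return a tibble with the grouping columns, `cost` (AUD), `pop_65plus`,
#'   `cost_per_person` (AUD/person/year) and logical `undefined`.
#' @export
per_person_cost <- function(ct, pt, by = character()) {
  check_by(by)
  costs <- tibble::as_tibble(ct) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
  pops <- total_population(pt, by = by)
  out <- if (length(by) == 0) {
    dplyr::bind_cols(costs, pops)
  } else {
    dplyr::full_join(costs, pops, by = by)
  }
  out$cost <- ifelse(is.na(out$cost), 0, out$cost)
  out$pop_65plus <- ifelse(is.na(out$pop_65plus), 0, out$pop_65plus)
  out$undefined <- out$pop_65plus == 0
  out$cost_per_person <- ifelse(out$undefined, NA_real_,
                                out$cost / out$pop_65plus)
  out
}

#' Format costs the way national cost tables print them
#'
#' `style = "millions"` reproduces the published display convention: values
#' of one million AUD and above are rounded to the nearest million
#' (`"$246"`); positive values below one million are shown in millions to
#' one decimal (`"$0.4"`); an exact zero prints `"$0"`. `style = "whole_aud"`
#' prints the unrounded AUD amount. Formatting is display-only: every
#' aggregation in the package uses unrounded values, because tables of
#' rounded cells do not re-add to their own printed totals.
#'
#' @param ct an `agecost_cost` tibble.
#' @param style `"millions"` or `"whole_aud"`.
#' @param by grouping keys for the report columns; default
#'   `"jurisdiction"` yields the published wide layout (rows = service
#'   areas sorted by descending national cost, columns = jurisdictions plus
#'   a `Total` margin).
#' @return a tibble of formatted character cells with an `area` column.
#' @export
format_report <- function(ct, style = c("millions", "whole_aud"),
                          by = "jurisdiction") {
  style <- match.arg(style)
  by <- by[seq_len(min(length(by), 1))] # wide layout uses one key
  long <- aggregate_costs(ct, by = by)
  totals <- aggregate_costs(ct, by = character())
  totals_order <- totals$area[order(-totals$cost)]
  if (length(by) == 0) {
    out <- totals
    out <- out[match(totals_order, out$area), , drop = FALSE]
    out$cost <- format_aud(out$cost, style)
    return(tibble::as_tibble(out))
  }
  key <- by[1]
  wide <- long |>
    dplyr::mutate(group = as.character(.data[[key]])) |>
    dplyr::select("area", "group", "cost") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cost",
                       values_fill = 0)
  col_order <- intersect(jurisdictions(), names(wide))
  if (length(col_order) == 0) col_order <- setdiff(names(wide), "area")
  wide <- wide[c("area", col_order)]
  wide$Total <- rowSums(as.matrix(wide[col_order]))
  wide <- wide[match(totals_order, wide$area), , drop = FALSE]
  wide[-1] <- lapply(wide[-1], format_aud, style = style)
  tibble::as_tibble(wide)
}

#' @rdname format_report
#' @param x numeric vector of AUD amounts.
#' @export
format_aud <- function(x, style = c("millions", "whole_aud")) {
  style <- match.arg(style)
  if (style == "whole_aud") {
    return(paste0("$", format(x, big.mark = ",", scientific = FALSE,
                              trim = TRUE)))
  }
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return("$0")
    if (v < 1e6) return(sprintf("$%.1f", v / 1e6))
    sprintf("$%.0f", round(v / 1e6))
  }, character(1))
}

#' Write an expenditure table as long-format delimited text
#'
#' @param ct an `agecost_cost` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(ct, path) {
  readr::write_csv(tibble::as_tibble(ct), path)
  invisible(path)
}
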