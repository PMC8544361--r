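#' Project total annual dental visits per stratum
#'
#' Implements the first step of the demand model: total annual visits of a
#' stratum are its 65+ population multiplied by the national per-person visit
#' rate (default 2.58 visits/person/year), optionally scaled by the mix's
#' dentate fraction. The unrounded value is carried internally; integer
#' displays such as 884,042 for a population of 342,652 are a formatting
#' concern only (the exact product is 884,042.16).
#'
#' Projection is linear in population: `project_visits` of `c` times the
#' population equals `c` times the projected visits, and projecting pooled
#' strata equals pooling projected strata.
#'
#' @param table an `agecost_population` tibble (see [population_table()]).
#' @param mix an `agecost_mix` object (see [service_mix()]).
#' @return the population tibble with a `total_visits` column
#'   (visits/year, unrounded).
#' @examples
#' pop <- population_table(data.frame(
#'   unit_id = "WA", jurisdiction = "WA", decile = 5,
#'   remoteness = "MajorCity", pop_65plus = 342652))
#' project_visits(pop, service_mix())$total_visits # 884042.16
#' @export
project_visits <- function(table, mix = service_mix()) {
  stopifnot(inherits(mix, "agecost_mix"))
  out <- tibble::as_tibble(table)
  out$total_visits <- as.double(out$pop_65plus) *
    mix$mean_visits_per_person * mix$dentate_fraction
  out
}

#' Decompose total visits into service areas
#'
#' Second step of the demand model: the visits of each stratum are multiplied
#' by the mean number of services of each clinical area delivered per visit,
#' giving area-level visit counts in long format. Full floating precision is
#' preserved (published decompositions print three decimals). Summed over areas, the
#' decomposition equals `total_visits` times the sum of the per-visit means
#' (2.241 under the default mix).
#'
#' @param visits output of [project_visits()]: a tibble with stratum keys and
#'   a `total_visits` column. A bare numeric vector is also accepted and
#'   treated as one anonymous stratum per element.
#' @param mix an `agecost_mix` object.
#' @return a tibble of class `agecost_visits` in long format: stratum key
#'   columns, `area`, `visits`, plus the per-stratum `total_visits`.
#' @examples
#' split_by_service(884042, service_mix())
#' @export
split_by_service <- function(visits, mix = service_mix()) {
  stopifnot(inherits(mix, "agecost_mix"))
  if (is.numeric(visits)) {
    visits <- tibble::tibble(
      unit_id = paste0("stratum_", seq_along(visits)),
      total_visits = as.double(visits)
    )
  }
  visits <- tibble::as_tibble(visits)
  if (!"total_visits" %in% names(visits)) {
    abort("`visits` must have a total_visits column (see project_visits()).")
  }
  if (any(!is.finite(visits$total_visits)) || any(visits$total_visits < 0)) {
    abort("total_visits must be finite and >= 0.")
  }
  areas <- names(mix$per_visit_mean)
  out <- visits[rep(seq_len(nrow(visits)), each = length(areas)), , drop = FALSE]
  out$area <- rep(areas, times = nrow(visits))
  out$visits <- out$total_visits * unname(mix$per_visit_mean[out$area])
  class(out) <- c("agecost_visits", class(out))
  out
}

#' Aggregate area-level visits over grouping keys
#'
#' Sums the visit decomposition over strata, per service area, for any
#' combination of `jurisdiction`, `decile` and `remoteness` (none for a
#' national profile). Because the projection is linear, aggregating
#' stratum-level results equals projecting the pooled population directly.
#'
#' @param vt an `agecost_visits` tibble from [split_by_service()].
#' @param by character vector of grouping keys.
#' @return a tibble with the grouping columns, `area` and summed `visits`.
#' @export
national_visit_profile <- function(vt, by = character()) {
  check_by(by)
  tibble::as_tibble(vt) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "area")))) |>
    dplyr::summarise(visits = sum(.data$visits), .groups = "drop")
}

#' Write an area-level visit table as long-format delimited text
#'
#' @param vt an `agecost_visits` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_visit_table <- function(vt, path) {
  readr::write_csv(tibble::as_tibble(vt), path)
  invisible(path)
}
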