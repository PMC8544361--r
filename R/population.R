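#' Construct and validate a population table
#'
#' A population table holds one row per stratum: an aggregation cell of the
#' 65+ population identified by `unit_id` and labelled with `jurisdiction`,
#' `decile` (IRSD disadvantage decile, integer 1--10 with 1 = most
#' disadvantaged) and `remoteness`. Each person belongs to exactly one
#' stratum, so the table total is the population total and group sums under
#' any partition of the labels conserve it exactly (integer arithmetic).
#'
#' Strata are generic cells, not geographic polygons: the model's arithmetic
#' only ever consumes counts per label combination, so a census-unit join is
#' reduced to its label columns.
#'
#' @param x a data frame with columns `unit_id`, `jurisdiction`, `decile`,
#'   `remoteness`, `pop_65plus`.
#' @param jurisdictions character vector of admissible jurisdiction codes.
#' @param remoteness character vector of admissible remoteness labels.
#'   `"Unclassified"` is accepted by default so partially labelled tables
#'   still aggregate.
#' @return a tibble of class `agecost_population`.
#' @seealso [load_population()] to read one from a delimited file,
#'   [total_population()] to aggregate it.
#' @export
population_table <- function(x,
                             jurisdictions = agecost::jurisdictions(),
                             remoteness = remoteness_levels()) {
  check_label_set(jurisdictions, "Jurisdiction")
  check_label_set(remoteness, "Remoteness")
  x <- tibble::as_tibble(x)
  required <- c("unit_id", "jurisdiction", "decile", "remoteness", "pop_65plus")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("Population table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- x[required]
  x$unit_id <- as.character(x$unit_id)
  x$jurisdiction <- as.character(x$jurisdiction)
  x$remoteness <- as.character(x$remoteness)

  problems <- character()
  row_problem <- function(rows, msg) {
    if (length(rows) > 0) {
      sprintf("row %s: %s", paste(rows, collapse = ", "), msg)
    } else {
      character()
    }
  }

  dec <- suppressWarnings(as.numeric(x$decile))
  bad <- which(is.na(dec) | dec != round(dec) | dec < 1 | dec > 10)
  problems <- c(problems, row_problem(bad, "decile must be an integer in 1..10"))

  pop <- suppressWarnings(as.numeric(x$pop_65plus))
  bad <- which(is.na(pop) | pop != round(pop) | pop < 0)
  problems <- c(problems,
                row_problem(bad, "pop_65plus must be a non-negative integer"))

  bad <- which(is.na(x$unit_id) | !nzchar(x$unit_id))
  problems <- c(problems, row_problem(bad, "unit_id must be non-empty"))
  bad <- which(!(x$jurisdiction %in% jurisdictions))
  problems <- c(problems, row_problem(
    bad, sprintf("jurisdiction must be one of %s",
                 paste(jurisdictions, collapse = ", "))))
  bad <- which(!(x$remoteness %in% remoteness))
  problems <- c(problems, row_problem(
    bad, sprintf("remoteness must be one of %s",
                 paste(remoteness, collapse = ", "))))

  if (length(problems) > 0) {
    abort(c("Invalid population table.", problems))
  }
  if (anyDuplicated(x$unit_id)) {
    dup <- unique(x$unit_id[duplicated(x$unit_id)])
    abort(sprintf("Duplicated unit_id: %s.", paste(dup, collapse = ", ")))
  }

  x$decile <- as.integer(round(dec))
  x$pop_65plus <- as.integer(round(pop))
  class(x) <- c("agecost_population", class(x))
  x
}

#' Read a population table from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row (UTF-8), renames
#' columns according to `schema`, and validates the result with
#' [population_table()]. Rows failing validation are rejected with
#' row-indexed messages; a missing mapped column is a schema error.
#'
#' @param path path to a delimited text file.
#' @param schema named character vector mapping the canonical column names
#'   (`unit_id`, `jurisdiction`, `decile`, `remoteness`, `pop_65plus`) to the
#'   column names present in the file. Defaults to the identity mapping.
#' @param delim field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @inheritParams population_table
#' @return a validated `agecost_population` tibble (possibly with 0 rows).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("unit_id,jurisdiction,decile,remoteness,pop_65plus",
#'              "A,WA,5,MajorCity,342652"), f)
#' pop <- load_population(f)
#' total_population(pop)
#' @export
load_population <- function(path, schema = NULL, delim = NULL,
                            jurisdictions = agecost::jurisdictions(),
                            remoteness = remoteness_levels()) {
  if (!file.exists(path)) {
    abort(sprintf("Population file not found: %s.", path))
  }
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  canonical <- c("unit_id", "jurisdiction", "decile", "remoteness", "pop_65plus")
  schema <- as.list(schema %||% setNames(canonical, canonical))
  missing_map <- setdiff(canonical, names(schema))
  if (length(missing_map) > 0) {
    abort(sprintf("Schema must map column(s): %s.",
                  paste(missing_map, collapse = ", ")))
  }
  absent <- setdiff(unlist(schema[canonical]), names(df))
  if (length(absent) > 0) {
    abort(sprintf("Schema error: column(s) %s not present in %s.",
                  paste(absent, collapse = ", "), path))
  }
  out <- tibble::tibble(
    unit_id = df[[schema$unit_id]],
    jurisdiction = df[[schema$jurisdiction]],
    decile = df[[schema$decile]],
    remoteness = df[[schema$remoteness]],
    pop_65plus = df[[schema$pop_65plus]]
  )
  population_table(out, jurisdictions = jurisdictions, remoteness = remoteness)
}

#' Write a population table as delimited text
#'
#' Inverse of [load_population()] under the default schema: a load/write/load
#' round trip is the identity on ids, labels and counts.
#'
#' @param table an `agecost_population` tibble.
#' @param path output path.
#' @param delim field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_population <- function(table, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(table), path, delim = delim)
  invisible(path)
}

#' Aggregate population counts over grouping keys
#'
#' Sums `pop_65plus` over any combination of `jurisdiction`, `decile` and
#' `remoteness`. With `by = character()` returns the grand total as a one-row
#' tibble. Group sums always add to the ungrouped total exactly: counts are
#' integers and each stratum belongs to exactly one group.
#'
#' @param table an `agecost_population` tibble (see [population_table()]).
#' @param by character vector of grouping keys drawn from
#'   `c("jurisdiction", "decile", "remoteness")`.
#' @return a tibble with one row per group and a `pop_65plus` column.
#' @export
total_population <- function(table, by = character()) {
  check_by(by)
  tibble::as_tibble(table) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(pop_65plus = sum(as.double(.data$pop_65plus)),
                     .groups = "drop")
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) return(",")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}
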