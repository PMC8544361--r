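#' Service mix: visit rate and mean services per visit
#'
#' The service mix holds the two utilisation parameters of the model:
#'
#' * `mean_visits_per_person` — annual dental visits per person aged 65+.
#'   The default, 2.58 visits/person/year, is the national telephone-survey
#'   rate for dentate older adults, applied, as published, to the
#'   whole 65+ population. The optional `dentate_fraction` multiplier
#'   (default 1) is provided for sensitivity analyses that restrict the rate
#'   to the dentate population.
#' * `per_visit_mean` — mean number of services of each clinical area
#'   delivered per dental visit (dimensionless), from the 2003--04 wave of
#'   the national dentists' practice activity study. These are services per
#'   visit, not shares: they need not sum to 1 (the default set sums to
#'   2.241).
#'
#' @param mean_visits_per_person positive visit rate (visits/person/year).
#' @param per_visit_mean named numeric vector, mean services per visit by
#'   service area. Names must be unique and values non-negative.
#' @param dentate_fraction multiplier in (0, 1] applied to the visit rate;
#'   default 1 reproduces the published model exactly.
#' @param areas the configured service-area set; every name in
#'   `per_visit_mean` must belong to it.
#' @return a list of class `agecost_mix`.
#' @examples
#' mix <- service_mix()
#' sum(mix$per_visit_mean) # 2.241
#' @export
service_mix <- function(mean_visits_per_person = 2.58,
                        per_visit_mean = default_per_visit_mean(),
                        dentate_fraction = 1,
                        areas = service_areas()) {
  if (!is.numeric(mean_visits_per_person) || length(mean_visits_per_person) != 1 ||
      is.na(mean_visits_per_person) || mean_visits_per_person <= 0) {
    abort("mean_visits_per_person must be a single positive number.")
  }
  if (!is.numeric(dentate_fraction) || length(dentate_fraction) != 1 ||
      is.na(dentate_fraction) || dentate_fraction <= 0 || dentate_fraction > 1) {
    abort("dentate_fraction must be a single number in (0, 1].")
  }
  if (is.null(names(per_visit_mean)) || anyDuplicated(names(per_visit_mean)) ||
      any(!nzchar(names(per_visit_mean)))) {
    abort("per_visit_mean must be a named vector with unique non-empty names.")
  }
  if (any(!is.finite(per_visit_mean)) || any(per_visit_mean < 0)) {
    abort("per_visit_mean values must be finite and >= 0.")
  }
  check_label_set(areas, "ServiceArea")
  unknown <- setdiff(names(per_visit_mean), areas)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Configuration error: area(s) %s in the mix are not in the configured service-area set.",
      paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      mean_visits_per_person = as.double(mean_visits_per_person),
      per_visit_mean = as.double(per_visit_mean) |>
        setNames(names(per_visit_mean)),
      dentate_fraction = as.double(dentate_fraction),
      areas = areas
    ),
    class = "agecost_mix"
  )
}

#' @rdname service_mix
#' @export
default_per_visit_mean <- function() {
  c(Diagnostic = 0.671, Restorative = 0.641, Preventive = 0.343,
    Prosthodontics = 0.257, CrownBridge = 0.097, Endodontics = 0.096,
    OralSurgery = 0.091, General = 0.029, Periodontics = 0.016)
}

#' Read a service mix from a flat key=value config file
#'
#' The file format is one `key = value` pair per line (`#` comments and blank
#' lines ignored). `mean_visits_per_person` and optionally `dentate_fraction`
#' are scalar keys; every other key is taken as a service-area name with its
#' mean services per visit, e.g. `Diagnostic = 0.671`.
#'
#' @param path path to the config file.
#' @inheritParams service_mix
#' @return an `agecost_mix` object.
#' @export
load_service_mix <- function(path, areas = service_areas()) {
  kv <- read_flat_config(path)
  if (!"mean_visits_per_person" %in% names(kv)) {
    abort(sprintf("Mix config %s must define mean_visits_per_person.", path))
  }
  scalars <- c("mean_visits_per_person", "dentate_fraction")
  pv <- kv[setdiff(names(kv), scalars)]
  service_mix(
    mean_visits_per_person = kv[["mean_visits_per_person"]],
    per_visit_mean = unlist(pv),
    dentate_fraction = kv[["dentate_fraction"]] %||% 1,
    areas = areas
  )
}

#' @export
print.agecost_mix <- function(x, ...) {
  cat(sprintf("<service mix> %.3g visits/person/year (dentate fraction %.3g)\n",
              x$mean_visits_per_person, x$dentate_fraction))
  cat("services per visit:\n")
  print(round(x$per_visit_mean, 3))
  invisible(x)
}

# Flat `key = value` config reader shared by mix and scenario files.
read_flat_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  parts <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    abort(sprintf("Config %s: cannot parse line(s) %s (expected key = value).",
                  path, paste(bad, collapse = ", ")))
  }
  keys <- trimws(vapply(parts, `[`, "", 2))
  vals <- trimws(vapply(parts, `[`, "", 3))
  num <- suppressWarnings(as.numeric(vals))
  out <- as.list(ifelse(is.na(num), vals, num))
  out <- lapply(seq_along(out), function(i) if (is.na(num[i])) vals[i] else num[i])
  setNames(out, keys)
}
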