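#' Default label sets for the model's aggregation dimensions
#'
#' The model stratifies the 65+ population by three categorical labels:
#' Australian state/territory, IRSD socioeconomic-disadvantage decile
#' (integer 1--10, 1 = most disadvantaged 10% of population) and ABS-style
#' remoteness class. All label sets are configurable; these functions return
#' the defaults.
#'
#' `service_areas()` returns the nine clinical service areas of the Australian
#' Schedule of Dental Services used by the model. Orthodontics is deliberately
#' absent from the default set: no utilisation data exist for the 65+ cohort,
#' so it is excluded from the modelled service mix.
#'
#' @return A character vector of labels.
#' @examples
#' jurisdictions()
#' service_areas()
#' @export
jurisdictions <- function() {
  c("NSW", "Vic", "Qld", "WA", "SA", "Tas", "ACT", "NT")
}

#' @rdname jurisdictions
#' @param include_unclassified if `TRUE`, append the `"Unclassified"` label
#'   used for units whose remoteness is unknown. Partial tables then aggregate
#'   cleanly instead of being rejected.
#' @export
remoteness_levels <- function(include_unclassified = TRUE) {
  lv <- c("MajorCity", "InnerRegional", "OuterRegional", "Remote", "VeryRemote")
  if (include_unclassified) c(lv, "Unclassified") else lv
}

#' @rdname jurisdictions
#' @export
service_areas <- function() {
  c("Diagnostic", "Preventive", "Periodontics", "OralSurgery", "Endodontics",
    "Restorative", "CrownBridge", "Prosthodontics", "General")
}

# Grouping keys permitted in `by =` arguments throughout the package.
stratum_keys <- function() c("jurisdiction", "decile", "remoteness")

check_by <- function(by, extra = character()) {
  allowed <- c(stratum_keys(), extra)
  bad <- setdiff(by, allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown grouping key(s): %s. Allowed: %s.",
      paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  invisible(by)
}

check_label_set <- function(x, what) {
  if (length(x) == 0 || anyNA(x) || any(!nzchar(x))) {
    abort(sprintf("%s labels must be non-empty and non-missing.", what))
  }
  if (anyDuplicated(x)) {
    abort(sprintf("%s labels must be unique.", what))
  }
  invisible(x)
}
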