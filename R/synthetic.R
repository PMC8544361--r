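#' Specification for the synthetic small-area population generator
#'
#' The generator emulates the structure of the smallest census geography the
#' model consumes: units of roughly 200--800 residents, of which a fraction
#' is aged 65+, labelled with jurisdiction, remoteness class and an IRSD-style
#' disadvantage decile engineered so that each decile holds as near 10% of
#' the population as whole-unit assignment allows. It reproduces structure,
#' not geography: there is no spatial autocorrelation and no realistic
#' settlement pattern.
#'
#' @param n_units number of synthetic units (strata) to generate.
#' @param unit_pop_range integer interval for total unit population,
#'   default `c(200, 800)` (uniform).
#' @param aged_fraction_mean,aged_fraction_sd mean and sd of the per-unit
#'   65+ fraction, drawn from a normal clamped to `[0, 1]` (defaults 0.15
#'   and 0.05). A boundary mean (0 or 1) is treated as degenerate: every
#'   unit gets exactly that fraction.
#' @param jurisdiction_weights named probability vector over jurisdiction
#'   codes; default proportional to the bundled 65+ jurisdiction counts.
#' @param remoteness_weights either one named probability vector over
#'   remoteness labels applied to all jurisdictions, or a named list with
#'   one such vector per jurisdiction.
#' @param decile_assignment `"uniform_population_shares"` (each decile
#'   targets 10% of generated 65+ population) or `"supplied"` with
#'   `decile_shares` a 10-vector of target shares summing to 1.
#' @param decile_shares target decile shares when
#'   `decile_assignment = "supplied"`.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return a list of class `agecost_synth_spec`.
#' @seealso [generate_population()]
#' @export
synthetic_spec <- function(n_units,
                           unit_pop_range = c(200L, 800L),
                           aged_fraction_mean = 0.15,
                           aged_fraction_sd = 0.05,
                           jurisdiction_weights = NULL,
                           remoteness_weights = NULL,
                           decile_assignment = c("uniform_population_shares",
                                                 "supplied"),
                           decile_shares = NULL,
                           seed = 1L) {
  decile_assignment <- match.arg(decile_assignment)
  if (!is.numeric(n_units) || length(n_units) != 1 || is.na(n_units) ||
      n_units != round(n_units) || n_units < 1) {
    abort("Infeasible spec: n_units must be a positive integer.")
  }
  if (length(unit_pop_range) != 2 || any(unit_pop_range < 1) ||
      unit_pop_range[1] > unit_pop_range[2] ||
      any(unit_pop_range != round(unit_pop_range))) {
    abort("unit_pop_range must be an increasing pair of positive integers.")
  }
  if (aged_fraction_mean < 0 || aged_fraction_mean > 1 ||
      aged_fraction_sd < 0) {
    abort("aged_fraction_mean must lie in [0, 1] and aged_fraction_sd be >= 0.")
  }
  if (is.null(jurisdiction_weights)) {
    pp <- published_populations()
    jurisdiction_weights <- setNames(pp$pop_65plus / sum(pp$pop_65plus),
                                     pp$jurisdiction)
  }
  check_prob_vector(jurisdiction_weights, "jurisdiction_weights")
  if (is.null(remoteness_weights)) {
    remoteness_weights <- c(MajorCity = 0.60, InnerRegional = 0.24,
                            OuterRegional = 0.12, Remote = 0.03,
                            VeryRemote = 0.01)
  }
  if (!is.list(remoteness_weights)) {
    remoteness_weights <- setNames(
      rep(list(remoteness_weights), length(jurisdiction_weights)),
      names(jurisdiction_weights))
  }
  missing_j <- setdiff(names(jurisdiction_weights), names(remoteness_weights))
  if (length(missing_j) > 0) {
    abort(sprintf("remoteness_weights missing jurisdiction(s): %s.",
                  paste(missing_j, collapse = ", ")))
  }
  for (j in names(remoteness_weights)) {
    check_prob_vector(remoteness_weights[[j]],
                      sprintf("remoteness_weights[%s]", j))
  }
  if (decile_assignment == "supplied") {
    if (is.null(decile_shares) || length(decile_shares) != 10) {
      abort("decile_shares must be a 10-vector of target shares.")
    }
    check_prob_vector(setNames(decile_shares, as.character(1:10)),
                      "decile_shares")
  } else {
    decile_shares <- rep(0.1, 10)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    abort("seed must be a single integer.")
  }
  structure(list(
    n_units = as.integer(n_units),
    unit_pop_range = as.integer(unit_pop_range),
    aged_fraction_mean = as.double(aged_fraction_mean),
    aged_fraction_sd = as.double(aged_fraction_sd),
    jurisdiction_weights = jurisdiction_weights,
    remoteness_weights = remoteness_weights,
    decile_assignment = decile_assignment,
    decile_shares = as.double(decile_shares),
    seed = as.integer(seed)
  ), class = "agecost_synth_spec")
}

check_prob_vector <- function(w, what) {
  if (is.null(names(w)) || any(!nzchar(names(w))) || anyDuplicated(names(w))) {
    abort(sprintf("%s must be a named vector with unique names.", what))
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    abort(sprintf("%s must be a probability vector summing to 1 (within 1e-9).",
                  what))
  }
  invisible(w)
}

#' Generate a synthetic small-area population table
#'
#' Draws `n_units` census-like units according to `spec`: total unit
#' population uniform over `unit_pop_range`, 65+ count
#' `round(total * aged_fraction)` with the fraction drawn from a clamped
#' normal, jurisdiction and remoteness sampled from the configured weights.
#' Disadvantage deciles are then assigned by greedy fill over a reproducibly
#' shuffled unit order: units accumulate into decile 1 until it holds its
#' target share of the generated 65+ population, then decile 2, and so on.
#' Each decile's population therefore deviates from its target by at most
#' one unit's population. The result is fully reproducible from the configured
#' seed and always satisfies every [population_table()] invariant.
#'
#' @param spec an `agecost_synth_spec` (see [synthetic_spec()]).
#' @return an `agecost_population` tibble with `n_units` rows.
#' @examples
#' pop <- generate_population(synthetic_spec(n_units = 100, seed = 7))
#' total_population(pop, by = "decile")
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "agecost_synth_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_units
  total_pop <- sample(seq(spec$unit_pop_range[1], spec$unit_pop_range[2]),
                      n, replace = TRUE)
  frac <- if (spec$aged_fraction_mean %in% c(0, 1) ||
              spec$aged_fraction_sd == 0) {
    rep(spec$aged_fraction_mean, n)
  } else {
    pmin(pmax(rnorm(n, spec$aged_fraction_mean, spec$aged_fraction_sd), 0), 1)
  }
  pop65 <- as.integer(round(total_pop * frac))
  jur <- sample(names(spec$jurisdiction_weights), n, replace = TRUE,
                prob = spec$jurisdiction_weights)
  rem <- vapply(jur, function(j) {
    w <- spec$remoteness_weights[[j]]
    sample(names(w), 1, prob = w)
  }, character(1))

  # Greedy decile fill over a reproducible shuffle of the units.
  ord <- sample.int(n)
  decile <- integer(n)
  grand <- sum(as.double(pop65))
  if (grand == 0) {
    # Degenerate: no aged population to balance; spread units evenly.
    decile[ord] <- ((seq_len(n) - 1) %% 10) + 1
  } else {
    targets <- cumsum(spec$decile_shares) * grand
    cum <- 0
    d <- 1L
    for (i in ord) {
      decile[i] <- d
      cum <- cum + pop65[i]
      while (d < 10L && cum >= targets[d]) d <- d + 1L
    }
  }

  population_table(tibble::tibble(
    unit_id = sprintf("U%0*d", nchar(n) + 1, seq_len(n)),
    jurisdiction = jur,
    decile = decile,
    remoteness = unname(rem),
    pop_65plus = pop65
  ), jurisdictions = names(spec$jurisdiction_weights))
}

#' Write a synthetic itemised fee schedule exercising all nine categories
#'
#' Produces a delimited fee-item file suitable for [load_fee_schedule()]:
#' the published high-frequency diagnostic items verbatim (so fee-derivation
#' tests run against a file fixture), plus three synthetic items per
#' remaining category whose fees are jittered around that category's default
#' per-visit fee. Synthetic item numbers are drawn from the category's
#' schedule block; the file is deterministic given the seed.
#'
#' @param path output path; defaults to a tempfile.
#' @param seed integer seed for the fee jitter.
#' @return the path, invisibly.
#' @export
generate_fixture_fees <- function(path = tempfile(fileext = ".csv"),
                                  seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  defaults <- default_fee_schedule()
  blocks <- c(Preventive = 100, Periodontics = 200, OralSurgery = 300,
              Endodontics = 400, Restorative = 500, CrownBridge = 600,
              Prosthodontics = 700, General = 900)
  synth <- purrr::map(names(blocks), function(cat) {
    base <- defaults$fee_per_visit[defaults$category == cat]
    k <- 3
    tibble::tibble(
      item_number = sprintf("%03d", blocks[[cat]] + sample.int(80, k)),
      description = sprintf("synthetic %s service %d", tolower(cat), seq_len(k)),
      category = cat,
      mean_fee = round(base * runif(k, 0.7, 1.3), 2),
      frequency_weight = 1L
    )
  }) |> purrr::list_rbind()
  items <- fee_items(dplyr::bind_rows(published_diagnostic_items(), synth))
  readr::write_csv(tibble::as_tibble(items), path)
  invisible(path)
}
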