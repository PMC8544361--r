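# Small in-code fixtures shared across the suite.

# A minimal valid stratum table.
tiny_pop <- function(pops = c(100, 200, 300),
                     jurisdiction = rep("WA", length(pops)),
                     decile = rep_len(c(1L, 2L, 5L), length(pops)),
                     remoteness = rep("MajorCity", length(pops))) {
  population_table(tibble::tibble(
    unit_id = paste0("u", seq_along(pops)),
    jurisdiction = jurisdiction,
    decile = decile,
    remoteness = remoteness,
    pop_65plus = pops
  ))
}

# Write a population CSV and return its path.
write_pop_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# The printed worked-example decomposition: rounded WA visit total times the
# default per-visit means, to three decimals.
printed_wa_decomposition <- function() {
  c(Diagnostic = 593192.182, Restorative = 566670.922,
    Preventive = 303226.406, Prosthodontics = 227198.794,
    CrownBridge = 85752.074, Endodontics = 84868.032,
    OralSurgery = 80447.822, General = 25637.218, Periodontics = 14144.672)
}
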