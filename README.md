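# agecost

Projected utilisation and cost of dental services for Australians aged 65
and over.

Older Australians increasingly retain natural teeth into old age, which
raises demand for restorative and replacement dentistry; most of that care
is privately billed, and older people — especially in disadvantaged and
regional areas — face real cost barriers. Health planners who want to know
*what it would cost to cover the dental needs of the 65+ population, and
where that money is needed*, need a transparent demand-and-expenditure
model over census-level population strata. agecost is that model as a
tested, reusable R package, aimed at health-services researchers and
oral-health policy analysts.

## The model

For a population stratum *s* (a census-like unit or a jurisdiction) with
65+ count *Pₛ*:

```
Vₛ    = Pₛ · r            annual dental visits        (r = 2.58 visits/person/year)
Vₛₖ   = Vₛ · mₖ           visits by service area      (mₖ = mean services of area k per visit)
Cₛₖ   = Vₛₖ · fₖ · λ      expenditure in AUD          (fₖ = per-visit fee, λ = scenario multiplier)
```

with nine service areas (Diagnostic, Preventive, Periodontics, OralSurgery,
Endodontics, Restorative, CrownBridge, Prosthodontics, General;
orthodontics intentionally excluded — no utilisation data exist for this
cohort). Costs aggregate by jurisdiction, IRSD socioeconomic-disadvantage
decile (1 = most disadvantaged) and remoteness class. Category fees are
either derived from itemised schedule extracts
(`derive_category_fee()`; the diagnostic worked example gives
206.65 / 4 = 51.66 AUD), supplied, or back-calibrated from published
aggregate costs (`calibrate_implied_fee()`). λ = 0.79 prices services off
the government veterans'-affairs schedule instead of private fees.

A synthetic census generator (`generate_population()`) emulates SA1-like
units — 200–800 residents, ~15% aged 65+, deciles holding 10% of population
each — so the entire pipeline is testable without external data. See the
methods vignette (`vignettes/cost-model.Rmd`) for assumptions, the fee
denominator ambiguity, and limitations.

## Worked example

Project and price the dental care of Western Australia's 342,652 persons
aged 65+:

```r
library(agecost)

pop <- population_table(tibble::tibble(
  unit_id = "WA", jurisdiction = "WA", decile = 5,
  remoteness = "MajorCity", pop_65plus = 342652))
mix <- service_mix()                       # 2.58 visits/person/year + per-visit means
vt  <- split_by_service(project_visits(pop, mix), mix)
vt[, c("jurisdiction", "total_visits", "area", "visits")]
#>   jurisdiction total_visits area                visits
#> 1 WA              884042.16 Diagnostic     593192.289
#> 2 WA              884042.16 Restorative    566671.025
#> 3 WA              884042.16 Preventive     303226.461
#> 4 WA              884042.16 Prosthodontics 227198.835
#> ...
```

342,652 × 2.58 = 884,042.16 annual visits (displayed as 884,042), of which
e.g. 0.671 diagnostic services are delivered per visit. Pricing with the
bundled fee schedule and formatting in the published millions style:

```r
ct <- compute_costs(vt, default_fee_schedule())
format_report(ct, by = "jurisdiction")
#>   area           WA    Total
#> 1 Prosthodontics $246  $246
#> 2 Restorative    $122  $122
#> 3 CrownBridge    $105  $105
#> ...
#> 9 Periodontics   $3    $3

per_person_cost(ct, pop, by = "jurisdiction")
#>  jurisdiction      cost pop_65plus cost_per_person
#>            WA 591546528     342652        1726.377
```

Prosthodontics dominates at $246M/year for WA (227,199 prosthodontic visits
× 1083 AUD implied fee); periodontics is smallest at $3M. Covering the
modelled service demand of WA's older population would cost about 1,726 AUD
per person per year at private fees.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/agecost.R synth --n-units 1000 --seed 7 --out pop.csv
Rscript inst/cli/agecost.R run --population pop.csv --by jurisdiction,decile --out results/
Rscript inst/cli/agecost.R reproduce-published --out published_out/
```

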