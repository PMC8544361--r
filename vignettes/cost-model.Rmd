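---
title: "An explanatory cost model of dental service utilisation by older Australians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An explanatory cost model of dental service utilisation by older Australians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agecost)
```

## The model

agecost implements a deterministic, point-estimate demand-and-expenditure
model for the dental care of Australians aged 65 and over. For a population
stratum $s$ with 65+ count $P_s$, the model computes

$$V_s = P_s \cdot r, \qquad
  V_{s,k} = V_s \cdot m_k, \qquad
  C_{s,k} = V_{s,k} \cdot f_k \cdot \lambda,$$

where $r$ is the national annual visit rate (default 2.58
visits/person/year, the national telephone-survey rate for dentate older
adults), $m_k$ is the mean number of services of clinical area $k$ delivered
per visit (the *service mix*, from the 2003--04 wave of the national
dentists' practice-activity study), $f_k$ is the per-visit fee of area $k$
in AUD, and $\lambda$ is a flat scenario multiplier (1 by default; 0.79
prices the same services off the government veterans'-affairs schedule,
which sits about 21% below private survey means in aggregate).

Everything downstream is aggregation: expenditure by jurisdiction, IRSD
disadvantage decile (1 = most disadvantaged 10% of population) and
remoteness class, and average cost per 65+ person per group. The model is
linear in population, so stratum-level computation followed by aggregation
equals computation on aggregated populations; the package exploits this as a
standing cross-check.

Two modelling conventions deserve emphasis:

* **One national rate and mix.** The visit rate and service mix do not vary
  by decile or remoteness; geographic and socioeconomic variation in the
  outputs is driven entirely by where the 65+ population lives. The visit
  rate was measured on dentate respondents but is applied to the whole 65+
  population, reproducing the published model; a `dentate_fraction` multiplier
  (default 1) is exposed for sensitivity analyses.
* **Unrounded internals.** All intermediate quantities are carried at full
  floating precision. The published tables round to whole millions at
  display time, and their grand total (6385M AUD) differs from the sum of
  their own rounded cells (6383M) — so rounded-cell arithmetic cannot be the
  internal representation. Rounding happens only in `format_aud()` /
  `format_report()`: values ≥ 1M round to the nearest million ("$246"),
  positive values below 1M print one decimal of a million ("$0.4"), zero
  prints "$0".

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `mean_visits_per_person` | visits/person/year | 2.58 | annual demand per person |
| `per_visit_mean` (9 areas) | services/visit | 0.671 … 0.016 | decomposition into service areas |
| `dentate_fraction` | — | 1 | optional sensitivity scaling of the rate |
| `fee_per_visit` (9 areas) | AUD/visit | see below | pricing |
| scenario `multiplier` | — | 1 | flat cost scenario (0.79 = government schedule) |

The nine service areas follow the Australian Schedule of Dental Services:
Diagnostic, Preventive, Periodontics, OralSurgery, Endodontics, Restorative,
CrownBridge, Prosthodontics, General. Orthodontics is deliberately absent
from the default set because no utilisation data exist for the 65+ cohort.
The per-visit means are services per visit, not shares; the default set sums
to 2.241, a derived constant asserted in the test suite.

## Fee derivation and the denominator ambiguity

A category's fee is the average charged fee over its high-frequency schedule
items: with items $i$ carrying mean fee $F_i$ and billing frequency weight
$w_i$ per representative episode,

$$f = \frac{\sum_i F_i\, w_i}{D}.$$

The published diagnostic derivation divides the billed total 206.65 AUD by 4
— the number of *line entries* (three examinations plus one per-exposure
radiograph line counted once, despite its weight of 2). This is the
package's default, `denominator_rule = "per_line_entry"`, and yields
51.66 AUD.

The published jurisdiction cost table, however, implies an effective
diagnostic fee near 68.5 AUD — consistent with dividing by 3, i.e. counting
only distinct *primary* services and folding the per-exposure radiograph
adjunct into the examinations it accompanies. That reading is retained as
`denominator_rule = "per_distinct_item"` (206.65 / 3 = 68.88). Both rules
are first-class and selectable throughout (`load_fee_schedule()`,
`run_config()`); which one the published downstream table actually used is
not stated, so the package defaults to the rule its worked example prints
and documents the discrepancy rather than hiding it.

Non-diagnostic itemised fees are not open data. The bundled default
schedule therefore uses three provenance classes, recorded per category and
propagated into run manifests:

* `derived_from_items` — Diagnostic, from the published item extract;
* `supplied` — Prosthodontics (1083 AUD) and Periodontics (203 AUD), the
  two implied per-category-visit fees printed alongside it (note the published
  source labels 1083 "per older person", but numerically it is expenditure
  divided by category visits; the package reproduces the number and uses
  the accurate label);
* `calibrated` — the remaining six, back-derived at run time as NSW cost
  cell ÷ NSW category visits via `calibrate_implied_fee()`. Calibrated and
  supplied fees price the published cells back to their printed values;
  they are model-implied numbers, not survey-published fees.

Derived fees are stored to cent precision (matching how fee schedules are
printed); calibrated fees keep machine precision so that
fee → cost → calibrated fee is an exact identity.

## Reproducing the published jurisdiction results

`published_populations()` reconstructs the eight jurisdiction 65+ counts from
printed values only, with provenance flags: WA is printed directly
(342,652); Tas, ACT and NT are printed visit totals divided by 2.58 and
rounded so their projection rounds back to the printed totals; NSW, Vic,
Qld and SA are back-derived from their prosthodontics expenditure cells at
1083 AUD (their visit totals are printed to only two significant figures,
so the cost cells are the more precise source). `reproduce_published()` runs
the pipeline on these inputs.

Under the default denominator rule the national total comes to 6281M AUD;
under the alternative rule, 6390M — bracketing the published 6385M, which
cannot be reproduced exactly from printed inputs because decile-level
populations and the non-diagnostic survey fees are not open data.
The acceptance script reports both totals; no test asserts the published
figure.

## The synthetic census generator

`generate_population()` emulates the *structure* of the smallest census
geography the real analysis consumes, so the whole pipeline is testable
without any download:

* unit total populations uniform on [200, 800] (the SA1 design range);
* a per-unit 65+ fraction from a normal with mean 0.15 and sd 0.05 clamped
  to [0, 1] — published inputs carry no within-area age structure, so any bounded
  unimodal choice suffices; the mean matches the national 65+ share and the
  sd spreads units without creating implausible outliers. Boundary means
  (0 or 1) are treated as degenerate point distributions so that "no aged
  residents" specs generate exactly zero counts;
* jurisdiction labels drawn with probabilities proportional to the bundled
  jurisdiction 65+ counts; remoteness labels from a configurable
  per-jurisdiction probability vector (default 60/24/12/3/1% from major
  city to very remote);
* deciles assigned by greedy fill over a seed-reproducible shuffle of the
  units, so each decile holds its target share (10% by default) of the
  generated 65+ population to within one unit's population. Real IRSD
  deciles are constructed on *total* residents; the generator balances the
  65+ population because that is the population the table carries and the
  one the model consumes.

What passing tests on synthetic data do show: exact conservation under
aggregation, linearity, calibration identities, decile-share convergence,
and end-to-end determinism. What they cannot show: anything about real
spatial structure — there is no spatial autocorrelation, no realistic
settlement pattern, and no correlation between disadvantage, remoteness and
age structure, all of which exist in real census data and shape the real
decile/remoteness cost gradients.

## Numerical choices and degenerate inputs

* Counts are validated as non-negative integers and summed in double
  precision; label-group sums are exact, cost aggregation is exact up to
  floating associativity (tested at 1e-9 relative).
* Rounding: half-even (`round()`) at display time only.
* Zero-population groups in `per_person_cost()` are flagged `undefined`
  with `NA` cost per person — never reported as zero cost.
* Missing fees, unknown areas, invalid deciles and malformed files fail
  fast with row-indexed messages before any computation or output; the
  pipeline writes via temp-file-and-rename so a failing stage leaves no
  partial artifacts. Manifests contain no timestamp, so identical inputs
  produce byte-identical outputs.
* Problem sizes in the test suite: worked examples run on 1--8 strata;
  property checks use 100--2,000 synthetic units, with the structural
  acceptance checks at 10,000 units (a few seconds on one core).

## Limitations

Point estimates only — no uncertainty propagation, consistent with a
full-census model in which even small differences are taken as real. One
national visit rate and one national mean fee per category, with no
state-level fee variation.
No time trends, no insurance or subsidy modelling, and no subgroup models
for Aboriginal and Torres Strait Islander or institutionalised older
populations. The service mix dates from 2003--04 and the fee survey from
2017; both are configuration, not code, and can be replaced from files.
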