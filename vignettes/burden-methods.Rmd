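---
title: "Methods: costing farm injury deaths and compensation claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costing farm injury deaths and compensation claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmburden)
```

## The problem

Farm injury surveillance in Australia draws on two access-restricted
registries: coronial records of on-farm deaths (work- and non-work-related)
and the national workers' compensation claims data set. Published outputs
from these sources are cohort summaries — cross-tabulations of fatality
agents by work status, age-band cost summaries, claim counts by severity
and agency, annual weeks-lost and cost totals, serious-claim medians — all
subject to confidentiality masking and rounding. This package implements
the full analysis chain behind such outputs: a per-case human-capital
valuation of fatalities, claims aggregation, the disclosure-control
conventions, and a synthetic registry generator so that every stage can be
exercised and tested without restricted data.

## The human-capital fatality model

A death at age $a$ in calendar year $y$ is valued as the sum of five
components, each computed in year-of-death dollars and indexed to the base
year (2023) by the CPI ratio $\mathrm{CPI}_{2023}/\mathrm{CPI}_y$:

1. **Future earnings.** With remaining life expectancy $e(a)$ (sex-specific
   life table) and occupation-matched annual earnings $w$,
   $$\mathrm{PV} = \sum_{t=1}^{\lceil e(a)\rceil} w\,(1+g)^{t-1}\,
   \mathrm{FTE}(a+t)\,(1+r)^{-t},$$
   where $r$ is the discount rate and $g$ an optional real wage-growth
   rate (default 0). The horizon is the rounded-up expectancy; the
   fractional final year is ignored — the simplest defensible convention,
   and the one the straight-loop test oracle recomputes.
2. **Household production.** A fixed annual value accrues for the years
   $\max(a+1, 16)$ through a sex-specific end age (76 for men, 82 for
   women, inclusive), discounted identically. A single annual value is
   used across ages and sexes within the window; nothing in the source
   material supports finer variation.
3. **Friction cost.** 25% of one annual salary, charged once in the year
   of death, for employer disruption and replacement.
4. **Fixed direct costs.** Funeral, coronial services, WHS/police
   investigation and emergency response, as a configurable component map.
5. **Compensation payout.** Applied if and only if the death is
   work-related.

The retirement trajectory assumes work at 0.9 FTE through age 71,
declining to 0.5 FTE by 75 and 0 from 76. The decline is linearly
interpolated (0.8, 0.7, 0.6, 0.5 at ages 72–75); only the endpoints are
fixed by the stated assumptions, and the taper is a configurable map, so a
step function can be substituted. Below a labour-entry age (default 16) a
person earns 0 FTE, but a child's valuation still accrues earnings from
the entry age onward — which is why fatalities under 15 carry substantial
costs.

### Parameters, units and defaults

| parameter | default | unit | note |
|---|---|---|---|
| `discount_rate` | 0.03 | /yr | unstated in the source; 3% is standard in human-capital costing; 0 and 5% are natural sensitivity settings |
| `friction_fraction` | 0.25 | of salary | stated assumption |
| `fte_full`, taper | 0.9; 0.8–0.5 | FTE | stated endpoints; interpolated taper |
| `hp_annual_value` | 25,000 | AUD/yr | placeholder magnitude |
| `fixed_costs` | 71,000 total | AUD | placeholder magnitudes |
| `compensation_payout` | 580,000 | AUD | placeholder magnitude |
| `coverage_fraction` | 0.58 | — | share of farm workforce covered by workers' compensation |
| `under_coverage_factor` | 0.4 | — | multiplicative uplift convention |
| `base_year` | 2023 | — | all outputs in 2023 AUD |

The life table and CPI series the published analysis used are not
redistributable, so the packaged defaults are synthetic approximations: a
Gompertz mortality law calibrated to life expectancy at birth of 78.1
(male) and 83.0 (female) years, and an annual CPI series approximating the
Australian all-groups index (2011–12 = 100). Both are built in code,
satisfy the declared invariants (positive, monotone expectancy; positive
index covering 2013–2023) and should be replaced with official series for
substantive estimates. The same applies to the earnings schedule and the
monetary placeholders above: per-case totals from the defaults are of the
right order (a mid-career farmer values at roughly \$2–3M) but are not
calibrated to reproduce the published \$1.78B cohort total, which depended
on restricted case-level data and unpublished magnitudes.

**Coverage adjustment.** Two conventions are offered for scaling
claims-based annual costs for workforce under-coverage: multiplying by
1.4 (the default, matching the published arithmetic that takes ~\$190M/yr
to ~\$265M/yr) or dividing by the 0.58 coverage fraction (a larger uplift,
~\$328M/yr). The multiplicative convention is the default because it is
the one the published figures embody.

**Annualisation rounding.** The work-related cohort figure illustrates a
rounding ambiguity in narrative figures: \$1.24B over 11 years is
\$112.7M/yr, which rounds to 113 under the nearest-million convention used
everywhere else, while the narrative says "approximately \$112 million".
`annualise()` reports the computed 113; the discrepancy is inherent to the
source, not resolvable by convention.

## The synthetic registries

The generator's defaults are the published study conditions, not tuning
knobs. Fatalities: 748 cases over 2013–2023; work status in proportion
544 : 203 : 1 (work / non-work / unknown); agents drawn as consistent
(group, agent) pairs in proportion to the published per-agent totals; ages
in proportion to the published band counts, uniform over integer ages
within a band (the open 65+ band truncated at 95); sex conditional on work
status (94% male among work-related; 75% among non-work, a documented
default where the source is silent). Claims: ~5,046/yr in the first
period and ~4,921/yr in the second; severity mix per period (54.0% and
58.5% serious); agency shares per period from the published totals.

Weeks lost follow a two-component mixture: minor claims uniform on
$[0, 5/7)$ weeks (under five working days), serious claims lognormal with
per-year medians set to the published values (pooling to ≈6.3 weeks) and
`sdlog` 1.58, chosen once so that the implied annual total of ~63,000
weeks matches the published aggregate — claim durations are heavily
right-skewed, and the published mean/median ratio (~3.5) fixes the spread.
Serious-claim costs follow `base × weeks^elasticity × lognormal noise`
with elasticity 1, `base` solved per year from the published median cost
and median weeks, and noise `sdlog` 0.94 so the aggregate lands near
\$190M/yr. Minor claims draw their own lognormal cost (median \$2,500):
making minor costs proportional to their tiny weeks-lost would give them
~1% of total cost, whereas the published split is ~95/5 — minor claims
carry medical and administrative costs even with little time off.

Category axes without published cell values (nature, mechanism, bodily
location) use defaults consistent with the published narrative shares
(top three natures ≈75% of claims, top three mechanisms ≈75%, upper limbs
≈38% and the top four body locations >90%); these are soft calibration
targets only and are not asserted in tests.

**What the generator does not emulate:** dependence between axes beyond
the sex-by-work-status conditioning (in the real cohort, age and work
status are associated — nearly half the work-related deaths were 60+ —
and agents differ by work status); year-on-year trends within periods;
claim-level correlation between category and cost. Passing tests
therefore demonstrate that the pipeline recovers configured marginal
structure and aggregate calibration, not that it would reproduce joint
structure in real registries.

## Disclosure control

Counts of 1–4 are suppressed (`np`); zeros are printed, so the threshold
concerns only 1–4. Totals are always computed from true values and
published, so suppression must be complemented: in any row or column where
exactly one cell is masked, that cell is recoverable by subtraction, so
the smallest remaining positive visible cell is masked (`+`), ties broken
by first category order, repeating over rows and columns to a fixpoint.
The trigger applies to *any* lone masked cell, not only `np`: a
complementary `+` left alone in its other line would be forced by that
line's total and the suppressed value would unravel by subtraction — the
brute-force audit in the test suite confirms this is not hypothetical.
Rounding (counts and annual means to 5, monetary summaries to 5,000,
narrative grand totals to 5,000,000; ties away from zero) is applied only
at render, never to stored values, which is why rendered subtotals can
disagree with sums of rendered components by one multiple — exactly as in
the published tables.

Known limitations, accepted deliberately: a line whose only nonzero entry
is the suppressed cell is disclosed by its own printed total, and no
in-table masking can protect it; a line holding exactly two suppressed
cells whose true values sum to 2 or 8 is pinned by its residual under full
attacker knowledge (each `np` is 1–4). Resolving these requires
restructuring tables or optimisation-based secondary suppression
(minimum-information-loss cell selection), which is out of scope; the
fixpoint heuristic is the declared convention. The safety tests audit
masked tables by exhaustively enumerating integer completions consistent
with visible cells and totals, under attacker knowledge that `np` ∈ 1–4
and `+` is 0 or ≥ 5, and assert that no suppressed cell is uniquely
determined on tables without the degenerate patterns above.

## Tabulation conventions

Annual means are computed from unrounded totals and rounded once at
render. Percentages are integer, half-up; percentage columns sum to
100 ± 1. Pooled serious-claim medians are medians of the pooled
claim-level values (midpoint convention for even counts), not means of
yearly medians. The single unknown-work-status fatality is carried in
grand totals but excluded from work/non-work shares (544 of 748 known
cases → 73%). Claims outside all defined periods are excluded with a
logged count.

## Problem sizes and numerics

The test suite exercises: oracle equivalence of the costing engine against
an independent straight-loop recomputation on 200 random cases at 1e-9
relative tolerance; monotonicity of the earnings PV over ages 16–95;
exact closed-form agreement at zero discount with flat FTE; marginal
recovery at n = 20,000 with an L∞ bound of 0.015 (≈4 binomial standard
errors at that n); disclosure safety by brute-force enumeration on tables
up to 4×4 with cells up to 30; and the desk-scale arithmetic connecting
all published figures, exactly. The demo pipeline runs the full study
scale (748 fatalities, ~45,000 claims) in seconds and is byte-reproducible
for a fixed seed and configuration.
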