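---
title: "Methods: activity-based costing of a multisectoral nutrition programme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-based costing of a multisectoral nutrition programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricost)
```

## The costing problem

`nutricost` implements the full cost analysis of a multisectoral
agriculture–nutrition programme delivered through a women's microcredit
platform in rural Bangladesh (the TRAIN programme, October 2016 – January
2020). The programme had an additive randomised design: arm 2 added
nutrition behaviour-change counselling to the credit platform, arm 3 added
agricultural extension, and arm 4 added gender sensitisation, with 1,260
study households per arm. Costing follows the activity-based-costing
ingredients (ABC-I) approach used by standardised multisectoral-nutrition
costing frameworks: every expenditure line item and every unpaid resource
(frontline-worker overtime, beneficiary participation time) is valued,
coded to a standard activity × input × stage classification, and aggregated
into a cost cube whose margins, unit costs, and sensitivity analysis are
the outputs.

Two cost natures are distinguished throughout. *Financial* costs are the
implementer's actual expenditures. *Economic* costs add the opportunity
cost of resources nobody paid for: unpaid worker time beyond the contracted
36-hour week, workers' out-of-pocket (OOP) spending net of stipends, and
beneficiaries' participation time valued at local agricultural wages.

## Pipeline

A run (`run_costing()`) proceeds in five steps.

1. **Coding** (`assign_codes()`). Each ledger entry is mapped to exactly one
   of 15 activities and one of 2 stages. Explicit hints pass through;
   cadre-tagged salary entries are deferred to time-share allocation;
   remaining entries resolve through an editable rule table
   (input-code lookups, then keyword rules). Anything unresolved is rejected
   with its entry id — never silently defaulted.
2. **Valuation** (`to_usd_2019()`, `capital_charge()`). Amounts convert at
   84.77 BDT/USD and are deflated to 2019 price levels by an annual index
   (identity by default, since no specific index is mandated; the series is
   configuration). Durable goods over the \$100 threshold lasting more than
   a year are annuitized at a 3% discount rate over a 10-year standard life
   — the annuity factor $(1-(1+r)^{-n})/r$ — and charged for the 40-month
   window; cheaper durables are expensed, signalled by a classed condition
   so callers cannot annuitize them by accident. Financial valuation keeps
   taxes; economic valuation excludes taxes on durables but keeps VAT
   embedded in small supplies.
3. **Allocation** (`allocate_personnel()`, `allocate_shared()`).
   Cadre salary pools split by surveyed time shares — e.g. nutrition
   frontline workers (PKs) at 80% home counselling / 10% training / 5%
   planning / 5% coordination, district managers at 30% FTE on supervision.
   Shared costs split proportionally with a largest-remainder cent
   correction so partitions always conserve money.
4. **Arm and typology attribution**. Every cell receives component-scope
   weights (nutrition / agriculture / gender) and is spread over the arms
   eligible for that component ({2,3,4}, {3,4}, {4} respectively),
   proportional to households. Independently, each activity maps to
   value-chain typology weights (supply / demand / enabling environment).
5. **Aggregation** (`build_cube()`, `unit_cost()`, `arm_unit_costs()`,
   `cost_profile()`). The cube's margins give the summary table; unit costs
   divide the total by four beneficiary denominators (households, index
   female + spouse, index adults + children, all members), annualized over
   40/12 years.

Uncertainty propagates through `run_psa()` and `tornado()`: the seven
survey parameters are modelled as gamma distributions (hours and costs are
nonnegative) parameterised by method of moments, shape $=(\mu/\sigma)^2$,
scale $=\sigma^2/\mu$; 5,000 seeded Monte Carlo draws push through the
deterministic cost model, and a one-at-a-time tornado at the 10th/90th
distribution percentiles (the common spreadsheet-PSA convention,
overridable) ranks parameters by the swing they induce in total incremental
cost.

## Key parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| Exchange rate | 84.77 | BDT/USD | study conversion rate |
| Discount rate | 0.03 | /year | reference-case convention |
| Useful life | 10 | years | standard capital horizon |
| Capital threshold | 100 | USD | expense/annuitize boundary |
| Window | 40 | months | Oct 2016 – Jan 2020, pre-COVID |
| Start-up window | months 0–5 | — | 6-month launch period |
| Hours per workday | 8 | h | converts daily wages to hourly |
| Contracted week | 36 | h | salaried PK hours; prices overtime |
| OOP periods | 0–16, 17–32, 33–39 | months | stipend regimes (none/200/500 BDT) |
| PSA draws | 5,000 | — | simulation count per scenario |

A month index maps to calendar years as month 0 = October 2016, so the
40-month window spans 2016–2020. OOP survey rows are treated as already net
of travel stipends; no further stipend subtraction occurs. Travel hours are
valued at the same hourly rate as overtime work hours (the alternative —
a discounted travel rate — is a configuration away, but no basis for a
different rate was available). The hourly rate itself is derived from the
monthly salary over contracted hours, `salary / (36 × 52/12)`, because
unpaid time is valued but no explicit rate is mandated anywhere.

## What the synthetic generator emulates

`generate_inputs()` produces a complete, internally consistent study:

- **Ledger** (`generate_ledger()`): line items whose coded, valued
  financial aggregates reproduce the reference budget margins
  (`reference_margins()`) to within one cent. Construction places the PK
  and DM salary pools first (the PK pool is implied by the time-valuation
  rate at expected survey hours and the contracted week), pins the small
  agriculture inputs to their natural activities — including a
  sub-threshold durable (the \$5.81 equipment item) exercising the capital
  rule, and taxed supplies exercising the tax rule — and fills the
  remaining activity × input cells with an independence table of the
  reduced margins, split into lognormally jittered line items rescaled to
  conserve each cell exactly. Start-up portions of the one-time activities
  (full installation and materials development, \$20,000 of planning, a
  solved training remainder) are dated in months 0–5.
- **Surveys** (`generate_worker_survey()`, `generate_beneficiary_timeuse()`):
  gamma draws per worker-month and household-month at the published
  moments; women's participation is roughly double men's, and spouse
  records exist only for the index-pair surplus over households.
- **Calibration**: three constants are solved at generation time and
  recorded in the run configuration — the hourly time-valuation rate
  (economic personnel target / realized survey hours), an OOP scale, and a
  beneficiary wage scale (the synthetic 300/250 BDT daily wages are
  declared placeholders, so the scale absorbs the gap to the economic
  beneficiary-personnel target). Economic costs are spread over activities
  by configurable shares defaulting to the normalized reference economic
  column.

The generator defines study conditions, not dials: its defaults *are* the
reference budget, roster, and moments, and tests assert reproduction under
those conditions.

What passing tests therefore show: the pipeline arithmetic (coding,
valuation, conservation, unit costs, PSA) is correct and reproduces the
reference analysis when fed data with its statistical structure. What they
do not show: robustness to the messiness of real institutional ledgers —
inconsistent descriptions, miscoded currencies, missing months — beyond
the validation rules, nor the realism of any specific line item
(descriptions and dates are cosmetic; only coded aggregates are
contractual).

## Design choices where the design was open

- **Arm allocation.** No explicit rule for dividing pooled costs across
  arms accompanies the published arm-level costs. The package's rule —
  component eligibility, proportional to households — reproduces the
  additive design's strictly increasing arm costs. The generator solves the
  shared-activity component-scope weights linearly from the arm-level
  annual household cost series (36.62 / 65.18 / 87.50 USD), so the default
  pipeline reproduces that series by construction rather than as an
  independent prediction.
- **Beneficiary arm attribution.** Participation moments are pooled across
  arms, so beneficiary opportunity costs follow the same component-scope
  arm rule as every other cell; a participation-count attribution (also
  available via `value_beneficiary_time()`) would flatten the arm gradient
  the additive design implies.
- **Economic activity shares.** Allocating worker economic costs by the PK
  salary time shares is infeasible against the reference economic activity
  column (it would overfill planning), so economic costs allocate by
  configurable shares defaulting to that column, normalized.
- **Nutrition/gender sub-split** of the combined home-visit activity:
  0.8/0.2 configuration default.
- **Typology weights** for shared activities default to
  {supply 0.21, demand 0.345, enabling 0.445}, chosen once so the default
  cube's typology profile lands near the reported ~23/47/30 split; this is
  a declared configuration, not an estimate, and no test asserts it
  exactly.
- **Start-up composition** by activity is a configuration (no published
  breakdown): full installation and materials development, a planning
  slice, and a training remainder solved from the stage margin.
- **Annualization divisor** is 40/12 years, not 3.5: the published annual
  unit costs are consistent only with 40/12.
- **PSA limits** are defined as the 2.5th/97.5th percentiles of the
  simulated outcomes. The published simulation table's base cases are not
  internally consistent with the published budget totals (they appear to
  exclude an unidentified component), so the package reproduces the PSA's
  *structure* and is deliberately not calibrated to those numbers.

## Numerical conventions and degenerate inputs

Money partitions use largest-remainder cent rounding at the reporting
surface (ties resolved toward the final key) and full-precision proportions
inside the pipeline, so cube margins conserve to well under a cent across
hundreds of cells. Percentages print with half-up rounding (`round_half_up()`),
matching conventional costing reports. Zero salary pools, zero-hour
profiles and empty ledgers all produce zero-cost results rather than
errors (an empty ledger warns); negative amounts, out-of-window months,
invalid codes and over-amount taxes are rejected with the offending entries
named. Infeasible generator margins are rejected with the inconsistent
dimension named. All randomness flows from explicit integer seeds;
generators and the PSA are bitwise reproducible given (config, seed).

Two small print-level discrepancies in the reference tables are handled
explicitly: the three margin panels disagree with their printed totals by
one cent (all conservation checks carry a ±\$0.01 tolerance), and the
pooled counts for two roster denominators exceed their per-arm sums by one
person (the package computes pooled totals as arm sums; unit costs round to
the same printed values either way).

## Worked example

```{r example, eval = FALSE}
inputs <- generate_inputs(synth_config(seed = 1))
result <- run_costing(inputs)
result
#> Programme costing result (2019 USD)
#>   Financial cost:      598,578.90
#>   Economic cost:       196,461.44
#>   Total:               795,040.34
#>   Annual cost per household: 63.10 (window 40.0 months)

model <- build_cost_model(result$totals[["financial"]], inputs$costing,
                          inputs$roster)
tornado(model)$parameter[1:3]
#> "beneficiary_hours_women" "beneficiary_hours_men" "pk_travel_hours"
```

Beneficiary participation time (women, then men) dominates the uncertainty
in total incremental cost, followed by worker travel time; the OOP
parameters matter least. The default problem sizes — a ~120-entry ledger,
3,200 worker-months, ~280,000 household-month records, 5,000 simulations —
run the full pipeline and PSA in a few seconds.

## Known limitations

- No cost-effectiveness: impact estimates are out of scope, so no
  cost-per-outcome ratios are computed.
- No double-entry accounting, accrual handling, or NLP auto-coding beyond
  keyword rules.
- PSA parameters are drawn independently; no correlation structure or
  variance-based (Sobol) indices.
- Single-currency ledgers (BDT/USD) and a single annual deflator; no
  purchasing-power-parity conversion.
- Arm-level costs inherit the declared allocation rule; they are
  reproductions under that rule, not independent validations of it.
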