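---
title: "Estimating indirect costs from planned-funding ledgers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating indirect costs from planned-funding ledgers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

PEPFAR publishes, through its annual Country Operational Plans (COPs), how
much planned funding each implementing partner receives from each US funding
agency, by country, year and programmatic budget code — but it does not
disaggregate direct from indirect costs. Indirect costs (facilities,
administration, depreciation) are recovered through Negotiated Indirect Cost
Rate Agreements (NICRAs) that are private for almost every international
organization (IO). US universities are the exception: they publish their
NICRA rates, including the "Other Sponsored Activities" (OSA) class that
covers service-delivery programs, with separate on-campus and off-campus
rates.

`copcost` estimates the plausible range of indirect costs embedded in such a
ledger for international organizations and universities by a process of
elimination. For each *cost cell* — one partner $i$, one funding agency $j$,
one fiscal year $t$ — the accounting chain is

$$
\begin{aligned}
\mathrm{Total}_{ijt} &= \mathrm{Sub}_{ijt} + \mathrm{Ret}_{ijt} \\
\mathrm{Ret}_{ijt} &= \mathrm{EC}_{ijt} + \mathrm{NEC}_{ijt} \\
\mathrm{NEC}_{ijt} &= \mathrm{MTDC}_{ijt} + \mathrm{Ind}_{ijt} \\
\mathrm{Ind}_{ijt} &= r_{ijt}\,\mathrm{MTDC}_{ijt}
\end{aligned}
$$

where Sub is money passed to sub-awardees, EC the costs excluded from the
Modified Total Direct Cost (MTDC) base (capital works, purchased vehicles,
laboratory equipment, ARV procurement), NEC the "non-excludable costs", and
$r$ an indirect cost rate. Because NEC combines the rate base and the
indirect costs charged on it, a known or assumed rate inverts it:

$$
\mathrm{Ind}_{ijt} = \frac{\mathrm{NEC}_{ijt}}{1 + r_{ijt}}\, r_{ijt}.
$$

## Pipeline stages and the choices behind them

### Classification and NA allocation

Every partner is classified IO / UNIVERSITY / LOCAL / USG from a supplied
classification table; unknown partners and the sentinel `"NA"` (funding not
yet awarded when a plan was published) become class NA. NA funding is then
redistributed proportionally to the classified funding of its stratum.

The allocation stratum was a genuinely open design choice: the source data
characterize NA amounts by country, year and budget code, so the package
allocates within `(country, year, budget_code)` first, escalating to
`(country, year)` and then `(year)` when a stratum has no classified funding,
and finally reporting anything unallocatable rather than forcing it.
Stratum-level allocation also means the allocated money inherits the
stratum's agency mix, which downstream retention rates require; universities
participate in the allocation alongside IOs, local and USG partners in
proportion to their in-stratum funding. USG and local partners are then
dropped: USG management costs are out of scope, and local organizations
rarely hold NICRAs.

### Retention

Sub-award amounts beyond the first \$25,000 each are outside the MTDC base.
Sub-award detail exists only for some years and some partners, so retention
is estimated: for every (partner, agency) pair that disclosed sub-awards
inside the observation window, $R = 1 - \mathrm{Sub}/\mathrm{Total}$ over the
window. Because sub-awards to *other* IOs or universities carry their own
indirect rates, the model treats the internationally sub-awarded share $p$
(measured per agency in the first observed year, with sub-partners at or
below a \$100,000 within-agency threshold, and unclassifiable sub-partners,
counted as local) as retained for rate purposes:

$$ \text{applied rate} = R + (1 - R)\,p. $$

Partners without disclosed sub-awards receive their agency's applied
average — the *funding-weighted* mean of observed partner retention over the
window, adjusted by the agency's $p$ — and agencies with no observed partners
receive the global funding-weighted average. Weighting by funding (rather
than a simple mean) was chosen because the fallback explicitly stands in for
a pool of funding, not a pool of partners; both provenance and rates are
recorded per cell (`PARTNER_OBSERVED` > `AGENCY_AVERAGE` > `GLOBAL_AVERAGE`).
The $p$ adjustment is applied at the agency level even for partners with
observed $R$, because per-partner sub-awardee composition is too sparse to
estimate. Deliberately, no credit is given back for the first \$25,000 of
each sub-award (sub-award detail is not uniformly available), which makes the
sub-award exclusion conservative.

### Exclusions and back-fill

Within each cell: capital = the construction/renovation cross-cutting
categories; vehicles = the purchased-vehicles category; laboratory equipment
= 40% of the laboratory-infrastructure budget code (HLAB); ARV procurement =
100% of the ARV budget code (HTXD). Rental costs are not excluded anywhere —
no data exist for them. All four are policy parameters
(`exclusion_policy()`).

Cross-cutting data exist only in part of the study window (capital from the
fourth year, vehicles from the seventh, in the emulated data). Years without
source data receive a back-filled proportional estimate: category spending
over funding pooled across the observed window, applied to the unobserved
years' cell totals. The pooling level is configurable; the default is
partner-level (falling back to agency, then global) because the exclusions
are applied to partner-subscripted funding and partner-level pooling
preserves partner heterogeneity. Cells whose exclusions would exceed
retained funding are clamped (components scaled proportionally so
EC = Ret, NEC = 0) and flagged as a data-quality signal rather than erroring.

### Rate scenarios

Six scenarios bound the unknown rates, from least to most conservative:

| id | universities | IOs |
|----|--------------|-----|
| A | on-campus OSA | average of university on-campus rates |
| B | off-campus OSA | average of university on-campus rates |
| C | off-campus OSA | average of university off-campus rates |
| ASSUMED_20/15/10 | off-campus OSA | fixed 20% / 15% / 10% |

The 10% scenario models every IO using the *de minimis* rate available
without a NICRA. The university average applied to IOs is an **unweighted**
mean over distinct universities, per year (membership of the rate table can
change across years as agreement periods begin and end); an unweighted mean
was chosen because the scenario describes a typical negotiated rate, not a
funding-weighted cost. A university's own rate comes from the agreement
period covering the year (inclusive bounds); when no period covers it, the
nearest period's rate is applied retrospectively or prospectively, most
recent period winning ties. Universities with no rate entry at all
(typically non-US universities, whose agreements are not public) are routed
through the IO rule by default (`missing_university = "io"`).

## Numerical conventions

* **Integer cents.** All money is carried as integer cents in doubles (exact
  below $2^{53}$). The additive identities — Total = Sub + Ret,
  Ret = EC + NEC, NEC = MTDC + Ind, and classification conservation back to
  the raw ledger — are asserted *exactly*, not to floating tolerance.
* **Largest-remainder apportionment.** Every proportional split (NA
  allocation, exclusion clamping, the generator's budget-code splits) uses
  Hamilton apportionment with ties broken by position, so each split sums to
  its total to the cent and is deterministic.
* **Rounding.** Multiplicative steps (`ret = round(rate * total)`,
  `ind = round(nec * r / (1 + r))`) round half-even to the cent. As a
  consequence `ind = r * mtdc` cannot also be exact; analytically
  $|{\mathrm{Ind} - r\,\mathrm{MTDC}}| \le (1+r)/2$ cents, and the test suite
  asserts it to one cent.
* **Presentation.** Reports are rendered in thousands of USD (half-even) and
  shares in percent to two decimals, only at presentation; all internal
  aggregation stays in cents.
* **Degenerate inputs.** Empty ledgers produce all-zero reports; zero-funding
  windows produce zero back-fill fractions with warnings; sub-awards
  exceeding funding clamp retention to zero with a flag; a model with no
  observed retention anywhere is a hard error.

## The synthetic generator

`generate_cop_ledger()` emulates the accounting structure of the real
ledgers, not their epidemiology. The default configuration mirrors the shape
of the real data: ten fiscal years (2007–2016), five agencies, 20 IOs, 8
universities, 22 local and 4 USG partners sized so that roughly 60% of
funding is in scope, a 14.2% NA share, sub-awards observed only in the first
three years with about 40% of pairs disclosing them, capital cross-cutting
data from 2010 and vehicles from 2013, a 4.3% HLAB and 14.3% HTXD budget
share, and capital/vehicle fractions of 0.85% and 0.53%. University
on-campus OSA rates are drawn around 36% with off-campus at 72% of
on-campus, matching the magnitudes published for such rates. These values
are the generator's definition of the study conditions and are set once in
`synthetic_config()`, not tuned per test.

Two design points make ground truth exact rather than approximate:

* NA funding is *carved out* of every row at a uniform rate, so the
  estimator's proportional stratum allocation inverts the carve (up to cent
  apportionment).
* Ground truth is defined as the accounting identity chain evaluated on the
  full-information (pre-mask) ledger. Sub-award fractions are constant per
  (partner, agency), so under `fully_observed = TRUE` (masks off, full
  disclosure, no NA share) the estimator reproduces every cell of ground
  truth to the cent, for all six scenarios — the round-trip test.

What passing these tests does **not** show about real data: real NA amounts
are not a uniform carve; real retention drifts across years; real partner
names need reconciliation beyond the deterministic normalization rules
shipped here; and the generator draws no country-level epidemiological
structure at all. Recovery error under the default (masked) configuration is
dominated by undisclosed sub-awards — the test suite checks that it is
bounded, collapses when disclosure is complete, and grows with partner
retention heterogeneity — but its magnitude on real data depends on how
heterogeneous real partners are.

Test and acceptance runs use the default generator sizes (about 80 prime
partners, 370 in-scope cells, ~8,000 ledger rows), which the package treats
as its reference desk-scale problem.

## Worked example

```{r, eval = FALSE}
library(copcost)

sim <- generate_cop_ledger(synthetic_config(seed = 5))
est <- estimate_indirect_costs(sim$funding, sim$subawards,
                               sim$crosscutting, sim$classes, sim$rates)
est                                  # annual report, shares, range
recovery_report(est, sim$ground_truth)

# the international-sub-awardee adjustment on published agency inputs
applied_retention(0.8633, 0.2675)    # 0.8998673 -> 89.99%
```

## Known limitations

* Negotiated cost bases narrower than MTDC (e.g. salary-only bases) are
  treated as rate-equivalent; fringe-benefit rates and the Overhead vs G&A
  split are out of scope.
* Indirect costs on the first \$25,000 of each sub-award are not credited,
  and local primes' sub-awards to IOs are not modelled.
* Cost-sharing offsets are not modelled (no data).
* The published headline totals for the real 2007–2016 ledgers are not
  reproducible without the external dataset; the package's checks rest on
  worked examples computable from published tables plus the synthetic
  round-trip.
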