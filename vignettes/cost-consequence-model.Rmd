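---
title: "An EDSS-based Markov cohort model for treatment sequencing in relapsing MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An EDSS-based Markov cohort model for treatment sequencing in relapsing MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscca)
```

## The model

`mscca` implements a deterministic, discrete-time Markov cohort model for
cost-consequence analysis (CCA) of disease-modifying therapy (DMT)
sequencing in relapsing multiple sclerosis. A CCA lists costs and
consequences side by side and deliberately computes no cost-per-outcome
ratio; the point of the model is to show, for a given treatment sequence,
what happens clinically and what it costs society.

The health states are the integer values 0--9 of the Expanded Disability
Status Scale (EDSS; half-point scores are rounded down), plus one absorbing
dead state. The cohort is additionally stratified by treatment status
(on/off DMT) and sex. One cycle is one year -- this is fixed, not
configurable, because every rate input (annualised relapse rates, annual
costs, annual discounting, annual life-table probabilities) is annual and a
configurable cycle length would make their semantics ambiguous.

Each cycle composes, in this order:

1. **Active-treatment lookup** from the scenario's segment list
   (switches happen exactly at cycle boundaries).
2. **Death**, state-independent: the age- and sex-specific background
   probability times one MS mortality hazard ratio (base case 1.7, applied
   uniformly to every living EDSS state, capped at 1). Because mortality
   does not depend on EDSS or treatment, the death trajectory -- and hence
   years of life lost -- is identical across scenarios; this is a
   structural property, not a numerical accident, and it is what the
   acceptance script verifies.
3. **EDSS transition conditional on survival.** Worsening probabilities
   (all moves to a higher EDSS) are adjusted on the complementary-log
   scale, $p' = 1 - (1-p)^{\mathrm{HR}}$, with the treatment's hazard
   ratio on 6-month confirmed disability progression (6-CDP); this is
   equivalent to scaling the underlying constant hazard and is the
   standard health-economics mapping. Improvement and stay probabilities
   are left at their natural-history values, with the probability mass
   freed by reduced worsening added to "stay". Whether improvement should
   also be treatment-adjusted is genuinely open; we adjust worsening only,
   because the treatment evidence is a progression endpoint, and the
   choice is isolated in `build_cycle_matrix()` should a user want to
   change it.
4. **DMT discontinuation** above EDSS 6 (states 7--9), irreversibly: mass
   that later improves below the threshold stays off treatment. The
   source analyses are silent on reversibility; irreversibility is the
   conservative and simpler reading. Off-treatment mass evolves under the
   reserved `"none"` effect (HR = RR = 1, zero drug cost).
5. **Relapse accrual** on the resulting state: occupancy times the
   state-specific annualised relapse rate, with the treatment's relapse
   rate ratio applied to on-treatment mass. Relapses are a counting
   process only; they do not feed back into EDSS transitions.
6. **Ageing** by one year. The cohort ages deterministically from its mean
   start age; ages are floored for life-table lookups. Individual age
   heterogeneity is not propagated through mortality (the age sensitivity
   factor covers this instead).

No half-cycle correction is applied: state membership is valued at the
start of each cycle for costs and years lived with disability, and
per-cycle event quantities (deaths, relapses) in the cycle ending at year
$t$ are discounted to year $t-1$. Natural-unit outcomes (years spent per
EDSS band, informal-care days, relapse counts) are reported undiscounted
over cycles 1 to the horizon, so a cohort that stays put for the whole run
scores exactly the horizon length.

## Scenarios

`builtin_scenarios()` returns the four-way comparison grid of the analysis
over a 10-year horizon: immediate high-efficacy treatment with ofatumumab
(OMB) throughout ("10/0"), a switch from the comparator (dimethyl
fumarate, DMF, or glatiramer acetate, GA) to OMB after 1 year ("1/9") or
after 5 years ("5/5"), and the comparator throughout ("0/10"). Arbitrary
user sequences are accepted through `scenario_spec()`. Switch times are
exact cycle boundaries rather than the distributed switch times observed
in registry data; the deterministic model has no notion of individual
switching variability.

## Outcomes and costs

`outcome_report()` produces the clinical/productivity block: end-of-horizon
EDSS band shares (mild 0--3, walking aid 4--6, wheelchair 7, bedridden
8--9, and the derived immobile band 7--9), computed among survivors -- the
published tables sum to 100% across bands, which implies survivor
normalisation; mean EDSS per year; undiscounted years per band; expected
relapses; disability-adjusted life years split into years lived with
disability (YLD: state-years weighted by per-EDSS disability weights) and
years of life lost (YLL: deaths weighted by remaining age/sex-specific
life expectancy at death), both discounted at the effects rate, with
DALY = YLD + YLL by construction; informal-care days; and
employment/full-time/invalidity shares among survivors below the
retirement age (67), reported as zero with a flag once the cohort passes
it.

`cost_report()` produces the societal cost block, discounted at the cost
rate (base case 3%/year, same as effects): DMT acquisition costs with a
two-tier price schedule -- the "year 1" tier is keyed to the first year of
each contiguous run of a drug *within the scenario*, not to calendar time,
so a mid-horizon switch to OMB is priced at its loading-year tier once;
eight non-DMT direct categories (inpatient care, day-care admissions,
consultations, tests & investigations, non-DMT medications, community &
social services, investments/equipment & aids, informal care); two
indirect productivity-loss categories (short-term absence; long-term
absence, invalidity & early retirement), accrued only below retirement
age. Indirect costs are modelled as per-EDSS annual productivity-loss
costs rather than a wage-times-employment microdata model: the source
gives no wage model, and per-state inputs keep the accounting transparent
while the employment shares are reported separately. Relapse costs
(expected relapses times a unit cost, base case 2662 EUR) are reported
separately *and* added into the total; since the per-state cost inputs
already contain an unknown share of relapse-related spending, the total is
an acknowledged overestimate, and the report says so.

All currency is a single abstract unit, documented as EUR; there is no
currency conversion or inflation machinery.

## Sensitivity analysis

`univariate_sensitivity()` is a one-way tornado: each factor is set to 90%
and 110% of its base value, everything else held at base, and both
scenarios of a comparison are rerun; results are ordered by range. The
nine default factors follow the published list: OMB price in year 1, in
year 2, and from year 2 onwards (the price schedule has two tiers, so the
latter two both act on the subsequent-year price), the 6-CDP hazard ratio
(the intervention's, matching the OMB-centric factor list), cohort size (a
documented no-op on per-patient metrics), start age, male fraction
(clamped to [0, 1] with a recorded warning), both discount rates jointly,
and the relapse unit cost. The default metric is the incremental
discounted total cost between the two scenarios; any
`function(params, reference, comparator)` can be substituted.

## Synthetic inputs: what they emulate and what they do not

The actual input tables of the published analysis (baseline EDSS
histogram, the British Columbia natural-history transition matrix, network
meta-analysis effect sizes, German life tables, per-EDSS cost and
productivity inputs) live in a supplement that is not machine-readable
here. `generate_parameter_set()` therefore produces seeded inputs with the
*described structure*:

* baseline: a truncated normal EDSS kernel on [0, 7), floored to integers
  (consistent with "intermediates rounded down") and renormalised over
  0--6, with its continuous location solved by root-finding so the
  discretised mean hits the target (2.3, SD kernel 1.2); age 36.3, 33%
  male;
* natural history: a band-dominant matrix (stay mass largest, most
  movement to the adjacent states, small two-step tails, per-seed jitter)
  with worsening strictly exceeding improvement in every row that can
  worsen; EDSS 9 is held at the living state because no worse living
  state exists;
* untreated ARR 0.7 for EDSS 0--4 and 0.5 for EDSS 5--9;
* 6-CDP hazard ratios ordered OMB (0.45) < DMF (0.71) < GA (0.83) and
  relapse rate ratios 0.35/0.55/0.65 -- plausible magnitudes for a
  high-efficacy antibody versus platform therapies, chosen once as
  realistic, not fitted to reproduce published results;
* annual drug costs OMB 19,000 EUR in year 1 and 17,000 EUR thereafter
  (a loading-dose premium), DMF 10,500 EUR, GA 12,500 EUR;
* per-EDSS disability weights, care costs, informal-care days and
  invalidity rising with EDSS; employment, full-time work and short-term
  absenteeism (which requires an employed patient) falling; one
  multiplicative jitter factor per cost category per seed, so
  monotonicity is preserved by construction;
* a Gompertz-style life table (mortality rising with age, higher for
  males) with remaining life expectancy computed from the same schedule,
  and the uniform MS mortality hazard ratio 1.7.

What passing tests on these inputs show is that the *machinery* is right:
conservation, stochastic dominance of a lower progression hazard,
identical YLL across scenarios, the published sign structure (later
switching worsens every clinical and productivity outcome, lowers DMT
costs and raises every care/productivity cost), and the published tornado
pattern. They do not show that the package reproduces the published point
estimates -- those depend on the unpublished supplement values, and the
published headline numbers are used only as arithmetic-consistency inputs
(do the printed components sum to the printed totals and shares?), never
as calibration targets.

`generate_worked_fixture()` is different: a deliberately unrealistic
round-number parameter set whose transition support is confined to EDSS
0--2, so every pipeline stage can be checked against independent
hand-unrolled 4-state arithmetic to 1e-10 in the test suite.

## Numerical choices

* Transition rows must sum to 1 within 1e-9 on load; rows measurably off 1
  (beyond 1e-12) but within tolerance are renormalised once, rows further
  off are rejected with the offending row named. All schema and invariant
  violations are collected and reported together.
* `apply_hazard_ratio()` returns `p` exactly when HR = 1, avoiding a
  floating-point round trip on the identity path.
* A hazard ratio large enough to overdraw a row's probability mass (the
  freed "stay" mass going negative) is an error, not a silent clamp.
* Parameter files are written with 17 significant digits so a load ->
  write -> load round trip is bit-exact.
* Percentage shares are held at full precision in reports; rounding to one
  decimal happens only in `print()` methods.
* Problem sizes: the test suite runs the full model (10 annual cycles,
  40 strata) across one hundred generator seeds for the invariant suite;
  the whole suite completes in well under a minute.

## Known limitations

Constant per-cycle transition probabilities and treatment effects (no
waning, no adverse-event states, no imputed discontinuation beyond the
EDSS rule); integer EDSS only; relapses do not drive transitions; cohort
mean age rather than an age distribution; sex strata differ only in
mortality; no probabilistic sensitivity analysis (the source performed
none); no payer-perspective split of direct costs.
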