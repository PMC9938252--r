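---
title: "Modelling germline BRCA testing policies in HER2-negative breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling germline BRCA testing policies in HER2-negative breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcacea)
```

## The decision problem

About one in ten patients with triple-negative breast cancer (TNBC), and
slightly fewer among all HER2-negative breast cancer patients, carry a
germline pathogenic variant (PV) in *BRCA1* or *BRCA2*. Knowing carrier
status at diagnosis changes management: carriers are candidates for
risk-reducing operations (RRO), high-risk carriers for a year of adjuvant
olaparib, and carriers who recur for olaparib at recurrence. The policy
question is who should be tested: nobody, only patients with a family
history (after genetic counselling), or everybody.

`brcacea` evaluates the three policies with a decision tree feeding a
three-state Markov cohort model, from a healthcare-sector perspective, and
compares them with incremental cost-effectiveness ratios (ICERs), net
monetary benefit (NMB) and a cost-effectiveness frontier, separately for
four populations: TNBC and all-HER2-negative cohorts in China and the USA.

## Model structure

**Decision tree.** The cohort is split by family history (FH), carrier
status, and — among carriers — a high-risk stratum. The testing strategy
determines who is tested: nobody (`NO_TEST`), FH-positive patients
(`SELECTED_TEST`), or everyone (`UNIVERSAL_TEST`). The test is modelled as
perfect (sensitivity = specificity = 1), reflecting the near-perfect
predictive values reported for germline panel testing; test accuracy is
therefore not a model parameter. Each leaf (a `Pathway`) carries a weight,
an upfront cost (test + counselling + RRO + adjuvant olaparib where
applicable) and a transition profile:

* detected carriers receive RRO (a lasting relative effect on the
  recurrence hazard); detected high-risk carriers additionally receive one
  year of adjuvant olaparib (a strong relative effect in the treatment
  year, a weaker durable effect afterwards);
* undetected carriers carry an elevated recurrence hazard (contralateral
  breast and other BRCA-associated second cancers are not modelled as
  separate states; the excess is a single relative-effect multiplier);
* any carrier who did not receive adjuvant olaparib receives one year of
  olaparib on entering recurrence — undetected carriers are assumed to be
  tested at that point, so that pathway also absorbs a test cost at
  recurrence entry. Patients already exposed to adjuvant olaparib are not
  re-treated.

**Markov model.** Three states — disease-free (DF), recurrence, death —
with annual cycles over a 20-year horizon from age 40. Recurrence merges
locoregional recurrence, second primary malignancy and distant metastasis
as independent competing events, `1 - (1-p1)(1-p2)(1-p3)`. Death is
absorbing, DF patients can die directly (trial-derived all-cause annual
probability; no life-table age indexing is layered on top), and recovery
from recurrence is impossible. Relative effects are applied on the rate
scale (`p -> 1 - (1-p)^RR`), so multipliers compose like hazard ratios and
probabilities stay in `[0, 1]`.

**Rewards.** Utilities are 0.85 (disease-free) and 0.51 (recurrence), with
a persistent +0.075 on the recurrence state for pathways receiving olaparib
at recurrence. Costs comprise annual state costs, upfront pathway costs,
and recurrence-entry costs charged to the new entrants of each cycle
(first-passage decomposition: entrants at cycle *t* are
`DF occupancy(t-1) x p(DF->REC)`), which honours "one year of olaparib at
recurrence" without tunnel states. A trapezoidal half-cycle correction
averages successive occupancies; it is exact for linearly varying
occupancy and a no-op on constant traces. Costs and QALYs are discounted
at 3% per year with cycle 0 undiscounted (`1/(1+r)^t`, *t* = completed
years) — stated explicitly because the discount-timing convention changes
second-decimal results.

## Parameters

Inputs arrive as a CSV with one row per parameter
(`name, category, population, base, low, high, distribution, source_note`,
optional `bound_type`), validated against invariants (bounds ordered,
probabilities and utilities in `[0, 1]`, costs non-negative, distribution
family matching category: beta for probabilities/utilities, gamma for
costs, log-normal for relative effects). Population-specific rows override
`ALL` rows, and a completeness check lists any missing required name.
Rates and multi-year risks are converted only through
`rate_to_probability()`, `probability_to_rate()` and
`multiyear_to_annual_probability()`; nothing guesses a row's scale.

The shipped table (`generate_parameter_table()`) pins the main-text
constants exactly — utilities 0.85/0.51/+0.075, carrier prevalence 0.10
(TNBC) and 0.097 (HER2-negative), 3% discounting, 20 one-year cycles,
age 40, willingness-to-pay 31,500 (China) and 100,000 (USA) USD/QALY — and
anchors the family-history branch so that selected testing detects 4.30%
of the TNBC cohort (p(FH) = 0.2, p(carrier|FH) = 0.215,
p(carrier|no FH) = 0.07125, which keeps marginal prevalence at 0.10) and
3.36% of the HER2-negative cohort. All remaining inputs — costs,
recurrence components, mortality, relative effects, the high-risk
fraction — are **synthetic placeholders**: field-plausible magnitudes
(olaparib list prices by country, metastatic-disease management costs,
adjuvant-trial-like hazard ratios), each flagged
`"placeholder - supplement value unknown"` in its `source_note` and kept
in a single constants file so real supplement values can be dropped in as
a file edit. Results computed from the shipped table are therefore
structurally faithful but not numerically comparable to any published
base case.

## Synthetic scenarios and what tests can show

`synthetic_scenario()` supports three realism levels. `paper_anchored` is
the shipped table. `random_plausible` perturbs every non-pinned value
uniformly within its documented range (bounds rescaled proportionally)
under a seed; it is used for fuzz and oracle testing. `degenerate` builds
corner cases (`no_benefit` makes testing free and treatment ineffective, so
all three strategies must coincide; `all_fixed` turns every distribution
into a point mass, collapsing the PSA). The generator emulates the schema
and statistical structure of a real parameter table, not real-world
correlations: parameters are independent, costs are time-constant, and
background mortality is age-flat. Green tests therefore demonstrate engine
correctness and internal consistency, not real-world predictive validity.

An independent individual-level microsimulation
(`generate_microsim_fixture()`, `microsim_strategy()`) walks 10^5 patients
through the same annual matrices and accumulates rewards per individual.
It shares the transition matrices (those are the object under test's
input) but none of the cohort accumulation code, so agreement of
occupancies and mean discounted cost/QALYs is a genuine cross-check of the
cohort algebra. Because ~1,260 occupancy cells are compared, the per-cell
3-standard-error band is judged as a family (familywise 1% calibration,
with the empirical 3-SE exceedance rate capped at the null-compatible 1%);
a per-cell 3-SE cutoff would be exceeded somewhere by a perfect engine
with probability ≈ 0.93.

## Sensitivity analysis

**One-way DSA.** Each parameter in turn is set to its low and high bound
and the incremental NMB of universal vs selected testing at the population
WTP is recomputed (`one_way_dsa()`); entries are sorted by range and bounds
that break model validity are flagged rather than dropped.

**PSA.** `run_psa()` draws every non-fixed parameter independently from a
method-of-moments fit (`fit_distribution()`): beta for probabilities and
utilities, gamma for costs, log-normal for relative effects. The SD comes
from the 95% CI (`(high-low)/3.92`) when one is reported; for ±10%
fallback ranges the utility overrides apply (SD = 10% of base for the
disease-free utility, 5% for recurrence-state utilities) and all other
CI-less parameters use 10% of base. A beta fit whose variance is
infeasible near 0/1 falls back to a point mass with a warning rather than
silently truncating. Infeasible joint draws (e.g. a sampled transition row
exceeding one) are redrawn with a counted, warned-about redraw rate.
`ceac()` scores each strategy by the fraction of draws in which it attains
the maximum NMB (ties split evenly) over a 0–150,000 USD/QALY grid in
1,500-USD steps; `ce_plane()` exports the incremental point cloud.

## Numerical and design choices

* **Recurrence merging** uses the independent-complement product; it
  degenerates correctly at zero and is bounded by `[max, sum]` of the
  components.
* **ICER ties**: effect differences below 1e-9 QALYs are flagged
  `equal`/`dominant`/`dominated` instead of forming astronomically
  unstable ratios.
* **WTP verdicts** are quadrant-aware so that the verdict is exactly the
  incremental-NMB sign test: a comparator that is cheaper and less
  effective is acceptable when its ICER is *above* the threshold.
* **Life-day conversions** use 365.25 days/year (recorded in output
  metadata; 365 vs 365.25 moves the third digit).
* **Frontier construction** sorts by cost, removes strict dominance, then
  prunes extended dominance until sequential ICERs are non-decreasing.
* **Degenerate inputs** fail loudly: transition rows that leave `[0, 1]`
  name the pathway and cycle; utilities stacking outside `[0, 1]` raise an
  error rather than clamping.
* **Problem sizes** used by the shipped tests: 10^5 microsimulated
  individuals on 20 fuzzed tables, 1,000-draw PSA, 100-seed end-to-end
  fuzz — sizes at which binomial noise is well below the effects being
  checked while a full run stays in the minutes range on one CPU.

## Known limitations

Test accuracy, cascade testing of relatives, population screening of
unaffected women, age-dependent background mortality, within-recurrence
cost/utility splits (locoregional vs distant) and parameter correlations in
the PSA are out of scope. The shipped cost and hazard placeholders make
absolute outputs illustrative; conclusions about the real policy question
require a real parameter table, which the loader accepts unchanged.

## A worked run

```{r run, eval = FALSE}
ps <- generate_parameter_table(synthetic_scenario("TNBC_CN"))
cmp <- compare_strategies(ps)
cmp$results
cmp$comparisons

tor <- one_way_dsa(ps)            # tornado, universal vs selected
samples <- run_psa(ps, n_draws = 1000, seed = 1)
curve <- ceac(samples)
```

The same stages are scriptable through `cmd_run()`, `cmd_synth()`,
`cmd_dsa()`, `cmd_psa()` and `cmd_ceac()` or the shell wrapper in
`inst/cli/brcacea.R`.
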