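---
title: "Methods: disproportionality screening, priority scoring and onset profiling for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening, priority scoring and onset profiling for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

# The problem and the data model

Spontaneous-report systems such as FAERS collect unsolicited suspicion
reports, not a cohort: there is no person-time denominator, reporting is
selective, and one clinical case can appear as several report *versions*.
All inference in this package is therefore *disproportionality* analysis:
for a target drug and an adverse-event term, the deduplicated reports are
cross-classified into the 2×2 table

|            | event | no event |
|------------|-------|----------|
| drug       | a     | b        |
| no drug    | c     | d        |

and every statistic asks whether `a` is large relative to what the margins
predict. The counting unit is the unique (report, PT) pair: a report
listing k distinct preferred terms contributes to k event tables but is
counted once per table.

The ingest layer makes the unit of analysis explicit:

* **Deduplication.** FAERS re-submits cases under the same `caseid` with a
  new `primaryid` per version. Since dropping duplicate `primaryid`s alone
  cannot remove cross-version duplicates, the default strategy keeps, per
  `caseid`, the version with the latest FDA receipt date (ties broken by
  the larger `primaryid`) — standard practice for FAERS analyses. A
  `primaryid-distinct` strategy is available for comparison. The operation
  is idempotent, which the tests assert.
* **Exposure.** A report is exposed when any drug entry matches a target
  name (case-insensitive substring after trimming) with role code in the
  configured set, default `PS` (primary suspect) only. No ingredient
  dictionary is bundled; synonym handling is the caller's responsibility.
* **Units.** Ages are converted to years (decades ×10, months ÷12, weeks
  ÷52.1775, days ÷365.25), weights to kg (pounds ×0.45359237). Any
  unparseable value degrades to missing with a warning counter; the
  normalizer never fails on malformed text (fuzz-tested).
* **Dates.** `YYYYMMDD` with partial forms `YYYYMM`/`YYYY` resolved to the
  first day/month and flagged; flagged dates are excluded from
  time-to-onset analysis by default because day arithmetic on them is
  fictitious.
* **Seriousness.** A report is serious exactly when it carries at least
  one of the outcome codes DE, LT, HO, DS, CA, RI, OT (CA/RI/OT are pooled
  as "other serious").

# The four algorithms

For a table with all cells positive:

* **ROR** `= ad/bc`, CI `exp(ln ROR ± 1.96 √(1/a+1/b+1/c+1/d))`. Zero
  cells are refused by default; an optional Haldane–Anscombe +0.5
  continuity correction is off by default because it changes small-count
  estimates materially and the screening floor (`a ≥ 3`) makes it rarely
  needed.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Pearson χ² without continuity
  correction. The same χ² implementation backs the serious-vs-non-serious
  comparison (single source of truth), where it reproduces the published
  canakinumab statistics to ±0.01 — the package's strongest evidence that
  this is the variant the field computes.
* **BCPNN.** The information component `IC = log2 p11/(p1. p.1)` under the
  conjugate Beta model with uniform margin priors (α₁ = β₁ = 1, α = β = 2)
  and joint pseudo-count γ₁₁ = 1, with the joint prior total tied to the
  data so the prior IC expectation is zero. The closed-form `E(IC)` equals,
  exactly, log2 of the ratio of posterior means; the tests verify this
  against a 10⁶-draw Monte-Carlo estimate, and verify that `ic` and
  `ic025 = E(IC) − 1.96 √V(IC)` fall inside the exact posterior's central
  99% band. A caveat worth knowing: the posterior *mean of IC itself* sits
  below the closed form by roughly `1/(2a ln 2)` (log of a right-skewed
  quantity), i.e. up to ~0.1 bits when `a` is in the single digits with
  large margins. This small-count bias is a property of the canonical
  closed form, not of this implementation; at screening-relevant counts it
  is negligible. The credibility multiplier 1.96 is configurable (a 2.0
  variant exists in the literature).
* **MGPS.** Observed count `a` is Poisson with mean λE, `E = (a+b)(a+c)/N`,
  and λ carries the two-component gamma prior (defaults a₁ = 0.2, b₁ = 0.1,
  a₂ = 2, b₂ = 4, w = 1/3). The posterior is again a two-component gamma
  mixture; `EBGM = exp(E[ln λ])` uses the digamma closed form per component
  and `EBGM05` solves the mixture CDF at 0.05 by bisection to 10⁻⁶. Both
  are validated against trapezoid quadrature of the posterior density on a
  log grid to 10⁻³. `fit_mgps_prior()` maximizes the negative-binomial
  mixture marginal likelihood by `L-BFGS-B` on log/logit-transformed
  parameters; parameter recovery (the mixture weight to ±0.1 from 5,000
  simulated pairs) is tested, and a boundary weight is flagged rather than
  hidden. Whether a published analysis used fitted or fixed
  hyperparameters is usually unstated, so both modes are first-class.

**Signal policies.** PT-level screening flags a term only when *all four*
criteria hold (ROR: a ≥ 3 and lower CI > 1; PRR: a ≥ 3, PRR ≥ 2, χ² ≥ 4;
IC025 > 0; EBGM05 > 2); SOC-level screening uses *any one*. Both policies
and every threshold are configuration, not code. No multiplicity
correction is applied — deliberate fidelity to standard pharmacovigilance
practice, and a documented limitation: at FAERS scale thousands of PTs are
screened and the all-four conjunction is the only false-positive control.

# Clinical-priority rubric

Each signal PT is scored 0–2 on five items and banded weak (0–4),
moderate (5–7) or strong (8–10):

| item | 0 | 1 | 2 |
|------|---|---|---|
| case count | <10 | 10–50 | >50 |
| ROR | <2 | 2–<5 | ≥5 |
| death proportion | <25% | 25–50% | >50% |
| event-list status | none | IME | DME |
| evidence grade | − | + | ++ |

These cut points were reconstructed so that the published 71-PT
canakinumab screen rescoring reproduces every printed per-PT score and the
44/27/0 band totals — shipped as a full-table regression test. Boundary
placements inside unobserved ranges (a death proportion of exactly 25% or
50%, ROR exactly 5) are conventions: no published PT sits on them, so the
data cannot pin them down. They are configurable via `priority_rubric()`.
When a PT is on both EMA lists, DME takes precedence (the deafness row
requires it). Monotonicity — improving any single attribute never lowers
the total — is property-tested.

# Serious vs non-serious comparison

The test for each PT's 2×2 (serious/non-serious × with/without PT) is
chosen from the observed with-PT cells: any 0 → Fisher's exact test; any
in 1–4 → Yates-corrected χ² (`max(|ad−bc|−N/2, 0)` clamped at zero); else
Pearson χ². This selection rule is reconstructed from the published
per-row test assignments, which it reproduces for all 37 rows; published
methods text stated only "Pearson or Fisher". Fisher's two-sided p sums
hypergeometric probabilities no larger than the observed table's, verified
against full enumeration for every table with N ≤ 30. Age and weight use
the Mann–Whitney U with midranks and the tie-corrected normal Z without
continuity correction; under a null with no serious/non-serious difference
the resulting p-values are uniform (KS-checked over 500 replicate
cohorts).

# Time to onset

`TTO = event date − therapy start`, per report, among exposed reports
(optionally restricted to a PT set). Exclusions are counted, never
silent: missing or partial dates; non-positive differences (input errors);
days beyond the observation window (default one year, configurable,
`Inf` to disable). The Weibull shape β solves the profile equation
`Σtᵢ^β ln tᵢ / Σtᵢ^β − 1/β − mean(ln tᵢ) = 0` by Newton iteration with a
bisection safeguard inside [0.01, 50] to 10⁻⁸ (the left side is strictly
increasing in β, so the bracket is reliable); then
`α = (Σtᵢ^β/n)^{1/β}`. The 95% CIs come from the observed information on
`(ln α, ln β)` (normal approximation; symmetric on the log scale, hence
positive bounds). A likelihood-ratio profile CI was considered and not
implemented: at the sample sizes where failure classification is
meaningful (hundreds of onsets) the two are practically identical, and
the classification rule only needs the CI position relative to 1. The
failure profile is early (β and CI < 1), wear-out (β and CI > 1), or
random. Quantiles are type-7 (linear interpolation) — IQR values depend
on this convention, so it is fixed and documented.

One behavior the synthetic workflow makes visible: a one-year window
right-truncates the onset distribution and biases the naive Weibull shape
upward, toward "random failure". The analysis scripts fit both windowed
and unwindowed samples; the unwindowed fit recovers the generating shape.
No censoring model is attempted — spontaneous reports carry event dates
only, so there is nothing to censor on.

# The synthetic cohort generator

`synth_config()` defines the study conditions; its defaults emulate a
canakinumab-like cohort and are not tuned per test:

* 10% of reports exposed (PS role, generic or trade spelling);
* an 18-PT catalog with background reporting probabilities 0.003–0.08,
  per-event serious probabilities and death probabilities shaped like an
  infection-heavy biologic profile;
* planted relative risks 2.25–3 on infection terms, with the
  serious-infection risk multiplied in males, subjects ≥ 60 years and
  those > 100 kg — the stratum-modifier mechanism used by the
  stratification tests;
* a bimodal age mixture (paediatric autoinflammatory plus adult
  indications: lognormal medians 11 and 48 years, weights 0.55/0.45),
  weight generated given age;
* Weibull onset times (scale 100 days, shape 0.9 — early failure);
* 5% duplicate case versions with later receipt dates; FAERS-like
  missingness (about a third of event and therapy dates absent);
* events assigned independently per PT given exposure.

The generator returns analytic expected cells (`synth_expected_tables()`),
integrating the clipped `background × RR × modifier` over the demographic
strata by quadrature, so convergence tests compare empirical counts to
closed-form expectations rather than to another simulation.

What the generator does *not* emulate — and therefore what passing tests
do not show about real FAERS data: event correlation within a report
(real reports carry syndromic clusters), drug co-prescription structure,
reporting waves and stimulated-reporting artifacts, term-preference
drift across MedDRA versions, and non-random missingness. Tests against
the generator validate the *machinery* (counting, estimation, coverage,
recovery); the published-table reproductions validate the arithmetic
against real-data outputs.

# Numerical choices and problem sizes

Degenerate inputs fail loudly and early: zero-cell tables are refused by
the estimators (screening converts those failures to `NA` statistics with
false flags rather than aborting a whole screen); empty samples,
all-identical TTO samples and zero-case PTs are errors; unknown pipeline
configuration keys abort before any computation.

The test suite's simulation sizes were chosen so the whole suite runs in
about two minutes while keeping every stochastic check comfortably
powered: 10⁶-draw Monte-Carlo posteriors for the BCPNN oracle, a 49-point
(a, E) grid for the MGPS quadrature oracle, 500 tables for ROR coverage,
300 replicates for Weibull CI coverage, 200 replicate null screens for the
false-positive rate, a 10⁶-report fixed-seed draw for generator
convergence, and full enumeration (46,376 tables) for the Fisher oracle.
All seeds are fixed in the tests; the analysis scripts use one 50,000-case
cohort.

# Known limitations

* Disproportionality is not risk: no denominators, no causality, and the
  package deliberately offers no propensity or regression adjustment.
* No multiplicity control, mirroring field practice (see above).
* The BCPNN closed form carries the documented small-count bias relative
  to the exact posterior mean of IC.
* The priority rubric's unobserved boundary placements are conventions.
* The Weibull fit ignores the truncation its own window introduces; the
  workflow surfaces the effect instead of correcting it, matching how the
  statistic is used in the literature it reproduces.
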