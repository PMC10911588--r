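---
title: "Methods: a partitioned survival model for first-line therapy in unresectable HCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned survival model for first-line therapy in unresectable HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

`psmcea` implements a cost-utility comparison of first-line Tislelizumab
(200 mg IV every 3 weeks) against Sorafenib (400 mg orally twice daily) in
unresectable hepatocellular carcinoma, from the Chinese health-system
perspective, built around the RATIONALE-301 trial population (338 vs 324
patients, median overall survival 15.9 vs 14.1 months). The package covers
the full analytic chain: reconstruction of pseudo individual patient data
(IPD) from digitized Kaplan-Meier figures, parametric survival fitting and
selection, a three-state partitioned survival model (PSM), an economics
ledger, deterministic and probabilistic sensitivity analysis, and a
synthetic-trial generator that makes the whole chain testable without any
proprietary data.

## The partitioned survival model

Three states are modelled: progression-free (PFS), progressed disease (PD)
and death. A PSM does not use transition probabilities; occupancy is read
directly off the two endpoint curves at each cycle time $t_k$:

$$p_{\mathrm{PFS}}(t_k) = \min\{S_{\mathrm{PFS}}(t_k),\, S_{\mathrm{OS}}(t_k)\},
\qquad p_{\mathrm{death}}(t_k) = 1 - S_{\mathrm{OS}}(t_k),$$

with PD as the remainder. The $\min$ repairs the occasional crossing of
independently extrapolated curves (the standard PSM convention; curves are
never re-fitted to avoid crossing). Everyone enters in PFS.

The cycle is 21 days, matching the dosing interval of both first-line
regimens. Each cycle $k \ge 1$ accrues utility
$(p_{\mathrm{PFS}} u_{\mathrm{PFS}} + p_{\mathrm{PD}} u_{\mathrm{PD}})
\cdot 21/365.25$ years and the state-specific costs, discounted by
$(1+r)^{-21k/365.25}$ with $r = 0.05$ per the Chinese pharmacoeconomic
guidelines (0-8% is the guideline range, explored in scenarios).
Occupancy is evaluated at the cycle **end** by default, the common
spreadsheet-PSM convention; this under-counts each cycle by at most one
cycle's worth of hazard (a first-order error of roughly 0.5-1% here). A
`half_cycle` flag switches accrual to cycle midpoints, which is
second-order accurate; the tests verify that halving the cycle length
moves cycle-end totals by ~0.5% and midpoint totals by an order of
magnitude less. Death carries no cost or utility, and no terminal-care
cost is applied (none is in the ledger).

## Survival inputs

Six parametric families are supported: exponential, Weibull, log-normal,
log-logistic, Gompertz and the generalized gamma in the Prentice
$(\mu, \sigma, Q)$ parameterization, which nests the Weibull ($Q = 1$) and
log-normal ($Q = 0$). For $Q \ne 0$, with $w = (\ln t - \mu)/\sigma$ and
$a = Q^{-2}$,

$$S(t) = \begin{cases} 1 - P(a,\, a e^{Qw}) & Q > 0 \\ P(a,\, a e^{Qw}) & Q < 0, \end{cases}$$

where $P$ is the regularized lower incomplete gamma function; $|Q| <
10^{-8}$ falls through to the log-normal limit. Survival quantiles are
closed-form for every family (through the gamma quantile function for the
generalized gamma), so median survival and inverse-CDF simulation need no
root finding; a plateauing negative-shape Gompertz returns `Inf` below its
plateau.

The base case uses the published fitted parameters as authoritative
inputs (generalized gamma for three of the four curves, log-normal for the
comparator's OS), with **time in months**: the comparator OS log-normal
median $\exp(2.783) \approx 16.2$ months sits next to the trial's 14.1
months, while days or cycles would be off by an order of magnitude.

For refitting reconstructed data the package carries its own maximum
likelihood machinery: the right-censored log-likelihood
$\sum_{\text{events}} \ln f(t_i) + \sum_{\text{censored}} \ln S(t_i)$ is
maximized by BFGS on transformed parameters (log scale for positive ones)
from a method-of-moments start plus two deterministically perturbed
restarts — reproducible without touching the RNG. Fits are cross-checked
in the test suite against `flexsurv::flexsurvreg`, agreeing in
log-likelihood to $10^{-6}$. Model selection is by AIC or BIC with exact
ties broken by the fixed family order, so selection is deterministic.

## Pseudo-IPD reconstruction

Digitized KM coordinates plus a numbers-at-risk table are inverted into
per-patient `(time, event)` records with the standard published-curve
reconstruction algorithm (Guyot et al., 2012, re-implemented): within each
risk-table interval censoring is assumed uniform, the censoring count is
solved iteratively so the implied risk set matches the published count at
the next boundary, and event counts at each digitized drop track the
product-limit ratios. Two conventions worth noting:

* a drop digitized exactly at a risk-table boundary belongs to the
  *earlier* interval — the printed number at risk is the post-drop count;
* placement is fully deterministic (events at drop times, censorings on a
  uniform grid), so reconstruction is exactly reproducible.

Raw digitizer output is cleaned before use: survival clamped to $[0,1]$,
forced monotone by a running minimum, and anchored at $(0,1)$. Without a
risk table a fallback assumes no censoring before the last follow-up and
warns loudly. Round-trip fidelity (re-estimated KM vs digitized input) is
below 0.005 absolute survival probability at trial scale in the tests,
against a 0.02 requirement.

## The economics ledger

All monetary inputs live in one parameter table
(`default_parameter_table()`), one row per price, adverse-event cost,
incidence, or utility, with the published base/low/high values and
distribution families. Costs are in USD as printed in the source ledger;
a currency tag guards against comparing arms costed in different
currencies. Assembly of an arm's per-cycle economics is pure arithmetic
over this table:

* **First line (PFS state).** Tislelizumab 200 mg per cycle at \$192.85
  per 100 mg vial → \$385.70/cycle; Sorafenib 800 mg/day at \$3.19 per
  200 mg tablet → \$267.96/cycle. Unit pack sizes are *not* printed in the
  source ledger; these are the package's calibration assumptions, exposed
  in the table's `unit_size` column.
* **Second line (PD state), both arms.** Camrelizumab 200 mg once per
  21-day cycle (its every-3-weeks schedule when combined with
  chemotherapy) plus FOLFOX4 on its own 14-day rhythm, costed as 1.5
  schedules per cycle: oxaliplatin 85 mg/m² day 1, calcium folinate
  200 mg/m² days 1-2, 5-FU 1000 mg/m²/day days 1-2, on a 1.72 m² body
  surface, with vials rounded up per administration → \$822.72/cycle for
  all PD occupancy, uncapped in duration (the source states no cap). An
  alternative costing that puts camrelizumab on the 14-day schedule
  raises the PD cycle to \$1,003 and overshoots the published cost totals
  by ~15-20%, which is why the every-cycle schedule is the default.
* **Follow-up** \$84.77 per cycle for all alive states.
* **Adverse events** (grade ≥ 3, incidence ≥ 10% in at least one arm; both
  arms keep the same 12 rows for symmetry) are costed once at entry as
  $\sum \text{incidence} \times \text{management cost}$ — \$79.63 and
  \$313.70 per patient. One-off application is adequate because the
  tornado shows AEs are negligible drivers.
* **Utilities** 0.76 (PFS) and 0.68 (PD) per year, death 0.

## Horizon: why "lifetime" is 17 years here

The fitted intervention-arm OS (generalized gamma with $\sigma = 1.40$,
$Q = -0.65$) has an extremely heavy extrapolation tail: 4.9% of the cohort
is still alive at 30 years, and the tail never covers 99.9% of the OS mass
at any practical horizon. "Lifetime" must therefore be an explicit choice.
The package sets it to **17 years (295 cycles)**, which is both the
residual life expectancy of the trial cohort (median age ~61 against a
Chinese life expectancy of ~78) and the horizon at which the model
reproduces the published discounted totals of both arms within a few
percent; at 30 years the intervention arm gains a further ~0.19 discounted
QALYs of tail and the incremental QALYs inflate by ~30%. The structural
scenario driver (`analysis/05_scenarios.R`) tabulates 10/17/20/30-year
horizons so the sensitivity of every headline number to this choice is
visible rather than buried.

```{r base-case}
bc <- base_case()
bc$summary[, c("qaly_intervention", "qaly_comparator",
               "delta_cost", "delta_qaly", "icer")]
```

## Sensitivity analysis

**One-way (tornado).** Each ledger parameter is set to its published low
and high (costs ±20%, adverse-event incidences ±10% relative, utilities
their printed 95% CI, including the one-sided 0.60-0.68 PD-utility
interval used as printed) with everything else at base; entries are ranked
by ICER swing. A parameter evaluation that breaks validity is recorded as
failed, never dropped silently.

**Probabilistic.** Ranges are treated as 95% intervals, $SE = (\text{high}
- \text{low})/3.92$, and moment-matched: gamma for costs
($k = b^2/SE^2$, $\theta = SE^2/b$), beta for probabilities and utilities
($\alpha = b(b(1-b)/SE^2 - 1)$) — every distribution's mean equals its
base value. Each of the 1000 draws samples all parameters independently in
fixed alphabetical key order from one seeded stream, so results are
bit-reproducible and adding a parameter perturbs downstream draws
predictably. Invalid draws (e.g. $u_{\mathrm{PD}} > u_{\mathrm{PFS}}$) are
resampled, up to 100 attempts, and counted — resampling rather than
truncation keeps the means unbiased. Survival parameters are **not**
varied (no ranges or covariance are published for them); this is the
analysis's main acknowledged limitation, shared with the source study.
Because the survival curves are fixed, state trajectories are computed
once and each draw only re-prices them, which keeps 1000 draws in seconds.

**Internal consistency of the acceptability curve.** A mean-matched PSA
centres the incremental cost and QALY distribution on the base case, so
the CEAC necessarily crosses 50% near the base-case ICER (~\$23,400 here)
and the probability of cost-effectiveness at any threshold below that
ICER is small (0.7% at \$19,000; essentially 100% at the \$37,653
three-times-GDP bound, where every sampled point falls below the
threshold line). An acceptability curve that crosses 50% at ~\$12,000 or
reaches certainty at \$19,000 cannot arise from this base case under
mean-preserving parameter uncertainty — any such published landmark is
arithmetically inconsistent with its own base-case ICER, and the package
reports what its model actually implies.

## The synthetic-trial generator

`simulate_trial()` emulates the structure the analysis assumes: two arms
of 338/324 patients, event times drawn by inverse CDF from the true
models, administrative censoring at a 33-month cutoff plus a small
exponential dropout (0.002/month by default — trial follow-up was nearly
complete), and per-patient coupling of the endpoints by redrawing PFS
until it does not exceed OS. The coupling keeps simulated KM curves
non-crossing, as in real trials, at a known price: it tilts the PFS
*marginal* toward earlier times, so full-loop parameter recovery is
asserted against the OS endpoint (whose marginal is exact) while the
reconstruction layer itself is validated by comparing fits on
reconstructed vs raw simulated records (ΔQALY agreement ~5%,
requirement 10%). `digitize()` emulates the manual digitization step:
step-function coordinates on a grid with optional ±0.005 uniform jitter,
plus numbers-at-risk counts.

What passing these tests does **not** show about real data: the generator
has no treatment switching, no cure fraction, no per-patient cost
heterogeneity, and its censoring is non-informative by construction; the
fidelity statements are about the algorithmic chain, not about the
clinical generalizability of the source trial.

## Numerical choices and problem sizes

Tie-breaks and tolerances that matter: family-order tie-break in model
selection; $|Q| < 10^{-8}$ switch to the log-normal branch; optimizer
relative tolerance $10^{-12}$ with up to 500 BFGS iterations per start;
reconstruction's censoring solve iterates to an exact risk-set match or
keeps the closest solution; `surv_quantile` is closed-form throughout, and
the independent bisection oracle in the tests agrees to $10^{-6}$.
Degenerate inputs are handled explicitly: zero-time survival is 1, flat
curves reconstruct to all-censored records, zero discount gives unit
factors, and a zero incremental-QALY comparison reports a dominance flag
instead of dividing.

The test suite runs at desk scale by choice: parameter recovery at
$n = 2000$-$5000$, trial-scale pipelines at the actual 338/324, PSA checks
at 150-1000 draws; the full suite completes in about half a minute and the
acceptance script in under a minute on one core.

## Known limitations

Unit pack sizes, the second-line schedule and the horizon are calibration
assumptions, surfaced in configuration rather than hard-coded; survival
uncertainty is absent from the PSA; adverse events are one-off expected
costs; and the cycle-end accrual convention biases totals down by under
1% relative to the continuous-time limit (quantified against quadrature
in the tests). All amounts are used as printed in USD with no currency
conversion.
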