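---
title: "Methods: partitioned-survival cost-effectiveness of first-line camrelizumab plus chemotherapy in non-squamous NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem and the model

The package evaluates first-line camrelizumab + pemetrexed/carboplatin (arm
`CC`) against pemetrexed/carboplatin (arm `C`) in advanced non-squamous
NSCLC without EGFR/ALK alterations, from the Chinese health-care system
perspective. The decision model is a three-state **partitioned-survival
model** (PSM): progression-free (PFS), progressed disease (PD), and death.
A PSM needs no transition probabilities; state occupancy comes directly from
the two survival curves evaluated at each cycle time $t$:

$$p_{PFS}(t) = \min\{S_{PFS}(t), S_{OS}(t)\},\quad
  p_{PD}(t) = S_{OS}(t) - p_{PFS}(t),\quad
  p_{death}(t) = 1 - S_{OS}(t).$$

The central assumptions are therefore those of any PSM: the PFS and OS
curves jointly determine occupancy (no structural link between progression
and subsequent death hazard), and everything beyond the trial's follow-up
rests on the parametric extrapolation.

Key structural settings (all in `model_config()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| cycle length | 21 | days | the q3w treatment schedule |
| discount rate | 0.05 (range 0–0.08) | per year | Chinese pharmacoeconomic guidelines |
| horizon | until $S_{OS} < 1\%$, capped at 25 | years | "lifetime" operationalized; the cap guarantees termination for heavy-tailed log-logistic extrapolations (a warning is recorded when it binds) |
| $u_{PFS}$, $u_{PD}$ | 0.804, 0.321 | utility | published NSCLC health-state utilities |
| half-cycle correction | off | — | occupancy is evaluated at cycle starts; a switch enables midpoint evaluation so its impact can be quantified (cycle-length refinement tests show the 21-day discretization moves life-years by under 1% for trial-like curves) |

Occupancy is clamped with $p_{PFS} \le S_{OS}$ because independently fitted
PFS and OS curves can cross during extrapolation; clamping preserves the
partition-of-one invariant, which is asserted on every trace.

## From published curves to survival functions

**Digitized-curve repair** (`clean_curve`): digitizer output is noisy —
pixel-level upward wobbles, values slightly above 1, duplicated points. The
cleaner merges tied times (keeping the lower survival), clips to $[0,1]$,
enforces monotone non-increase, and anchors the curve at $(0, 1)$. It is
idempotent.

**Pseudo-IPD reconstruction** (`reconstruct_ipd`): the iterative
interval-by-interval algorithm of Guyot and colleagues. Within each interval
between consecutive numbers-at-risk times, the number censored is first
guessed from the survival ratio, censor times are spread uniformly, event
counts are recovered from the product-limit relation, and the censor count
is adjusted until the implied number at risk matches the published count
(stopping when the adjustment no longer changes, or after 100 iterations).
Numerical choices worth knowing:

- Event counts carry the rounding residue across steps, so totals do not
  drift by one per interval.
- Beyond the last risk-table time there is no at-risk anchor: events are
  taken from the remaining survival drops and all remaining subjects are
  censored at the last digitized time. When a total event count is
  supplied, censoring in this final interval is searched to match it — but
  an allocation is rejected if it distorts the reconstructed curve by more
  than 0.015 survival units. Curve fidelity deliberately outranks the event
  total: on synthetic fixtures the total still lands within ±2 events in
  about 90% of strata, and the Kaplan–Meier round-trip error stays below
  0.02 everywhere.
- A risk-table interval containing no digitized step censors its losses at
  the interval midpoint.
- Times are months throughout reconstruction and fitting; the 21-day cycle
  conversion happens only inside the PSM, so no stage can silently mix
  units.

**Parametric fitting** (`fit_distribution`): six families under fixed,
documented parameterizations — exponential $S = e^{-\lambda t}$; Weibull
$S = e^{-(t/\sigma)^k}$; Gompertz $S = \exp\{-(b/a)(e^{at}-1)\}$;
log-logistic $S = 1/(1+(t/\alpha)^\beta)$; log-normal
$S = 1 - \Phi((\ln t - \mu)/\sigma)$; generalized gamma in the
$(\mu, \sigma, Q)$ form, which nests Weibull ($Q = 1$) and log-normal
($Q = 0$). Maximization of the right-censored likelihood
$\sum_{events}\ln f(t) + \sum_{censored}\ln S(t)$ is delegated to
`flexsurv::flexsurvreg`, whose parameterizations match the above; the
package keeps its own likelihood, AIC/BIC bookkeeping ($AIC = 2k - 2\ln L$,
$BIC = k\ln n - 2\ln L$ with $n$ = subjects, a convention fixed for
reproducible fit tables), and selection logic. Optimizer failure is never
silent: a non-converged fit carries its diagnostic and is excluded from
selection. `select_best` minimizes AIC by default (BIC reported alongside;
a disagreement between the two is messaged, never silently resolved), with
ties broken by parameter count and then a fixed family order. The
"visual inspection" part of model selection is supported by
`overlay_data`, which emits the KM steps plus every fitted curve on a grid.

## Costs

All monetary values are USD (the 6.47 CNY/USD conversion is metadata).
`econ_parameters()` holds every input as value / min / max / distribution,
mirroring the published input table row by row so it can be audited against
it. Accumulation per cycle: active drug cost × $p_{PFS}$, subsequent-therapy
cost × $p_{PD}$, monitoring while alive, terminal care weighted by incident
deaths, all discounted; PD-L1 testing and the expected adverse-event cost
(incidence × unit cost, grade ≥3 neutropenia / anaemia / thrombocytopenia)
are one-time first-cycle items. The adverse-event disutility is likewise a
one-time QALY decrement in the first cycle, whose discount factor is 1 —
whether to discount it is moot at that position, which is why the default
applies it undiscounted.

Design choices where the published description left room:

- **Induction length 5 cycles** (the input table's own specification), not
  the "4–6" of the protocol prose; configurable.
- **Camrelizumab 2-year exposure cap** implemented as 34 complete 21-day
  cycles of camrelizumab cost; afterwards maintenance continues with
  pemetrexed alone.
- **Monitoring while alive in either state**; a flag restricts it to PFS.
- **Subsequent therapy for the whole PD duration** — the source gives a
  per-cycle figure with no stopping rule, including the chemotherapy arm's
  62.2% crossover to camrelizumab, which is deliberately not capped at two
  years either (`monitoring_pfs_only` and the cap are flags, so both
  readings can be quantified).
- **Printed per-cycle drug costs are authoritative** (452.00 / 740.00 /
  87.50 $/cycle). The per-mg prices and dosing constants (BSA 1.80 m²,
  weight 65 kg, creatinine clearance 90 ml/min) are carried for
  re-derivation, but 500 mg/m² × 1.80 m² × 0.86 $/mg = 774 ≠ 740, so the
  per-mg route is documented rather than silently reconciled.

## Sensitivity analysis

**One-way DSA** (`run_dsa`): each parameter to its min and max (published
95% CI where available, otherwise ±20%), everything else at base, ICERs
recorded and rows ranked by spread. Because the dominant uncertainty in
survival-driven models is the extrapolation family itself, each
(arm, endpoint) also gets a categorical scenario row: the model re-run with
every converged alternative family, reporting the ICER range.

**PSA** (`run_psa`): 1000 iterations by default. Probabilities, proportions
and utilities are beta; costs are gamma; shapes are matched by method of
moments with $sd = (max - min)/3.92$. Negative disutilities are sampled on
magnitude and negated; infeasible beta moments fall back to uniform with a
warning. Survival parameters stay at base — only economic inputs carry
distributions — and one RNG stream, seeded once, samples parameters in the
fixed order of the parameter table, so runs reproduce bit-exactly across
platforms. The CEAC reports, on a $0–100{,}000 grid (always including
$32,457 = 3\times$ and $10,819 = 1\times$ GDP per capita), the fraction of
iterations with positive incremental net monetary benefit
$w\,\Delta QALY - \Delta Cost$.

## The synthetic trial generator

No individual-level or digitized trial data are deposited, so `trial_spec()`
ships a generator whose defaults emulate the trial's published summaries:
205/207 patients, median OS 27.9 vs 20.5 months, median PFS 11.3 vs 8.3
months; OS log-normal in the combination arm and log-logistic in the
chemotherapy arm, PFS log-normal in both — the same families the published
analysis selected, so family-recovery by AIC is a meaningful test. Where
the summaries pin down only the median, the second parameter was fixed
once at a typical value for advanced-NSCLC survival curves: log-sd 0.8 for
the log-normal endpoints, and log-logistic shape 1.6, chosen so that
survival at twice the median (≈ 24%) matches what an exponential with the
same median would give. Follow-up is administrative: uniform accrual over
12 months with a 30-month cut, giving censor times between 18 and 30 months
— the published interim analysis had much shorter follow-up (median 11.9
months), but stable six-family fits need longer observed support.

PFS and OS must satisfy $S_{PFS} \le S_{OS}$ subject-wise, so OS is drawn
first and PFS as $\min(OS, \text{latent progression time})$. Drawing the
latent time straight from the marginal PFS family would drag the realized
PFS median below target, so the latent distribution is rescaled in closed
form such that $S_{OS}(m) \cdot S_{latent}(m) = 1/2$ exactly at the target
median $m$.

What the generator does **not** emulate: response dynamics, time-varying
hazards beyond what the chosen families express, adverse-event time
courses, informative censoring, or treatment crossover as an event process
(crossover enters only through the subsequent-therapy cost mix). Passing
tests on this fixture therefore validate the pipeline's mechanics and
statistical behaviour, not the clinical truth of any particular
extrapolation.

## What the synthetic base case shows — and a reproducibility caveat

On the shipped fixture the combination arm gains discounted QALYs
(≈ 0.14) and life-years, with an ICER around \$18,000/QALY — comfortably
cost-effective at the \$32,457/QALY threshold, in line with the published
decision conclusion. The published analysis, however, reported the
combination as outright cost-*saving*. That specific sign cannot be
derived from the published inputs: back-solving the published per-arm
LY/QALY totals for state occupancy and pricing those occupancies with the
published per-cycle costs yields a combination arm that is several
thousand dollars *more* expensive (its progression-free state, at
camrelizumab + pemetrexed maintenance prices, is the costliest
person-cycle in the model), and per-arm totals roughly twice those
published. The package implements the accumulation as specified and
documented here and reports what it computes; the acceptance suite
records this discrepancy rather than calibrating it away.

## Problem sizes and numerical tolerances

The test suite and acceptance script use: the full two-arm fixture
(205/207) for end-to-end runs; n = 200/arm over 10 seeds for the
reconstruction round trip (sup-norm tolerance 0.02 at digitized times);
n = 20,000 with ~20% censoring for log-normal parameter recovery (±0.03 on
both parameters); n = 5,000 over 20 seeds for family recovery (≥80% by
AIC); 1000 PSA iterations; 50,000 draws for generator median checks (±2%).
Occupancy conservation is asserted at $10^{-12}$; itemized costs must sum
to totals at $10^{-6}$; the ICER identity holds to $10^{-9}$ whenever
defined.

## Limitations

- Everything downstream of fitting inherits extrapolation uncertainty; the
  family-scenario DSA rows quantify, and on synthetic data confirm, that
  the OS model choice is the largest single driver of the ICER.
- The reconstruction's event-total contract is best-effort (±2 in ~90% of
  synthetic strata) because late-interval censoring is not identifiable
  from the curve alone once fidelity is enforced.
- The PSA samples economic parameters independently (proportions are not
  renormalized to sum to one, matching the published setup; their sums are
  checked and logged).
- No indirect costs, vial-sharing, subgroup effects, or external validation
  against registry survival.
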