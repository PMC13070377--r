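---
title: "Methods: surveillance statistics and the LGD cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveillance statistics and the LGD cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrettsCEA)
```

## Scope

`barrettsCEA` implements two connected analyses for Barrett's esophagus (BE)
surveillance cohorts stratified by low-grade dysplasia (LGD) status:

1. **Person-time progression statistics** — crude progression proportions,
   incidence rates per 100 person-years with exact Poisson confidence
   intervals, and incidence rate ratios (IRR) with exact conditional
   intervals, for three groups: never-dysplastic BE, LGD at the index
   endoscopy, and LGD first seen during surveillance.
2. **A cost-utility model** — a discrete-time Markov cohort model comparing
   continued endoscopic surveillance of LGD against three radiofrequency
   ablation (RFA) policies, with staged calibration, deterministic and
   probabilistic sensitivity analysis, and acceptability curves.

A synthetic cohort generator provides patient-level data with the same
statistical structure, so every stage is testable without access to the
clinical database.

## Person-time statistics

Rates are `100 * events / person_years`. Confidence intervals use the exact
(Garwood) Poisson bounds, `qchisq(a/2, 2k)/2` and `qchisq(1-a/2, 2k+2)/2`
scaled by `100/PY`, with a zero lower bound at zero events. The exact method
was chosen over the log-normal approximation because only the exact bounds
reproduce all published per-100-person-year intervals for this cohort's
counts at one-decimal precision.

IRR intervals condition on the total event count: given `k1 + k0`, the
comparison-group events are binomial, an exact Clopper–Pearson interval is
computed for that proportion and mapped to the ratio scale by
`p/(1-p) * PY0/PY1`. Again, the exact conditional method (not the Wald
log-IRR interval) matches the published intervals. Zero reference events
yield an unbounded upper limit, flagged rather than erred.

Reported values are rounded half-up to one decimal (`round_half_up()`),
matching the convention of clinical tables; base R's banker's rounding
would differ on exact ties.

## Synthetic cohorts

`generate_cohort()` draws, per patient, an exponential progression time at
the group's constant hazard and an administrative censoring time from a
gamma distribution moment-matched to follow-up of mean 5.7, SD 4.7 years,
truncated at the 21-year program window; exposure is the minimum of the
two. Constant hazards are the minimal model consistent with aggregate
per-100-person-year reporting — the generator makes no claim about
time-varying risk, and passing recovery tests therefore says nothing about
non-exponential hazards in real data. LGD course categories
(reverted/back-and-forth/persistent at 0.690/0.198/0.112) and the per-group
EAC share of progressions are drawn from the published proportions; they
are descriptive labels, not dynamic constraints, in the generator. All
draws derive from one seed; identical seeds give byte-identical tables.

## The Markov cohort model

**States.** LGD is kept as two copies tagged by origin (index endoscopy vs
developed during surveillance) because the ablation policies discriminate
on origin and the starting cohort mixes ~52% index / ~48% surveillance
LGD. Non-dysplastic BE after reversion passes through interval-tagged
tunnel states (6-month confirmation, then 12-month, then 2-yearly recall),
because the recall policy depends on dysplasia history and a memoryless
state could not encode it. High-grade dysplasia (HGD), early (T1a) and
advanced adenocarcinoma (EAC), two post-ablation states and two absorbing
death states (cancer/other) complete the set. The admissible movements are
defined by the parameter schema and documented here.

**Cycles, horizon, discounting.** 6-month cycles over 35 years (70
cycles); discrete discounting at 5%/year, `(1.05)^(-t_years)`, applied
identically to costs and QALYs. State payoffs accrue on start-of-cycle
occupancy; event payoffs on within-cycle transition flow; no half-cycle
correction. These conventions are stated explicitly because cost-utility
results are only comparable across implementations that share them. One
caveat: at 5%
discounting the maximum attainable discounted QALY over 35 years is about
17, so reported QALY totals near 24 for this horizon can only be
undiscounted quantities; the engine reports both streams so either
convention can be compared.

**Strategies.** All four strategies ablate HGD and treat EAC identically
(T1a: endoscopic resection plus ablation; advanced: a stage-specific care
payoff bundle charged on entry). They differ only in the LGD rows: under an
ablation trigger every occupant of a triggered LGD state is treated that
cycle, moving to the post-ablation state on success (default 90%) and
staying for retreatment otherwise, both arcs carrying the procedure cost,
complication-adjusted, and disutility. Post-ablation recurrence is
retreated identically under all strategies; this keeps downstream dynamics
strategy-independent, which is both the clinically standard policy and what
makes "ablate surveillance-detected LGD" exactly inert on an all-index
cohort (a property the tests exploit).

**Numerical contracts.** Transition rows must sum to 1 within 1e-9 (the
validator names the offending state); traces conserve probability;
combined death occupancy is non-decreasing. Annual rates convert to cycle
probabilities via `1 - exp(-r * cycle_length)`.

## Calibration

The LGD transition probabilities (progression per origin, reversion,
recurrence after reversion) are not directly observed; they are fitted so
that a simulated all-LGD cohort (187 patients, 1341 person-years, i.e. 14
six-month cycles of mean follow-up) reproduces five targets: progression
1.0 and 2.2 per 100 person-years and the three course proportions. Course
categories are read from a history-tracking chain (LGD-never-reverted /
reverted-never-recurred / ever-recurred split into current LGD or ND),
measured among surviving non-progressed patients at the end of follow-up.

The objective is the weighted squared *relative* deviation, scale-free
across rate and proportion targets. The staging is a user-configurable
`stage_plan`; the shipped default has seven stages ordered from best- to
least-identified — each progression probability against its own rate, then
reversion, then recurrence, then joint refinements ending with a joint
polish. Per stage, single parameters are bracketed by a coarse logit-space
scan and refined by golden-section search (the feasible region where rows
stay sub-stochastic can be a narrow sliver of (0,1), which defeats a naive
unimodal search); multi-parameter stages use Nelder–Mead on the logit
scale, which enforces the bounds by the transform. A stage keeps its
incumbent unless the candidate improves it, so the objective is
non-increasing by construction. `converged` requires both stabilization of
the outer stage cycle (change < 1e-8) and a final objective below 1e-6;
a fit stalled against a feasibility boundary by an unattainable target
reports `converged = FALSE` with `boundary_saturated = TRUE`.

Noise-free parameter recovery on the default chain is essentially exact
(median relative error ~1e-11 %), so the shipped tolerance of 5% in the
recovery tests is conservative.

## Economic evaluation

`compare_to_baseline()` mirrors the published presentation: pairwise
incremental cost, QALYs, ICER (with dominance labels) and net monetary
benefit against the surveillance-only arm. `efficiency_frontier()`
additionally prunes strict and extended dominance and computes sequential
ICERs; both modes are available because pairwise-vs-baseline tables and
frontier ICERs answer different questions and published tables mix the
conventions. The NMB-optimal strategy at any threshold equals the frontier
decision at that threshold (property-tested on random strategy sets).

## Sensitivity analysis

Distributions are assigned by family convention — gamma for costs, beta
for probabilities and utilities — parameterised by method of moments from
(mean, SE). Annual rates are varied on the cycle-probability scale
(`beta_rate`) and converted back. Because no sourced uncertainty table
ships with the package, default SEs are placeholder coefficients of
variation (20% for costs, 10% otherwise) and one-way ranges default to
mean ± 2 SE clipped to validity; both are overridable per parameter.
Parameters are drawn independently; no correlation structure is assumed.

PSA draw `i` uses RNG substream `seed + i`, so enlarging `n_draws` never
reshuffles earlier draws. A sampled transition row exceeding 1 is
renormalized and logged per draw rather than discarded, which would bias
the sample toward the interior. The CEAC splits exact NMB ties equally, so
win fractions sum to 1 at every threshold. The degenerate-PSA contract
(all SE = 0 equals the deterministic run to 1e-9) is tested, as is
convergence of the CE-plane cloud mean — checked with payoff parameters
varied, because outcomes are linear in costs and utilities (the cloud mean
is then unbiased for the deterministic point), whereas under varied
transition parameters the cloud mean estimates `E[f(theta)]`, which
differs from `f(E[theta])` by a nonlinearity offset that is a feature of
PSA, not an engine error.

Threshold analysis (`threshold_find()`) bisects the parameter until the
incremental ratio crosses the willingness-to-pay value, returning a
no-crossing result rather than an error when the bracket does not straddle
the threshold.

## Parameter provenance and limitations

The shipped parameter file distinguishes three provenance classes: (i) the
four LGD dynamics rates, calibrated to the cohort targets; (ii) the
never-dysplastic progression hazard, taken from the cohort's own rate; and
(iii) everything else — costs, utilities, disutilities, cancer and
post-ablation dynamics — shipped as literature-informed placeholders listed
under `placeholders:` and flagged on load. Cost-utility totals are only as
good as the tariff and utility tables behind them; until locally sourced
values are transcribed into the file, the base-case cost/QALY/ICER outputs
of this package characterise the model mechanics under the documented
placeholder inputs, and no placeholder was adjusted to steer those outputs
toward any external benchmark.

Problem sizes used by the shipped checks: 1e5 individuals for the
microsimulation cross-check, 20 ground-truth sets for calibration
recovery, 5000 draws for PSA convergence on a 10-year-horizon
configuration, 1000 draws for the full-horizon acceptability curves. Other
known limitations: constant other-cause mortality (a cycle-indexed matrix
is supported but no life table is shipped); no lead-time or
misclassification modelling for the LGD diagnosis itself; no
value-of-information analysis.
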