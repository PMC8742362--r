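---
title: "Causal identification in case-control designs: models, functionals and checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal identification in case-control designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccident)
```

## The scientific problem

Case-control studies are best understood as cohort studies with additional,
design-induced missingness: a fixed cohort is followed from a common time
zero over `K` discrete exposure windows, and the control-sampling scheme
decides whose exposure information is collected. Whether the resulting
case-control contrast carries a causal meaning depends on the estimand one
has in mind, on the sampling scheme, and on a set of identification
assumptions. `ccident` makes this whole chain executable: it simulates
cohorts from fully specified structural models with counterfactual ground
truth, enumerates their exact distributions, applies the classical sampling
schemes, and evaluates the identifying functional of each scheme both on
samples (estimators) and on the exact law (identification checks).

### The cohort model

A subject carries, while at risk, a discrete covariate `L_k`, a binary
exposure `A_k` and an event indicator `Y_k = I(T < t_k)` on windows
`k = 0, ..., K-1` (half-open `[t_k, t_{k+1})`, administrative end `t_K`,
all indices 0-based). A `dgp_spec()` gives the structural laws as
probability functions of the observed history — initial covariate law,
exposure law, covariate transition law, discrete-time hazard — plus an
optional binary unmeasured confounder `U` that may enter the exposure and
hazard equations. Windows are unitless indices throughout: interval lengths
play no role in any of the quantities computed here, so the package never
assigns calendar durations.

Two intervention pairs define the causal contrasts:

* the **intention-to-treat (ITT)** pair sets the baseline exposure `A_0` to
  1 versus 0 and leaves later exposures to their natural law;
* the **per-protocol (PP)** pair holds the entire exposure path at 1
  ("always exposed") versus 0 ("never exposed").

Counterfactual outcomes are generated from shared exogenous uniforms — one
draw per structural equation per subject-window — so all four regimes are
jointly defined on every simulated subject and consistency holds row by
row: a subject whose observed path happens to follow a regime has exactly
that regime's counterfactual outcome. The coupling is a simulation device;
it does not affect any marginal interventional distribution, which is the
only level at which estimands are defined.

### Estimands and identifying functionals

Four estimand families are computed by exact enumeration of the intervened
model (never by simulation — identification is a statement about
distributions, and Monte Carlo noise belongs only to estimator checks):

| Sampling scheme | Estimand |
|---|---|
| case-base | marginal risk ratio `Pr(Y_K(1)=1) / Pr(Y_K(0)=1)` |
| survivor | conditional odds ratio of `Y_K(a)` given `L_0` |
| risk-set, ITT | marginal discrete-time hazard ratio of the baseline pair |
| risk-set, PP | marginal discrete-time hazard ratio of the sustained pair |

with matched variants targeting the marginal risk ratio, the conditional
odds ratio, the `L_0`-conditional hazard ratio, and the history-conditional
per-protocol hazard ratio respectively. Each scheme's identifying
functional — a weighted exposure-odds ratio, or a discordant-pair ratio for
matched designs — is evaluated exactly by
`evaluate_identifying_functional()`: expectations over the enumerated
observed-data law replace sample sums, exact conditional probabilities
replace fitted propensities, and expected selection counts replace realized
draws. On a model satisfying a result's assumption set the functional
equals the estimand to enumeration precision (about `1e-15` in practice,
asserted at `1e-10`); breaking a single assumption moves it off target by a
margin that the test suite freezes after computing it once by enumeration.

The history-conditional per-protocol estimand is computed through the
consistency identity: among subjects whose observed exposure is constant
through window `k`, the observed hazard given the covariate history equals
the counterfactual hazard of the corresponding sustained regime, so
`true_hazard_ratio(spec, "sustained", "history")` reads it off the observed
law directly.

### Weights

Baseline confounding is handled by time-fixed inverse probability weights
`W = A_0/p + (1-A_0)/(1-p)` with `p` the control-conditional propensity
`Pr(A_0 = 1 | L_0, S = 1)`; time-varying confounding by the telescoping
per-window product of inverse propensity factors conditioned on the full
covariate and exposure history among the event-free selected controls.
Weights are always derived from control data and applied to cases and
controls alike; the estimators have no access to case-fitted propensities.
Per-protocol analysis censors every subject from its first deviation
(`censor_at_deviation()`), after the weights are derived, so uncensored
exposure paths are constant. The reference propensity fitter is saturated
(stratum-wise frequencies over discrete covariates); no truncation or
stabilisation is applied, because the identification results concern the
untruncated functional.

For the risk-set ITT weights, the propensity is fitted on window-0 selected
controls (the literal derivation with the selection indicator replaced by
`S_0`). A `pool_controls` flag fits instead on all selection events; at the
distribution level this is a slightly different functional — ever-selected
controls over-represent long survivors — and the package keeps both so the
difference can be measured (it is about `0.0015` on the constant-hazard
preset, versus an exactly identifying literal variant).

## Sampling devices

Eligibility is "event-free at `t_k`" for risk-set sampling (the index case
is a member of its own window's eligible set, and a subject may be selected
repeatedly), the whole baseline cohort for case-base sampling, and the
event-free-at-`t_K` for survivor sampling. Per-protocol eligibility does
not screen on adherence — deviation is handled downstream by censoring —
but the matched per-protocol pool does, because there the control's
exposure history is the exposure information being transferred.

Two risk-set selection devices are implemented:

* **per-case**: a fixed number `m` of controls per qualifying case, drawn
  uniformly without replacement from the eligible set. The per-eligible
  selection probability is then proportional to the case hazard of that
  window, so the constant-selection-probability condition holds exactly
  when that hazard is constant — which the `constant-hazard` preset
  engineers (see below).
* **fraction**: every eligible subject-window is selected independently
  with the same probability, satisfying the selection condition by
  construction. The per-protocol identification checks use this device: in
  a two-window model with genuine deviation, the adherent-case hazard is
  necessarily thinned after window 0 relative to the full event hazard, so
  no parameter choice can make the per-case device's selection probability
  exactly constant under per-protocol qualification. The level of the
  fraction (like `m`) cancels from every odds-ratio functional.

Three bookkeeping choices matter for exactness. First, the per-window
selection indicator `S_k` is binary, but "number of times selected"
(`n_selected`, and the weighted count `sum_k W_k S_k`) counts multiplicity
across cases within a window; this makes the sample-level count an
unbiased realisation of the expected selection count used at the
distribution level, with no collision correction. Second, a case is never
paired with itself: the index case is excluded from its own draw (a
toggle restores inclusion). Third, distribution-level evaluation ignores
the self-exclusion, an `O(1/n)` effect that vanishes in the
infinite-population limit the functionals are defined on.

Matched sampling assigns each qualifying case one control exposure `A'`
drawn uniformly from the scheme's pool (all subjects, survivors, the
window's risk set, or the adherent history-matched risk set, always sharing
the case's covariate value). Cases with an empty pool are dropped with a
warning and counted — a finite-sample positivity event, not an error.

## The preset catalogue as an experimental design

Each preset of `preset_dgp()` plays a role in the identification or
violation suite; the non-obvious constructions are:

* **`constant-hazard`** — the risk-set ITT result needs constant marginal
  counterfactual hazards *and* a constant selection probability (here:
  constant observed marginal hazard). With covariate-dependent hazards
  neither constancy holds for free, because differential depletion of
  susceptibles makes mixture hazards time-varying. The preset therefore
  solves for its hazard table window by window: exposed-arm levels from the
  counterfactual-1 mean constraint (with a fixed within-arm covariate
  ratio), unexposed-arm levels from a 2-by-2 linear system pinning the
  counterfactual-0 mean and the observed hazard. The resulting model is
  genuinely confounded, yet all three marginal hazard series are constant
  to machine precision.
* **`tv-confounding`** — the per-protocol analogue. Its covariate space has
  three levels for a structural reason: with binary `L`, pinning the
  window-1 mean hazard under both sustained regimes forces the hazard to be
  covariate-free (two mixing distributions, two constraints, two unknowns),
  which would destroy the time-varying confounding the preset exists to
  exhibit. The two arms' window-1 hazard shapes are free up to their
  regime-mixture means, and switching probabilities depend on the current
  covariate. Covariate cell masses are kept away from zero so saturated
  per-window propensities are estimable at moderate cohort sizes.
* **`tv-confounding-homogeneous`** — the same confounding structure with
  pointwise proportional adherent hazards, for the history-matched
  per-protocol check, whose side condition is hazard-ratio constancy across
  histories and windows (no hazard-constancy or selection calibration is
  needed: the matched functional involves no sampling fractions).
* **`hazard-homogeneous`** — proportional hazards in every stratum-window,
  the side condition of the covariate-matched risk-set check. The
  cumulative-risk-homogeneous and odds-homogeneous presets enforce their
  constancy on the cumulative scale by deriving per-window hazards as
  `1 - (1 - R)^(1/K)` from target risks.
* **`rare-outcome`** — exposure is deliberately unconfounded (hazards stay
  covariate-heterogeneous). The rare-event question is whether the crude
  survivor exposure-odds ratio approximates the marginal risk ratio; under
  confounding it approximates the confounded odds ratio instead, which
  would test the wrong thing. At the default scale (overall risk about
  `5e-4`) the relative gap is about 0.04%, asserted under 2%.
* **`null`** — the hazard ignores exposure but depends on the covariate,
  which also drives exposure: a *confounded* null. Every identifying
  functional equals 1 exactly on it; the crude (unstratified) survivor
  odds ratio does not, and is excluded from the null-invariance check
  precisely because it is not an identifying functional.

Violation margins frozen in the tests (computed once by enumeration):
survivor-only controls under the case-base functional, `0.119`; an
unmeasured confounder, `0.711`; non-constant hazards under risk-set
sampling, `0.600` from the nearest per-window hazard ratio (the preset
doubles only the exposed arm's hazard after window 0, so the per-window
ratios themselves disagree and no single number is recoverable); effect
heterogeneity under matching, `0.086` (a sub-multiplicative
exposure-covariate interaction; with the original symmetric exposure
prevalences the matched weighting distortion cancelled almost exactly,
which is itself a caution about how easily this bias can hide); time-fixed
weights under time-varying confounding, `0.026`.

## Numerical choices and problem sizes

Exact checks assert at `1e-10` (enumeration arithmetic lands near
`1e-15`); probability-table normalisation at `1e-12`. Enumeration is capped
at `1e7` atoms with a structured error. Zero cells and degenerate
propensity strata raise classed conditions (`cc_zero_cell`,
`cc_positivity_violation`) rather than returning infinities; the matched
estimator returns a structured undefined result when a discordant cell is
empty, with an optional 0.5 continuity correction that is off by default.

The simulation studies in the test suite use 200 replicates at `n = 5000`
per scheme (mean within 3 Monte-Carlo standard errors of the true
estimand) plus a single `n = 200,000` cohort per scheme compared with the
exact functional at 3 MC standard errors scaled from the replicate spread.
The per-protocol scheme samples controls at a 0.5 per-window fraction in
the replicate study: its saturated propensities span 18 history strata,
and thinner control series leave strata empty at `n = 5000`; such
replicates are flagged and counted by `run_study()`, never silently
dropped.

## What the generator does and does not emulate

The simulator covers fixed cohorts with aligned time zero, discrete
covariates, binary time-varying exposure, discrete-time hazards,
unmeasured confounding, and exactly enumerable laws — the setting in which
identification claims can be verified to machine precision. It does not
emulate continuous covariates or continuous time, competing risks, loss to
follow-up, outcome censoring, measurement error, dynamic cohort entry, or
caliper/partial matching. Passing checks therefore demonstrate the
identification logic, not robustness of any estimator to those real-data
complications; in particular the saturated propensity fitter is exact only
because the covariate spaces here are small and discrete.
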