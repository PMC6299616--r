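---
title: "Modeling acute post-TBI neuroinflammation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling acute post-TBI neuroinflammation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbinflam)
```

## The model

Severe traumatic brain injury triggers an acute neuroinflammatory
response in which resting microglia polarize into a pro-inflammatory
(M1-like) or anti-inflammatory/reparative (M2-like) state under cytokine
cues, and the balance of those states shapes secondary tissue damage
over the first days after injury. `tbinflam` encodes this as seven
coupled ODEs for M1- and M2-like microglia, the CSF cytokines IL-1β and
IL-12 (pro-inflammatory) and IL-10 and IL-4 (anti-inflammatory), and a
qualitative damage variable D.

Signaling is saturating throughout: activation terms are Hill functions
$u^n / (K^n + u^n)$ of weighted cytokine pools, and anti-inflammatory
inhibition enters as quadratic suppression factors
$1 / (1 + (u/a_\infty)^2)$. The composite rates are

* $R_{m1}$, $R_{m2}$ — activation of resting microglia toward M1/M2,
  with $R_{m1}$ damped by IL-10 + IL-4;
* $R_{ms}$ — the IL-4/IL-10-driven switch of M1 cells to M2 (no reverse
  switching: once debris is cleared, M2 status is maintained);
* $R_p$ — pro-inflammatory cytokine release by M1 (a baseline term plus
  promotion by IL-12 and by damage-released DAMPs, damped by
  IL-10 + IL-4);
* $R_t$ — Th2-mediated release of IL-4/IL-10, self-limited by IL-10;
* $R_a$ — anti-inflammatory release by M2, likewise self-limited.

Resting microglia are not integrated as an eighth state: their balance
equation is fast relative to the rest of the system, so the
quasi-steady-state expression $mr = s_{mr}/(R_{m1} + R_{m2} + \mu_{mr})$
is substituted everywhere. `simulate_model_full_mr()` integrates the
full eight-state variant so that this reduction can be checked; with the
default fast resting turnover the two agree on M1 to within a few
percent over the whole horizon, which is the self-consistency test run
in the suite.

Damage integrates pro-inflammatory drive (IL-12 and IL-1β, suppressed by
IL-10), direct M1 neurotoxicity, and clearance by both microglial
phenotypes; it is a qualitative proxy for secondary injury, not a
measured quantity.

### Units and ranges

Time is in hours with a 0–120 h horizon (days 0–5 post-injury), matching
the 6-h resolution of the binned data. Cytokine states are on the pg/mL
scale of the CSF assays; microglia and damage are in arbitrary units, as
only their relative dynamics are interpretable. The 45 parameters
(`param_names()`) are rates (1/h), half-activation constants (pg/mL
scale), threshold-like factors, or dimensionless Hill exponents
constrained to be ≥ 1. All parameters are strictly positive.

### Numerics

Integration uses a stiff-capable adaptive solver (`deSolve::ode`,
`lsoda`) with default tolerances `rtol = 1e-6`, `atol = 1e-9`. Because
the state space is a positive cone, post-hoc negativity is treated
strictly: undershoots within the absolute tolerance are clipped to zero,
anything larger raises a solver-failure condition carrying the failing
time — clipping silently past that point would mask genuine solver
breakdown. The test suite cross-checks the adaptive solution against a
fixed-step classical RK4 oracle at Δt = 0.01 h (agreement within 1e-4
relative) and the derivative field against an independent transcription
of the equations (1e-12 relative).

## Binning sparse clinical series

CSF draws arrive roughly twice daily and irregularly, so the model is
fitted to moving-average summaries: overlapping 12-h windows shifted by
6 h (0–12, 6–18, …, 108–120 h), each summarized per analyte by the
pooled mean, sample SD, and SE across all measurements of all patients
in a cluster. Design choices a user should know:

* Windows are half-open `[lo, hi)` with the last closed at 120 h, so a
  measurement at an interior 6-h mark contributes to exactly two
  windows and boundary values are never triple-counted.
* The bin's representative time is the window midpoint (6, 12, …,
  114 h); a bin centered at 0 is not formed because the first window is
  0–12 h.
* Values are pooled across patients rather than averaged per patient
  first; with unequal sampling this weights patients by their number of
  draws, which matches averaging "all values" in a window.
* Windows with fewer than two values carry no SD and are skipped by the
  fitting objective; empty windows are reported but never interpolated.

## The fitting objective

Goodness of fit is the SD-normalized squared error summed over the four
cytokines and all usable bins, with the model evaluated at bin centers,
plus flat penalties for three microglia heuristics: M1 > M2 before day
2, M2 > M1 after day 3, and M1, M2 > 2 throughout. Each violated
heuristic adds 100 once (not per time point); smaller penalties fail to
enforce the constraints against data terms of this magnitude. The
heuristics are checked on a 1-h grid, with "before day 2" read as
[0, 48) h and "after day 3" as (72, 120] h, leaving days 2–3
unconstrained; the grid, penalty, and the SD floor below which bins are
skipped are all configurable through `fit_opts()`.

Optimization is Nelder–Mead (via `stats::optim`, whose simplex uses the
standard reflection/expansion/contraction/shrink coefficients 1, 2, 0.5,
0.5) over all 45 parameters and 7 initial conditions in log space, which
converts the positivity constraint into an unconstrained search; Hill
exponents are floored at 1 on decoding, and initial conditions use a
small offset (1e-6) so exact-zero starts are representable. A free/fixed
mask supports restricted fits. Two departures from a bare `optim` call:
the best evaluated point is tracked explicitly, so a fit can never
return worse than its start, and a hard evaluation cap is enforced
mid-iteration. `tol_x` is recorded in the options for provenance but the
simplex stops on the function-value tolerance, which is the control
`optim` exposes. Integration failures inside the objective return a
large sentinel (1e10) instead of raising, so the simplex simply moves
away from pathological regions.

A caution on interpretation: the 52-dimensional problem is not
identifiable from four cytokine time courses, and no claim of
identifiability is made. The restricted-recovery tests (≤ 6 free
parameters on zero-noise data, each recovered within 10%) validate the
optimizer plumbing, not global identifiability; the ensemble exists
precisely because diverse parameter sets can fit similarly.

## Ensembles and distribution comparison

Each cluster's baseline fit is perturbed 100 times — every optimized
quantity multiplied by an independent U(0.5, 1.5) draw — and refitted,
giving an ensemble that captures fit variability. Initial conditions are
perturbed alongside parameters because they are optimized jointly; a
flag excludes them. One master seed spawns per-member substream seeds,
so ensembles are reproducible and independent of execution order. A
member whose perturbed start fails to integrate is redrawn once, then
kept as a sentinel-error member; all members are kept regardless of
convergence (no error-quantile filtering).

Per-parameter distributions of two ensembles are compared by the
Bhattacharyya coefficient $BC = \sum_i \sqrt{p_i q_i}$ over shared
histogram bins (default: 10 equal-width bins spanning the pooled range)
and distance $BD = -\ln BC$, undefined when the distributions do not
overlap. The empirical-histogram estimator is the default deliberately:
a Gaussian closed form can never report $BC = 0$, whereas non-overlap is
exactly the strongest signal the ranking uses (undefined BD sorts as
most disparate); the Gaussian variant `gaussian_bhattacharyya()` is
provided as a cross-check and the two agree for large well-behaved
samples. Parameters are ranked by ascending BC with ties broken by
descending BD, and called disparate when BC ≤ 0.38, BD ≥ 0.97, and the
parameter passes the sensitivity gate below. The exact histogram
settings behind a reported BC are a known source of near-threshold
ambiguity; the bin count is configurable and anchor tests use
constructed proportions rather than a particular binning.

## Sensitivity screen

Local normalized sensitivity is the elasticity
$S(t) = \frac{\Delta x(t)}{\Delta p} \cdot \frac{p}{x(t)}$, computed by
a central difference at $p(1 \pm 0.02)$ (the ±2% perturbation read as a
two-sided difference), evaluated for all seven states on the 6-h grid.
Grid points where the unperturbed output is below 1e-8 are excluded
rather than floored — dividing by a near-zero output manufactures huge
spurious elasticities. The scalar summary is the maximum |S| over
included outputs and times, and a parameter passes the gate when its
summary exceeds 2 at the baseline fit of at least one of the two
clusters being compared. Which output/time defines the threshold and
whether baseline fits or ensemble members are screened are not uniquely
determined by the analysis being reproduced; max-over-everything at the
baseline fit is the default, and both the output set and the threshold
are configurable. The suite validates the elasticity against the
analytic law $S = -\mu t$ for a pure decay process (0.1% at 24 h) and
requires the exceed set to be stable under halving the perturbation.

## The synthetic cohort generator

No patient-level data are distributed, so the generator emulates the
study's structure: 89 patients in three clusters (29 / 28 / 32), CSF
draws nominally at hours 7, 19, 31, … post-injury (7 AM / 7 PM) for five
days with Gaussian timing jitter (SD 1 h), independent per-draw dropout
with probability 0.36 — chosen so the expected draw count is the
study's ≈ 567 — and multiplicative lognormal measurement noise with CV
0.3, a typical scale for bead-array cytokine panels on positive,
right-skewed concentrations. Real missingness is driven by clinical
care, not coin flips, and real assay error has floor and ceiling
artifacts; passing tests on this generator therefore demonstrates that
the pipeline machinery works under realistic sparsity and noise, not
that the model fits any particular patient population.

The three cluster archetypes are parameter sets whose simulated
trajectories reproduce the qualitative phenotypes reported for the
patient clusters: cluster 1 (high inflammatory load, unfavorable
outcome) with prolonged elevated M1, high slowly-decaying IL-10 and
strong IL-1β/IL-12 release; cluster 2A (favorable) with faster M1 than
M2 decay, an M2:M1 ratio near 1 that ends above 1, and the least end
damage; cluster 2B (low load, unfavorable) with the most transient
microglial response, rapidly decaying IL-10/IL-4 and the highest end
damage. Absolute magnitudes are model-unit choices; what is contractual
— and what `make_archetypes(check = TRUE)` enforces at build time — is
the set of ordinal relations between the clusters' parameters
(`archetype_relations()`), the phenotype orderings above, and that the
parameters planted as disparate between clusters also carry model
sensitivity above the gate threshold, since only sensitive parameters
are reportable by the comparison. The fast resting-microglia turnover
(`mu_mr = 0.5`/h) serves that last requirement: it keeps the
quasi-steady resting pool from buffering parameter changes, so the
planted decay and release rates actually move the observable outputs.

One modeling tension is worth stating plainly: the reported cluster
phenotypes have the M2:M1 ratio of clusters 1 and 2B starting near 1:4
and *decreasing*, and cluster 2A starting near 1:1 — while the fitting
heuristics demand M1 dominance early and M2 dominance late. No
trajectory can do both. The archetypes follow the phenotypes, so each
cluster's ground truth carries a constant heuristic penalty (100 for
cluster 1, 200 for 2A and 2B) that no refit can remove without leaving
the phenotype. End-to-end recovery tests therefore assert the data term
of the objective, with the truth's constant penalty acknowledged.

## Pipeline and problem sizes

`run_pipeline()` sequences the stages — synthetic cohort (or a
user-supplied CSV), binning, baseline fit, ensemble, sensitivity screen,
and the three pairwise comparisons — writing every stage artifact plus
the fully-resolved configuration to the output directory, so any stage
can be re-run or audited in isolation. Reruns with the same
configuration and seed are byte-identical.

Default problem sizes follow the study (100-member ensembles, full
optimizer budget). The test suite and the acceptance script run the
same pipeline at deliberately reduced scale — 30-member ensembles and a
few hundred objective evaluations per fit — sizes chosen so the whole
analysis replays on a single CPU in minutes. At that budget a refit
mostly polishes its perturbed start, which is sufficient for the
distribution-comparison machinery being exercised: the planted
between-cluster differences are several-fold, so the ensembles separate
regardless of refit depth, and the screens gate them exactly as at full
scale.

## Known limitations

* Two microglial extremes only; no activation spectrum, no M2
  sub-phenotypes, and no spatial structure.
* Four modeled cytokines; IL-6, IL-8, TNF-α and the adhesion molecules
  measured in the same panels are outside the model.
* Damage is qualitative; its absolute scale is not interpretable.
* The chronic phase (> 5 days) is out of scope; so is the upstream
  PCA/k-means clustering that produced the cluster labels, which this
  package takes as input.
* Histogram-based BC near the selection threshold is bin-sensitive;
  treat parameters at BC ≈ 0.38 as borderline under either convention.
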