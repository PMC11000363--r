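---
title: "Deriving in-hospital-mortality cutoffs for rSIG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving in-hospital-mortality cutoffs for rSIG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsigcut)
```

## The problem

The reverse shock index multiplied by the Glasgow Coma Scale,

$$\mathrm{rSIG} = \frac{\mathrm{SBP}}{\mathrm{HR}} \times \mathrm{GCS},$$

is a bedside trauma severity score: hypotension, tachycardia, and
depressed consciousness all pull it down, so *low* rSIG marks
high-risk physiology. To use a continuous score for field triage one
needs a cutoff. This package derives and evaluates such cutoffs for
predicting in-hospital mortality in adult trauma cohorts, three ways:

1. **Curve-based**: fit a shape-restricted regression spline of
   mortality against rSIG, then read off (a) the *onset* score where
   mortality starts to rise above its high-score plateau, and (b) the
   *knee*, the score where the slope of the curve changes the most.
2. **Youden-based**: the threshold maximizing
   $J = \text{sensitivity} + \text{specificity} - 1$.
3. **Triage evaluation**: under-/over-triage rates of any cutoff on a
   stated population, against the American College of Surgeons field
   triage targets (under-triage < 5%, over-triage < 35%, both strict).

Throughout, the positivity convention is *score at or below the
cutoff predicts death*. Under it, under-triage is exactly
$100(1-\text{sensitivity})$ and over-triage $100(1-\text{specificity})$
at the same cutoff — an identity the test suite asserts rather than
assumes.

Because the national registry this kind of analysis runs on is not
redistributable, the package ships a synthetic registry generator with
a *planted, analytically known* mortality-risk curve, so that every
stage of the pipeline can be validated against ground truth.

## The shape-restricted spline model

Mortality is modelled as a Bernoulli outcome with

$$\operatorname{logit} p(x) = \beta_0 - \sum_j \gamma_j I_j(x),
 \qquad \gamma_j \ge 0,$$

where the $I_j$ are monotone I-splines (integrated M-splines): each
basis function is nondecreasing, 0 at the left boundary knot and 1 at
the right. A nonnegative combination of nondecreasing functions is
nondecreasing, so the linear predictor — and hence $p(x)$ — is
*nonincreasing by construction*, not merely post-hoc checked. The
basis is built from partial sums of B-splines
(`splines::splineDesign`), which also yields exact first and second
derivative matrices; the reported curve derivatives are analytic, not
finite differences.

For TBI-like curves, where mortality can rise again at very high rSIG
(Cushing-reflex physiology: intracranial hypertension producing
hypertension plus bradycardia, hence inflated rSIG in the sickest
patients), the `unconstrained_shape` variant fits
$\beta_0 - \sum_j \gamma_j I_j + \sum_j \delta_j I_j$ with
$\gamma, \delta \ge 0$ — a difference of two monotone components that
can bend both ways. With a vanishing ridge this spans the same fits as
an unconstrained logistic GLM on the basis, which the tests verify to
$10^{-4}$ in fitted probabilities.

Fitting alternates iteratively reweighted least squares with a
nonnegativity-constrained inner solve (Lawson–Hanson NNLS,
`pracma::lsqnonneg`; the free intercept is split into positive and
negative parts). Step-halving guards every update, so the penalized
log-likelihood is nondecreasing across iterations; convergence is
declared at a relative change below `tol` (default 1e-8) within
`max_iter` (default 100) iterations, and a non-converged fit is
returned with `converged = FALSE` rather than silently.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_interior_knots` | 5 | — | see below |
| `degree` | 3 (cubic) | — | smooth curve with continuous curvature, needed because the knee reads the second derivative |
| `ridge_lambda` | 1e-4 | — | identifiability of the split `unconstrained_shape` basis; negligible bias at cohort sizes |
| `grid_step` | 0.01 | rSIG units | curve/derivative evaluation grid; cutpoints are reported to this resolution |
| `onset_alpha` | 0.05 | fraction of peak slope | operationalizes "where mortality starts to increase" (below) |

**Why 5 interior knots and not more.** Interior knots sit at quantiles
of the *distinct* observed scores. The knee is the arg-max of
$|p''(x)|$, and for a cubic spline $p''$ is piecewise linear with its
extremes pinned at knots; a knot-dense fit therefore concentrates
spurious curvature at knots near the data-dense shoulder of the curve.
In a recovery study on 20 independently seeded synthetic cohorts
(n = 50,000 each, generator defaults), 10 interior knots produced knee
errors of up to 2.5 rSIG units against the planted curve's analytic
curvature extrema (4 of 20 cohorts beyond 1.5), while 5 interior knots
gave mean error 0.61 and maximum 0.92. Five knots still leave the
sigmoidal target curve well within the model class. Users fitting
curves with more structure should raise `n_interior_knots` and treat
the knee with correspondingly more caution.

### Cutpoint extraction

*Onset.* The fitted curves plateau at high rSIG with a slope that is
small but rarely exactly zero, so "where mortality starts to increase"
needs an operational threshold. `find_onset()` returns the largest
grid score at which the downhill slope $-p'(x)$ reaches `alpha` times
its own maximum. The default `alpha = 0.05` is a relative criterion,
invariant to rescaling mortality; results for 0.01/0.05/0.1 can be
compared by calling the function thrice.

*Knee.* `find_max_slope_change()` returns the grid arg-max of
$|p''(x)|$. Ties within a relative tolerance of 1e-8 of the maximum
are broken toward the **smaller** score — the clinically conservative
side, since a lower cutoff flags fewer patients as high-risk
mistakenly late. The tolerance matters: a pure decreasing logistic
ramp has two *exactly equal* curvature extrema at
$x_0 \pm w\ln(2+\sqrt 3)$, which differ only in floating-point noise
on a finite grid, and the tolerance makes the tie-break deterministic
there. The top three local maxima of $|p''|$ are reported as
alternatives so a secondary bend (e.g. the TBI high-score bump) is
visible. A curve with no curvature (constant or exactly linear) is an
error, not a silent answer.

*Youden.* Candidate thresholds are midpoints between consecutive
distinct scores, plus one candidate below the minimum and one above
the maximum; among ties the largest threshold wins (the most
permissive cutoff achieving the same $J$). The search is exact — the
tests check it against exhaustive brute force on random instances,
including heavily tied score vectors.

### ROC and confidence intervals

The AUC uses the rank (Mann–Whitney) formulation with ties counted
0.5, which equals the trapezoidal area under the empirical ROC; the
tests assert the two routes agree to 1e-12. The 95% CI uses the DeLong
structural-components variance estimator (cross-checked against an
independent implementation), with a seeded bootstrap available via
`ci = "bootstrap"`. DeLong was chosen as the default because it is
deterministic and standard for AUC inference; the bootstrap exists for
users who want percentile intervals on small strata.

## The synthetic registry

`generate_registry()` draws each patient from a single-latent-severity
model: a uniform latent $u$ (low = severe) maps monotonically to GCS
through a fixed quantile table, and through a Gaussian copula (loading
0.35) to SBP and HR, so low $u$ jointly implies low GCS, low SBP, high
HR — hence low rSIG. The in-hospital outcome is Bernoulli in the
planted risk curve evaluated at the *true* pre-contamination rSIG:

$$p(x) = p_{\text{floor}} + (p_{\max} - p_{\text{floor}})\,
  \sigma\!\left(\tfrac{x_0 - x}{w}\right)
  + [\text{TBI}]\, h\, e^{-(x - c)^2 / 2s^2}.$$

Default parameters: non-TBI $p_{\text{floor}}=0.004$, $p_{\max}=0.5$,
$x_0=13$, $w=2$; TBI $p_{\text{floor}}=0.006$, $p_{\max}=0.55$,
$x_0=15$, $w=2$ with bump $h=0.03$, $c=30$, $s=3$. The bump emulates
the high-rSIG mortality rise seen in TBI cohorts above rSIG 25. The
marginals are calibrated to a large all-comers emergency-department
trauma registry: overall mortality in the 1–3% band (the defaults land
near the upper end, ~2.6%), TBI prevalence 16.6%, male fraction
61.5%, mechanism mix 37.8/37.3/17.4/6.5/1.0% across
traffic/fall/blunt/penetrating/other, survivor rSIG centred near 24
with an interquartile width of ~6.

EMR-ISS is a monotone noisy transform of $1-u$ into $[1, 75]$ (a
power-4 quantile map), so that "EMR-ISS ≥ 25" carves out a ~25%
severe stratum; it makes no claim of clinical realism beyond
monotonicity in severity. Diagnosis codes are `S06.x` strings for TBI
(half of them with a concomitant non-S06 injury code, driving the
isolated-TBI vs TBI-plus split) and non-S06 S/T-chapter codes
otherwise. Small fractions of ineligible records — minors, arrivals
beyond 6 h, non-EMS transport, non-traumatic mechanisms,
transferred-out and dead-on-arrival outcomes — are planted so the
inclusion filter has real work; field-level missingness and
out-of-range vitals (SBP in [301,400] or [5,29], HR in [201,250],
exactly the ranges the cleaning rule blanks) are injected *after*
outcome assignment, so cleaning can never alter the truth.

What the generator deliberately does **not** emulate: correlation of
TBI status with severity (TBI is an independent coin flip, so the
synthetic TBI group is less enriched for deaths than a real one);
realistic joint vital-sign distributions beyond the single latent
factor; ICD-10 code structure beyond the S06 prefix; and
registry-specific quirks such as digit preference in blood pressure.
Passing tests therefore demonstrate that the *pipeline* recovers known
truth under its stated assumptions — not that any specific clinical
cutoff transfers to real registries.

## Cohort rules

Cleaning blanks SBP below 30 or above 300 mmHg and HR above 200
beats/min (strict inequalities; the boundary values are retained).
Inclusion keeps adults (age ≥ 18) arriving within 6 h of injury
(`time_to_ed` ≤ 360 min, boundary inclusive) by EMS with a traumatic
mechanism and a verifiable survived/died outcome, then requires SBP,
HR, GCS and EMR-ISS to be present. Exclusions are counted in two
stages — eligibility first, then missingness — so a record failing
both counts once, as an eligibility exclusion; a missing outcome
counts as a missing-data exclusion (an unverifiable treatment result).
The flow identity `final = total − eligibility − missing` is enforced
by construction.

The "rSIG 20 or less" triage population is implemented as
`score <= 20` (boundary included): where a table caption and the
running text disagree on "under 20" versus "20 or less", the more
inclusive text convention is adopted and documented here.

"Isolated TBI" is operationalized as an S06 code with no other
S/T-chapter injury code; the concomitant-injury pattern is a
configurable regex (`injury_pattern`) since registries differ in what
they record alongside the index diagnosis.

## Regression table

The odds-ratio table fits one univariable logistic model per variable
(likelihood-ratio test for the variable as a whole), screens at
p < 0.05, and fits one joint multivariable model on the survivors of
the screen. Wald 95% intervals, $\exp(\hat\beta \pm 1.96\,\mathrm{se})$,
match the conventional presentation; profile-likelihood intervals are
out of scope. SBP, HR and GCS are *refused* as covariates — they are
the components of rSIG, and entering them alongside it would be
double-counting. Mechanism is coded as dummies against the
traffic-accident reference. Model fitting delegates to `stats::glm`;
quasi-separation (diverging coefficients with fitted probabilities
pinned at 0/1) aborts with a diagnostic instead of returning a
meaningless table.

## Numerical choices, degenerate inputs

- IRLS working weights are floored at 1e-10; fitted-probability
  underflow is avoided by computing log-likelihoods via `log1p(exp())`
  on the linear predictor.
- Basis evaluation outside the boundary knots clamps to the boundary
  with a warning (relevant when predicting a curve on new data).
- `fit_shape_spline` requires two distinct scores and both outcome
  classes; `youden_cutoff`, `roc_auc` and `triage_rates` error on
  single-class input, and `triage_rates` names the empty stratum.
- A variable constant across comparison groups gets p-value 1 with a
  `constant` flag and a warning, rather than NaN.
- Report-table percentages round half away from zero to one decimal;
  scores are never rounded internally.

## Problem sizes used by the test suite

The test suite validates parameter recovery on one 50,000-record
synthetic cohort (fixed seed), monotonicity certificates on twenty
4,000-record cohorts, oracle equivalence for the Youden search and
AUC on one hundred 200-record instances, and the remaining contracts
on cohorts of 300–20,000 records. These sizes were chosen so the
whole suite exercises every operation at cohort scale while running
in well under a minute; the 50,000-record size matches the generator
default and gives Monte-Carlo error comfortably inside the recovery
tolerances.

## Known limitations

- The knee of a *fitted* curve is a noisy functional: even with the
  conservative knot default its sampling variability is a few tenths
  of an rSIG unit, and on curves whose true curvature has two nearly
  equal extremes (any symmetric sigmoid) the recovered knee can sit at
  either; the reported `knee_alternatives` should always be inspected.
- The onset point depends explicitly on `alpha`; there is no
  parameter-free definition of "where the curve starts to rise".
- The decreasing constraint is an assumption. For TBI-like groups it
  is wrong at high scores by design, which is why those groups default
  to the unconstrained-shape fit.
- Synthetic-data validation bounds implementation error, not clinical
  transportability (see the generator's non-goals above).
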