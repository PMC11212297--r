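---
title: "Comparing rare adverse-event outcomes between rural and referral facilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing rare adverse-event outcomes between rural and referral facilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruralni)
library(dplyr)
```

## The problem

Evaluations of rural surgical and obstetrical services ask whether patients
at small rural facilities experience adverse events at rates comparable to
patients at the larger referral facilities that are their only practical
comparators. Three features make this statistically awkward at once:

* **Events are rare.** Combined adverse-event proportions for low-acuity
  index procedures (hernia repair, appendectomy, colonoscopy, cesarean
  delivery) run between roughly 0.5% and 8%.
* **Arms are unbalanced.** Rural visits are typically 5-20% of the total,
  so the rural arm may contribute only a dozen events. Rare events plus
  imbalance invite complete or quasi-separation, under which the ordinary
  logistic maximum-likelihood estimate diverges.
* **"No significant difference" is not the question.** The policy-relevant
  claim is noninferiority — that rural care is *not worse than* referral
  care by more than a tolerable margin — which a nonsignificant superiority
  test cannot establish.

`ruralni` implements the full analysis chain for this setting: a synthetic
cohort simulator, Firth penalized logistic regression with penalized
likelihood-ratio inference, noninferiority margins and tests on proportions
and on adjusted odds ratios, cumulative risk stratification with E-value
sensitivity analysis, and a Monte Carlo power and minimum-sample-size
engine.

## Model and inference

The outcome model is ordinary logistic regression of the combined
adverse-event indicator on the facility-type indicator (rural = 1) plus
adjustment covariates; the treatment coefficient is the adjusted log odds
ratio of an adverse event at a rural versus a referral facility.

`fit_logistic()` maximizes the unpenalized likelihood by IRLS and flags
separation (fitted probabilities pinned at 0 or 1, IRLS non-convergence, or
a diverging coefficient norm); flagged fits return last-iterate coefficients
with `converged = FALSE` rather than presenting divergent estimates as
valid.

`fit_firth()` maximizes the Jeffreys-penalized log-likelihood

$$\ell^*(\beta) \;=\; \ell(\beta) + \tfrac12 \log \det I(\beta),$$

where $I(\beta)$ is the Fisher information. The penalty keeps estimates
finite under any separation pattern and reduces the small-sample bias that
afflicts rare-event fits. The optimizer is Newton iteration on the
Firth-modified score

$$U^*_r(\beta) = \sum_i \left( y_i - \pi_i + h_i\left(\tfrac12 - \pi_i\right) \right) x_{ir},$$

with $h_i$ the hat diagonal of the weighted design, step-halving whenever a
step fails to increase $\ell^*$, and convergence when the largest modified
score component or coefficient change falls below $10^{-8}$ (at most 100
iterations). These tolerances are package choices; they are far inside the
Monte Carlo noise of any downstream quantity. Two closed forms pin the
implementation down and are enforced in the tests to $10^{-6}$: the
intercept-only fit has event probability $(k + \tfrac12)/(n + 1)$ for $k$
events in $n$ trials, and a single binary covariate reproduces the
Haldane-corrected log odds ratio
$\log\{(a+\tfrac12)(d+\tfrac12)\} - \log\{(b+\tfrac12)(c+\tfrac12)\}$.

Inference on the treatment coefficient uses a Wald test for the MLE engine
and a **penalized likelihood-ratio test** (PLRT) for the Firth engine:
$2\{\ell^*(\hat\beta) - \ell^*(\tilde\beta)\}$ against $\chi^2_1$, where
$\tilde\beta$ maximizes $\ell^*$ with the tested coefficient held at the
null. Two conventions had to be fixed because reference implementations
differ:

* **Constrained-fit penalty.** The constrained fit maximizes over the free
  coefficients while the penalty continues to use the full-design
  information (the convention of the standard Firth software lineage),
  rather than the information of the reduced design.
* **One-sided PLRT.** One-sided p-values use the signed-root convention:
  half the two-sided p when the estimate falls on the alternative's side of
  the null, one minus half otherwise. This is what noninferiority testing
  on a penalized fit requires, since the PLRT is the only trustworthy test
  under separation.

## Noninferiority

With $\tau_t$ and $\tau_c$ the rural and referral event proportions, the
noninferiority test is one-sided:

$$H_0: \tau_t - \tau_c \ge \delta \quad\text{vs}\quad H_1: \tau_t - \tau_c < \delta.$$

**Margin rule.** The margin is chosen conservatively as *half the margin of
error* of the 95% confidence interval for the difference in proportions: a
difference reported as 0.3% ± 0.1% gives $\delta$ = 0.05%. The symmetric
Wald interval is used deliberately — it is the "±" form in which historical
differences are actually quoted. `margin_from_ci()` computes the half-width
from proportions and arm sizes; `margin_from_moe()` accepts a quoted margin
of error directly.

**Proportion scale.** `test_proportions_ni()` is the one-sided Wald z-test
of the shifted null. At $\delta = 0$ it reduces *exactly* to the one-sided
superiority test (enforced in the tests), and its p-value is nonincreasing
in $\delta$.

**Odds-ratio scale.** For adjusted comparisons the margin must live on the
log-odds scale. The package maps it through the control proportion:

$$\delta_{\mathrm{logOR}} = \log\frac{(\tau_c + \delta)/(1 - \tau_c - \delta)}{\tau_c/(1 - \tau_c)},$$

the log odds ratio produced by lifting the control event proportion by
$\delta$. This mapping is a design decision of this package — one
defensible reading among several, chosen because it is anchored at the
control rate, strictly increasing in $\delta$, and zero iff $\delta = 0$ —
and it is stated prominently in the documentation rather than buried.
`test_or_ni()` then tests $H_0: \beta_{\mathrm{arm}} \ge
\delta_{\mathrm{logOR}}$ with a one-sided Wald test (MLE engine) or the
one-sided PLRT at the shifted null (Firth engine).

The default one-sided level is $\alpha = 0.025$, the clinical-trial
convention; it is configurable, and the power analysis below uses the
conventional two-sided 0.05 on the superiority test instead.

## Risk stratification and E-values

Comorbidity gradings are themselves built from coded diagnoses, so putting
them *in* the outcome model would manufacture outcome-confounder
correlation. The package therefore stratifies instead of adjusting:
`cumulative_strata()` forms the five nested populations with comorbidity
level ≤ 0, ≤ 1, ..., ≤ 4 (the widest stratum is the full cohort), and the
whole analysis is run in parallel across them. `stratum_profile()` reports
per-arm sample statistics and — importantly — per-individual-event
proportions, the transparency view that a combined indicator otherwise
hides.

`e_value()` quantifies robustness to unmeasured confounding: the minimum
risk-ratio-scale association an unmeasured confounder would need with both
arm and outcome to explain an observed odds ratio away,
$E = RR + \sqrt{RR(RR-1)}$ (applied to $1/RR$ when $RR < 1$). Because every
outcome here is rare (< 4%), the odds ratio is treated as a risk ratio by
default; the square-root conversion $RR \approx \sqrt{OR}$ is available
behind `rare_outcome = FALSE` for common outcomes. The CI E-value uses the
confidence limit closer to 1 and equals 1 when the interval crosses the
null.

## The cohort simulator

`simulate_cohort()` draws the data-generating process the power analysis
assumes:

* a **deterministic arm split**, `n_rural = round(rural_fraction * n)` —
  "proportional to relative volumes" read as a fixed split, which removes a
  needless source of Monte Carlo variance;
* per-row Bernoulli events with the arm's event proportion;
* covariates drawn independently per arm from normal or Bernoulli
  specifications, with **no effect on the outcome**. The simulation design
  is deliberately null in the covariates: they reproduce the adjustment
  structure of the real analysis (so the tests pay the degrees-of-freedom
  cost of estimating them) without injecting signal.

The bundled scenarios (`table2_presets()`) fix, for each of the four index
procedures and five cumulative comorbidity strata, the available visit
count, the rural count, and the two arm event proportions. Covariate
*distribution parameters* are not part of the study conditions and are
package defaults chosen to be realistic for each surgical population (e.g.
hernia-repair age 55 ± 16, 25% female, 40% laparoscopic; cesarean age 31 ±
5.5, gravidity 2.4 ± 1.4, 60% emergency; income decile 5.5 ± 2.9
throughout). Because the covariates are null, power is insensitive to these
choices — a property the test suite checks rather than assumes. Two related
choices: the cesarean scenarios omit sex (an all-female population makes it
a constant, rank-deficient column), and gravidity is simulated as a normal
variable (the simulator's covariate families are normal and Bernoulli; a
count distribution would add fidelity the null-covariate design cannot
use). A comorbidity-level column is drawn from a fixed decreasing
distribution over the stratum's range, for use by the stratification
utilities only; it is never a model term.

What the simulator does *not* emulate: within-facility clustering (no
random intercepts — hierarchical extensions are out of scope), covariate
effects on the outcome, coding variation between facilities, or transfers
between them. Passing power and calibration tests on simulated cohorts
therefore validates the statistical machinery under the stated generating
process, not the epidemiology of any particular dataset.

Event derivation from coded visits is the one part of the simulator meant
for real data: `detect_events()` flags an index visit if any same-patient
visit within a day window carries a code in a named set, matched by exact
prefix (ICD-10-CA / CCI style). The window is inclusive on both ends — day
0 and day 30 both count under the default 30-day window, day 31 does not —
and a flag (`include_index_day = FALSE`) starts the window the day after
the procedure for analyses that should not count codes recorded at the
index admission itself. `combine_events()` ORs the indicators into the
combined outcome.

## Monte Carlo power and minimum sample size

`estimate_power()` repeats simulate → fit → test: per replication, a cohort
is simulated, the chosen engine is fit with the scenario's covariates as
adjustment terms, and the treatment coefficient is tested against zero
(two-sided Wald for MLE, two-sided PLRT for Firth) at $\alpha = 0.05$.
Power is the fraction of replications with $p < \alpha$; the binomial Monte
Carlo standard error is always reported. Three engine-room decisions:

* **Paired engines.** Per-replication seeds are drawn once from the root
  seed, so both engines see identical cohorts — engine comparisons are
  paired, not independent.
* **Failed fits.** MLE replications that hit separation count as
  *non-rejections* (and are tallied in `failed_fits`), never discarded:
  discarding exactly the replications where the rural arm ran out of events
  would bias power upward.
* **Default 1000 replications** (MC SE ≤ 0.016), reducible for larger
  scenarios; scaled-down runs stay interpretable because the MC SE travels
  with every estimate.

`min_sample_size()` finds the smallest n on a grid (default 1000-100,000)
with power ≥ 0.8: a geometric 8-point coarse grid brackets the crossing,
bisection narrows it to a resolution of 10. The search assumes power is
monotone in n — true up to Monte Carlo noise whenever the arm proportions
differ — and warns when an evaluation contradicts monotonicity beyond 3
pooled standard errors. When even the grid ceiling falls short, the result
is the explicit sentinel ">100000" rather than a number. Scenario-scale
runs in this package's own checks use 200-500 replications per grid point,
which locates the hernia-repair all-comorbidity minimum (≈ 2800 visits)
to well within the ±25% that replication noise and unknown covariate
parameters warrant.

Two calibration properties anchor the whole engine: under equal arm
proportions the rejection rate matches $\alpha$ (type-I calibration,
checked at 2000 replications), and under the boundary null
$\tau_t = \tau_c + \delta$ the noninferiority test rejects at its one-sided
level — at event counts large enough for the Wald approximation to hold;
at very small expected counts the unpooled z-test is known to be mildly
anticonservative, a limitation inherited from the test, not the
implementation.

## Degenerate inputs and numerical edges

* Scenarios with both event proportions zero simulate event-free cohorts;
  power is reported as 0 with a warning rather than an error.
* Cohorts too small to place a visit in each arm are rejected.
* A zero margin is accepted but announced as collapsing noninferiority into
  superiority; a margin that would lift the control proportion to 1 is
  rejected.
* Constant and linearly dependent design columns are errors that name the
  offending columns; an all-one-class outcome is an error for the MLE
  engine (unbounded likelihood) and a finite fit for Firth.
* The penalized LRT statistic is clipped at zero against roundoff; working
  weights are floored at `1e-300` inside Cholesky factorization to keep
  extreme linear predictors from producing NaN.

## Limitations

The package powers the *superiority* comparison (as the study design it
reproduces did), not the noninferiority tests themselves. It fits no
hierarchical models, computes no profile-penalized confidence intervals
(Wald intervals only), implements no score-type noninferiority variants
(Farrington-Manning would be the natural extension), and ships no
adverse-event code lists — event definitions are the user's, supplied as
YAML/JSON code sets. Comorbidity level is consumed as a column, never
derived from raw codes: the grouping methodology that assigns it is
proprietary to its custodian.
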