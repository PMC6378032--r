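---
title: "The cascade model behind adcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cascade model behind adcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcascade)
```

## The model

`adcascade` implements the dynamic biomarker cascade hypothesis of
Alzheimer's disease as a causal, mechanistic model: five normalized
biomarker levels evolve as coupled nonlinear first-order ODEs over the
lifespan (ages 0--100 years). The states are amyloid pathology
$A_\beta$, amyloid-related phospho-tau $\tau_p$, aging/SNAP-related tau
$\tau_o$, neurodegeneration $N$, and cognitive impairment $C$; total tau
is the derived sum $\tau = \tau_p + \tau_o$. The equations are

$$
\begin{aligned}
\dot A_\beta &= \lambda_{A\beta}\,A_\beta\,(K_{A\beta}-A_\beta)
  + \lambda_{A\beta A_o}A_o - \delta_{A\beta}\,A_{Rx}(t),\\
\dot\tau_p &= \lambda_{\tau_p A\beta}\,A_\beta
  + \lambda_{\tau_p}\,\tau_p\,(K_{\tau_p}-\tau_p),\\
\dot\tau_o &= \lambda_{\tau_o AS}\,AS,\\
\dot N &= \lambda_{N\tau_o}(\tau-\tau_p) + \lambda_{N\tau_p}\tau_p
  + \lambda_N\,N\,(K_N-N) + \lambda_{NAS}AS,\\
\dot C &= \lambda_{CN}\,N\,R + \lambda_C\,C\,(K_C-C)
  + \lambda_{CAS}AS + \lambda_{C\varepsilon}\varepsilon .
\end{aligned}
$$

Each cascade has a logistic self-amplification term, which produces the
sigmoidal shape the hypothesis postulates, and linear cross terms that set
when a downstream cascade is ignited by its upstream drivers. The host
factors -- amyloidopathy $A_o$, aging/SNAP burden $AS$, ApoE genetic risk
$\varepsilon$, and cognitive reserve $R$ -- are constants over the age
span. All rates are per year; levels are dimensionless with 1 the maximal
(fully abnormal) level.

Only $\tau_p$ and $\tau_o$ are integrated; total tau is derived. The
published tau equation is algebraically the sum of the $\tau_p$ and
$\tau_o$ equations, so integrating total tau as a third tau state would be
redundant and invite drift. A unit test asserts the sum identity at
machine precision.

Two points in the printed equations are genuinely ambiguous, and the
package takes a documented stance on each:

* **Cognitive reserve enters multiplicatively**, as
  $\lambda_{CN} N R$. The published parameter table assigns $R = 1$ to the
  low-risk and $R = 25$ to the high-risk group, and the published
  trajectory figures show the high-risk group declining *earlier*; a
  multiplicative $R$ reproduces that, a divisive one would invert it. With
  this reading "reserve" is effectively a vulnerability multiplier; the
  protective quantity is $1/R$.
* **The therapy withdrawal term is a constant sink**,
  $-\delta_{A\beta} A_{Rx}(t)$, exactly as printed
  (`degradation_form = "literal"`). A state-proportional alternative
  $-\delta_{A\beta} A_\beta A_{Rx}(t)$ is exposed as
  `degradation_form = "proportional"`. The literal form lets therapy
  drive amyloid all the way to zero (hence the nonnegativity floor below)
  and produces the larger amyloid decline; the proportional form stalls at
  the equilibrium $K - \delta/\lambda$ and reduces tau slightly more
  gently. The literal form is the default because it is what the equation
  says and because it yields the marked amyloid drop the therapy scenario
  describes.

Anti-amyloid therapy is a Heaviside step input with the half-maximum
convention ($H(0)=\tfrac12$), switched on at the onset age and maintained
for life. The half-maximum value only matters on a measure-zero time
point: the integrator splits the time span at the onset age, so each
segment sees a constant input and the convention never influences a
trajectory. It is implemented and tested for fidelity nonetheless.

## Scenario presets

Four presets reproduce the published parameter table:
`early_onset` (autosomal dominant AD, $A_{\beta 0}=0.05$,
$\lambda_{A\beta}=0.08$, no comorbidity), `late_amyloid_first`
($A_{\beta 0}=0.01$, $\lambda_{A\beta}=0.12$, $AS=1$, $\tau_{o0}=0.05$),
`late_tau_first` ($\lambda_{A\beta}=0.1$, $AS=2$), and
`late_amyloid_first_rx` (the amyloid-first scenario plus
$\delta_{A\beta}=0.04$ with therapy onset at age 65). Shared values:
all carrying capacities 1, $R_1=1$, $R_2=25$, and the cross-rate constants
listed in `ad_preset()`. A table-driven test pins every cell.

The published table lists all $K=1$ even though the construction narrative
says $K$ is adjusted by least squares; it does not say whether the printed
values are pre- or post-calibration. The presets therefore carry the
literal $K=1$, and calibration is an explicit separate step
(`calibrate_capacities()`), never applied silently.

## Calibration

`calibrate_capacities()` adjusts $K_{A\beta}, K_{\tau_p}, K_N, K_C$ by
bounded Levenberg--Marquardt least squares so that amyloid, total tau,
neurodegeneration, and cognition all reach level 1 at age 100. Choices:

* Targets are the four capacity-bearing observables; $\tau_o$ has no
  capacity (its growth is linear) and is captured through total tau.
* The cognition target uses the **high-risk** reserve curve: it is the one
  that saturates within the modeled horizon, and therefore the one the
  target can pin; the low-risk curve may never reach 1 by age 100.
* The starting point is the published $K=1$ and the search is bounded to
  $[0.1, 10]$ per capacity, which rules out degenerate dynamics while
  leaving the optimum comfortably interior.
* For a therapy scenario, capacities are fitted with $\delta_{A\beta}$
  forced to zero (natural history) and then frozen before the degradation
  term is restored, so the pre-therapy course is unaffected by the later
  intervention.

The objective has a triangular structure (amyloid feeds tau feeds
neurodegeneration feeds cognition, never backwards), which makes the
four-parameter fit well conditioned; on the presets it converges to a
near-zero residual in a few dozen objective evaluations.

## Numerical integration

The system is small and non-stiff. It is integrated with `deSolve`'s
adaptive `lsoda` at relative tolerance `1e-8` and absolute tolerance
`1e-10` -- several orders below any quantity interpreted scientifically --
and sampled on the output grid (default step 0.1 years). Unit tests hold
each decoupled logistic cascade to the closed-form solution
$K/(1+\frac{K-x_0}{x_0}e^{-\lambda K t})$ within `1e-6` at every grid
point, and halving the tolerances moves no output by more than `1e-6`.

Two non-smooth features are handled structurally rather than through the
step-size controller:

* **The therapy step.** Integration is split at the onset age; the
  right-hand side seen by the solver is smooth on each segment.
* **The nonnegativity floor.** With the literal constant-sink withdrawal,
  amyloid would cross zero and keep falling. The right-hand side is
  therefore evaluated on the zero-floored state, and a component sitting
  at or below zero with an inward-pointing derivative is frozen; output
  levels are additionally clamped at zero. (An alternative
  clamp-and-restart scheme was considered and rejected: once amyloid is
  exhausted the sink keeps pointing inward, so restarts re-trigger at
  every step and the integration never terminates.)

States may transiently exceed their carrying capacity where additive
forcing pushes them past it; no upper clamp is applied, since saturation
at 1 is the calibration target at age 100, not a hard constraint.

## Onset detection and therapy metrics

A biomarker's onset age is the first age its level crosses the clinical
detection threshold, 0.15 by default, linearly interpolated between the
bracketing grid points (with a 0.1-year grid the interpolation error is
negligible). Biomarkers that never reach threshold are reported as absent.
Orderings break exact ties (within `1e-9` years) in the canonical cascade
direction amyloid, tau, neurodegeneration, cognition. The separate 0.05
"minimal level on the graphs" is a display floor applied only by the
plot method; it never enters the dynamics or the onset logic.

`therapy_effect()` reduces a treated-vs-untreated pair to four outcomes:
the shift in cognitive onset age, the change in the post-onset slope of
cognitive decline (least-squares slope over a 10-year window after onset;
the window length is configurable because the underlying notion of "slope
of decline" is not quantified more precisely than that), the fractional
drop of amyloid from its treated-run peak, and the total-tau reduction at
the end age. On the published therapy scenario the cognitive metrics are
exactly null -- symptom onset precedes therapy onset, so the onset and its
slope window lie entirely in the shared pre-therapy segment -- which is
the model's account of why anti-amyloid therapy given after symptom onset
fails.

## Synthetic observations and parameter recovery

`generate_observations()` samples the model's own trajectories on a fixed
age grid and adds independent Gaussian noise (truncated at zero, since
levels are nonnegative), seeded and reproducible. This emulates the
longitudinal biomarker tables a cohort study would provide: repeated
normalized measurements at known ages. It deliberately does *not* emulate
real-data features such as per-subject random effects, irregular visit
schedules, assay-specific noise scales, censoring, or cohort heterogeneity
-- so passing recovery tests demonstrates identifiability of the
machinery, not readiness for clinical data.

`fit_parameters()` recovers named free parameters by bounded
Levenberg--Marquardt least squares against such observations. Default
bounds are wide but physical (rates in $[0,1]$ per year, capacities in
$[0.1,10]$, initial levels in $[0,1]$). Small subsets observed through
their own cascade are well identified -- the amyloid growth rate alone is
recovered essentially exactly from noiseless amyloid samples, and the
pair (growth rate, initial level) to well within 20% from 21 noisy
samples at noise SD 0.02 -- whereas freeing many rates against a
single biomarker is typically unidentifiable; the fit then returns a
boundary or flat solution with `converged = FALSE` left to the caller to
interpret. Bayesian inversion with full posteriors is out of scope here.

## Problem sizes

The default grid (1001 output points over 100 years) integrates in well
under a second; calibration needs a few dozen sparse-output simulations
and finishes in under a second per scenario; the recovery studies in the
test suite use 21 observation ages and at most a few dozen refits. The
entire test suite runs in seconds on one core.

## Known limitations

* The model abstracts biomarkers interacting with each other; it contains
  no molecular, cellular, spatial, or network-level mechanism.
* Host factors are constant for life; there is no age-dependent comorbidity
  accrual and no feedback from cognition to biology.
* The two ambiguous readings above (reserve placement, withdrawal form)
  are choices, not facts; both switches are exposed so the alternatives
  can be simulated.
* Published trajectory figures for this model are schematic; quantitative
  agreement is asserted only against the model's own closed forms and
  stated thresholds, and scenario-level checks are ordering properties,
  not numeric curve matches.

```{r example, fig.width = 7, fig.height = 4.5}
pair <- simulate_risk_pair(ad_preset("early_onset"))
plot(pair, main = "Early-onset cascade")
detect_onset(pair)
```
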