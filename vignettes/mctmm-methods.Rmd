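---
title: "Dose-toxicity modelling of ordered adverse-event grades with a minimal continuous-time Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-toxicity modelling of ordered adverse-event grades with a minimal continuous-time Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mctmm)
```

## The problem

Hand-foot syndrome (HFS, palmar-plantar erythrodysesthesia) is a
dose-dependent skin toxicity of oral capecitabine. Patients grade its
severity themselves on an ordinal CTCAE-style scale (0 = asymptomatic to
3 = severe, with impaired daily activities), once per 3-week treatment
cycle, for up to six cycles. The questions a dose-toxicity model must
answer are longitudinal: how quickly does severity build up and resolve,
how strongly does the daily dose drive it, how much do patients differ,
and what would label-style grade-driven dose reductions change?

Ordinary ordinal regression ignores the strong serial dependence of
within-patient grades. This package models the grades as a
**minimal continuous-time Markov model (mCTMM)**: a four-state
continuous-time Markov chain over grades 0--3 in which

* only adjacent grades communicate directly (single-step worsening and
  recovery),
* the stationary distribution of the chain is a **proportional-odds
  model**, and
* all transition rates share one time-scale parameter, the **mean
  equilibration time (MET)**.

## The model

### Stationary distribution (proportional odds)

For subject $i$ at occasion $j$, the cumulative probabilities of being at
grade $n$ or above satisfy

$$\mathrm{logit}\, P(Y_{ij} \ge n) = \alpha_n + g(x_{ij}) + \eta_i^{(\alpha)},
\qquad n = 1, 2, 3,$$

with ordered intercepts enforced through strictly negative increments,
$\alpha_{n+1} = \alpha_n + b_{n+1}$, $b_{n+1} < 0$. In the final
dose-toxicity model the covariate term is a linear effect of the absolute
daily dose, centered at the population median:

$$g(x_{ij}) = \theta_{\mathrm{Dose}} \cdot (\mathrm{Dose}_{ij} - 3000\,\mathrm{mg}).$$

Grade probabilities follow by differencing inverse logits. The shared
random intercept $\eta_i^{(\alpha)} \sim N(0, \omega_\alpha^2)$ shifts all
three cumulative logits identically (one $\eta$, as in a standard
proportional-odds mixed model); because the terms are additive, it is
immaterial whether it is added before or after covariate centering.

### Kinetics

Between observations the state probabilities $P(0), \dots, P(3)$ evolve by
the usual compartment equations of a birth-death chain with adjacent-state
rate constants. The mCTMM ties every rate to the stationary target
$\pi = (\pi_0,\dots,\pi_3)$ (the proportional-odds distribution at the
current dose) and the single time-scale MET:

$$K_{i \to j} \;=\; \frac{\pi_j}{\mathrm{MET}_i \,(\pi_i + \pi_j)},
\qquad |i - j| = 1, \qquad \mathrm{MET}_i = \mathrm{MET}\cdot e^{\eta_i^{(m)}},$$

with $\eta_i^{(m)} \sim N(0, \omega_m^2)$. Two properties motivate the
pairwise normalization by $\pi_i + \pi_j$:

1. **Detailed balance**, $\pi_i K_{i\to j} = \pi_j K_{j \to i}$, holds
   exactly, so the proportional-odds distribution is the stationary
   distribution of the chain by construction.
2. Each adjacent pair of states, taken in isolation, relaxes with time
   constant exactly MET ($K_{i\to j} + K_{j \to i} = 1/\mathrm{MET}$),
   which is what makes "mean equilibration time" a meaningful name and
   keeps MET identifiable on the cycle time scale.

An unnormalized variant ($K_{i\to j} = \pi_j/\mathrm{MET}$) also satisfies
detailed balance, but its escape rate from a state is gated by the
*destination's* stationary probability: a patient whose equilibrium sits at
grade 3 would leave grade 0 at a rate proportional to the (tiny)
intermediate-grade probability and effectively never progress within six
cycles. Under that variant the dose-adjustment simulation below degenerates
(virtually no sustained grade 2--3 episodes), while under the normalized
rates the simulated transition structure closely mirrors observed HFS
cohorts; the package therefore uses the normalized form throughout. Note
that MET is only interpretable jointly with this normalization convention.

Propagation over an interval is the matrix exponential of the (4x4,
piecewise-constant-dose) generator; the test suite cross-checks it against
a high-accuracy ODE integration (`deSolve`, tolerance 1e-10). Dose is
piecewise constant per cycle: within-cycle dose changes and
treatment-interruption timing are outside the model's resolution, because
only one (maximum) grade per cycle is reported.

### Observation model and likelihood

Patients are asymptomatic at baseline, so each trajectory starts as the
grade-0 indicator. When a grade is observed, the probability state is reset
to the indicator of that grade (the Markov property); a subject's
conditional likelihood is the product over consecutive observations of the
corresponding transition-matrix entries, with skipped questionnaires
handled by propagating piecewise over the per-cycle dose sequence (no
imputation). Subjects observed only at baseline carry no information and
are dropped with a message.

## Estimation

The marginal likelihood integrates the two independent random effects out
of each subject's conditional likelihood. The estimation method is the
**Laplace approximation**: an inner Newton optimization (finite-difference
gradient and Hessian, gradient tolerance 1e-8, started at $\eta = 0$ on
every outer iteration for reproducibility) locates the per-subject mode of
the penalised deviance, and the curvature there supplies the Gaussian
correction. **Adaptive Gauss--Hermite quadrature** (default 21 nodes per
dimension, nodes centered at the mode and scaled by the inverse square-root
curvature) is implemented as the slower, higher-accuracy cross-check; on a
20-subject cohort the two objective functions agree to a fraction of a
point per subject, with the residual gap reflecting the skewness of the
integrand rather than implementation error (the quadrature itself matches
brute-force integration to six decimals in the tests).

The objective function value is OFV $= -2 \log$ (marginal likelihood),
minimized by `nlminb` over a transformed parameter space:
$\log(-b_2), \log(-b_3), \log \mathrm{MET}, \log \omega$, with continuous
covariate columns rescaled to unit order (dose in grams, age in decades).
Because the inner optimization leaves ~1e-6 of roughness in the OFV, the
outer optimizer is fed an explicit central-difference gradient with step
1e-4 -- well above the noise floor -- instead of its default
machine-epsilon-scaled steps. Standard errors come from the
finite-difference Hessian of the OFV at the optimum,
$\widehat{\mathrm{cov}} = 2 H^{-1}$ on the transformed scale, delta-mapped
to natural units; the convention is recorded in the fit object.

Nested models are compared by the likelihood-ratio test; one added
parameter must drop the OFV by at least 6.64 ($p \le 0.01$, $\chi^2_1$).
The univariate covariate screen (`covariate_screen()`) applies that rule to
sex, dose, mono/combination therapy, tumor-entity indicators, age, the
three-level adherence group (2 df) and cycle time, each on the logit
intercepts and on MET.

Parameter uncertainty is assessed by a non-parametric bootstrap: subjects
resampled with replacement to the original cohort size, each replicate
refit from the original estimates, percentile 2.5/50/97.5 summaries, failed
replicates counted and excluded (a hard warning above 20%).

### Known estimation limitations

The intercept random-effect SD $\omega_\alpha$ is weakly identified by
design: all patients start at grade 0, at most six occasions follow, and
extreme intercept shifts push the stationary distribution toward the scale
ends where one-cycle transitions carry little information about it. In
simulate-and-refit experiments $\omega_\alpha$ is often estimated far below
its generating value with very large uncertainty, dragging $\alpha_1$
somewhat below truth through the usual attenuation coupling -- the same
phenomenon the original analysis reported as an implausibly large relative
standard error on this parameter. MET, the dose slope and $\omega_m$ are
recovered without systematic distortion. Exact-likelihood (quadrature)
refits show the same pattern, so this is an information limit of the
design, not a defect of the Laplace approximation.

## The synthetic cohort generator

Because the clinical dataset is not deposited, `generate_design()` draws
virtual cohorts matching the published design margins: 150 patients; daily
dose from {1000, 1500, ..., 5000} mg weighted to median 3000 (combination
patients from the lower half); 39/101 male/female; entities 71/67/12; 71 on
monotherapy; planned questionnaire occasions weighted so the realized mean
is about 5 cycles; 56 discontinuations (dose set to 0 afterwards), 25 of
which keep returning questionnaires; a 3% missing-questionnaire rate; about
15% of patients get one 500-mg dose reduction. Adherence-group proportions
(0.25/0.55/0.20 for >100%, 90--100%, <90%) are an assumption -- the source
tables give none -- and adherence, age, sex and entity exert *no* effect
under the final model, existing purely so the covariate screen can be
exercised against known-null effects. `generate_cohort()` then simulates
grades from the mCTMM. What the generator does **not** emulate: treatment
interruptions in time (the model has no within-cycle axis), dose rounding
to tablet strengths in the observed data, any misreporting of grades
(observed = true grade), and any dose-choice feedback from toxicity to the
oncologist. Passing tests on these cohorts therefore demonstrate
self-consistency of the machinery under the study design, not fidelity to
unmodelled features of real data.

## The dose-adjustment simulation

`run_scenario()` simulates 1000 virtual patients for six cycles from a
starting daily dose of $2 \times 1250\,\mathrm{mg/m^2} \times$ BSA, with
BSA drawn from a truncated normal (assumed mean 1.8 m^2, SD 0.2 m^2, range
1.2--2.6 m^2; the source publication's BSA moments are not printed, so
simulated transition counts are comparable only directionally). Two
matched arms share all random draws: one without adjustments, one applying
a label-style rule after each conducted cycle (grade $\le 1$ maintains;
grade 2 occurrences keep 100%/75%/50% of the *starting* dose and the fourth
recommends discontinuation; grade 3: 75%/50%, then discontinuation).
Recommended-discontinuation patients are retained at their last dose so
both arms keep the same n; doses never re-escalate. Probability states
propagate continuously across cycles (the default `reset = "none"`): the
modal grade -- argmax of the propagated distribution, ties broken toward
the lower grade -- is used only to assess toxicity and drive the rule. The
alternative `reset = "modal"`, which restarts each cycle from the previous
modal-grade indicator, is available but collapses both arms onto nearly
identical, low-toxicity trajectories and is therefore not the default.
Per-cycle summaries report the across-patient median probability of each
grade with an order-statistic (binomial-rank) 95% confidence interval for
the median, plus the 4x4 modal-grade transition-count table over the five
cycle-to-cycle steps.

## Individual prediction

`prediction_table()` walks every patient forward: for a target cycle $c \ge
2$, the random effects are estimated by empirical Bayes (MAP: maximizing
$\log L_i(\eta) + \log \phi(\eta;\Omega)$ with population parameters fixed)
from the observations before $c$, and the grade distribution at $c$ is
propagated from the last observed grade at the known doses; the modal grade
is the prediction. Baseline rows are excluded (they are deterministic).
"Bayesian estimation" is implemented as the posterior mode, the standard
pharmacometric reading; the prediction is the single propagated
distribution rather than an average over simulation replicates -- both give
the same modal grade in expectation and the deterministic version is
reproducible. PPV is the fraction of predicted grade $\ge 2$ events that
were observed $\ge 2$; NPV the fraction of predicted $\le 1$ events
observed $\le 1$; empty denominators yield missing values. Values are
reported per cycle *and* pooled, labelled, since pooling conventions
differ.

## Numerical choices

* Grade probabilities are floored at 1e-12 (and renormalized) before rate
  construction, keeping the generator finite at saturated logits.
* Transition probabilities are floored at 1e-300 inside the log-likelihood.
* 4x4 matrix exponentials use scaling-and-squaring (Armadillo `expmat`);
  zero elapsed time returns the identity exactly.
* Inner Newton: ridge on a non-positive-definite Hessian, step-norm cap 5,
  backtracking line search, at most 100 iterations.
* Outer optimizer bounds (transformed scale) keep MET in [1e-3, 50] cycles
  and the omegas in [1e-4, 20].
* Modal-grade ties break toward the lower grade (conservative, and
  measure-zero in practice).
* The median's 95% CI uses binomial order-statistic ranks, not bootstrap.
* All simulation entry points take explicit seeds; a fixed seed reproduces
  byte-identical outputs.

## Problem sizes in the test suite

The default suite exercises the full 150-patient design for single fits,
the VPC (1000 replicates) and the paired 1000-patient policy scenarios; the
bootstrap machinery runs at 20 replicates on a 100-subject cohort, and the
no-IIV consistency fit uses 250 subjects. The `analysis/` scripts run the
same stages at the full published scale (e.g. 50+ bootstrap replicates),
and `scripts/acceptance.R` re-runs the headline simulate-and-refit
experiment end to end.
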