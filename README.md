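# mctmm

Dose–toxicity modelling of longitudinal **ordered adverse-event grades** with
a **minimal continuous-time Markov model (mCTMM)**, built around the
motivating case of patient-reported hand–foot syndrome (HFS) under oral
capecitabine: 150 patients grade their skin toxicity (0–3, CTCAE-style
descriptions) once per 3-week cycle for up to six cycles, doses change
between cycles, and the question is how strongly the daily dose drives
severity and what grade-driven dose reductions would change.

The package is aimed at pharmacometricians and biostatisticians who want a
self-contained, NONMEM-free implementation of this model class: estimation,
model development, evaluation and simulation all run from R.

## The model

Grades follow a four-state continuous-time Markov chain in which only
adjacent grades communicate. Its stationary distribution is a
proportional-odds model on the logit scale,

```
logit P(Y_ij >= n) = alpha_n + theta_Dose (Dose_ij - 3000 mg) + eta_i,   n = 1..3,
alpha_{n+1} = alpha_n + b_{n+1},  b_{n+1} < 0,   eta_i ~ N(0, omega_alpha^2),
```

and all adjacent transition rates share a single time scale, the mean
equilibration time (MET, in cycles, with a log-normal random effect):

```
K(i -> j) = pi_j / (MET_i * (pi_i + pi_j)),   |i - j| = 1,
```

where `pi` is the proportional-odds distribution at the current dose. The
construction satisfies detailed balance, so `pi` is exactly the stationary
distribution, and each adjacent pair of states relaxes with time constant
MET. Between questionnaires the state probabilities evolve by the matrix
exponential of this generator (piecewise-constant dose); at each observation
the state is reset to the observed grade (the Markov property). Random
effects are integrated out by a Laplace approximation (adaptive
Gauss–Hermite quadrature as cross-check), and nested models are compared by
likelihood-ratio tests (ΔOFV ≥ 6.64 for one parameter, p ≤ 0.01).

See `vignettes/mctmm-methods.Rmd` for the full methods account.

## Worked example

The clinical dataset is not publicly deposited, so the package ships a
synthetic-cohort generator that reproduces the published design margins
(dose median 3000 mg over 1000–5000, 39 M / 101 F, 71/67/12 tumor entities,
56 discontinuations, ~5 questionnaires per patient) and simulates grades
from the model at the reference estimates:

```r
library(mctmm)

cohort <- generate_cohort(cohort_design(), default_params(), seed = 1)
fit <- mctmm_fit(cohort)                     # Laplace marginal ML, ~2 min
print(fit)
#> mCTMM fit (laplace marginal likelihood)
#>   subjects: 150   observations: 763
#>   OFV: 1553.1023  converged: TRUE
#>
#>    parameter   estimate       se rse_pct
#>       alpha1  1.6850000 0.212000   12.60
#>           b2 -1.7890000 0.159000    8.90
#>           b3 -1.9380000 0.211000   10.90
#>          met  0.9022000 0.083600    9.27
#>   theta_dose  0.0007234 0.000189   26.10
#>  omega_alpha  1.0150000 0.215000   21.20
#>    omega_met  0.4541000 0.120000   26.30
```

The recovered values sit close to the generating ones (`default_params()`:
alpha1 1.81, b2 −1.80, b3 −2.08, MET 1.09 cycles, theta_dose 8.33e-4 per mg,
omega_alpha 1.12, omega_met 0.542): e.g. the typical patient's stationary
probability of any HFS at 3000 mg/day is `expit(1.685) ≈ 0.84`, and 1000 mg
more of daily dose
shifts every cumulative logit up by ~0.72.

The dose effect is confirmed by the likelihood-ratio test against the base
model, the model describes its own data (categorical VPC), and label-style
dose adjustments curb sustained grade-3 toxicity in 1000 matched virtual
patients dosed at 1250 mg/m² twice daily:

```r
base <- mctmm_fit(cohort, spec = mctmm_covspec(), se = FALSE)
likelihood_ratio_test(base, fit, df = 1)
#> LRT: dOFV = -15.203 (df = 1), p = 9.654e-05 -> significant at p <= 0.01

vpc <- categorical_vpc(cohort, fit$params, coefs = fit$coefs,
                       n_sim = 1000, seed = 2)
mean(vpc$observed_prop >= vpc$lo95 & vpc$observed_prop <= vpc$hi95)
#> [1] 0.96   # fraction of cycle x grade bins inside the 95% band

s_no <- run_scenario(1000, 6, fit$params, rule = NULL,        seed = 3)
s_ad <- run_scenario(1000, 6, fit$params, rule = smpc_rule(), seed = 3)
c(s_no$transitions[4, 4], s_ad$transitions[4, 4])
#> [1] 493  88   # grade 3 -> 3 transitions without vs with dose adjustments
```

The numbered scripts under `analysis/` run the complete workflow at full
scale (cohort simulation, base/final fits, the univariate covariate screen,
bootstrap, VPC, the paired dose-policy study, and per-cycle PPV/NPV of
individual predictions), writing tidy CSVs under `results/`.

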