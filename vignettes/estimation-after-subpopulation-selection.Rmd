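---
title: "Conditionally unbiased estimation after subpopulation selection in adaptive seamless trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditionally unbiased estimation after subpopulation selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdest)
```

## The design and its estimation problem

A two-stage adaptive seamless design (ASD) with subpopulation selection
recruits `n1` patients in stage 1 from the full population F, of whom a
proportion `p_S` belong to a pre-specified subpopulation S (defined, say, by
a biomarker or baseline severity) and the rest to its complement S^c.
Randomization is stratified 1:1 within each stratum and the outcome is normal
with known common standard deviation `sigma`, so a stratum contributing `m`
patients yields a mean treatment difference with variance `4 sigma^2 / m`.
At the interim, the trial continues with S when the observed effect in S
exceeds the pooled effect by more than a margin `b` —
`x > z + b`, equivalently `x > y + b/(1 - p_S)` — and with F otherwise
(equality goes to F). Stage 2 recruits `n2` further patients from the
selected population, and the final estimate pools both stages.

Because the same stage-1 data drive both the selection and the estimate, the
pooled two-stage mean (the *naive* estimator) is biased *conditional on the
selection made*: conditioning on `X > Y + b/(1-p_S)` tilts the distribution
of `X` upwards, so the naive estimate for S is optimistic when S is selected
and pessimistic when F is selected. The estimand itself is branch-dependent:
`theta_S` after selecting S, `theta_F = p_S theta_S + (1-p_S) theta_Sc`
after selecting F.

## Exact conditional bias of the naive estimators

With `t_S = S_X/(S_X + n2)` the stage-1 fraction of S-patients, the
conditional bias of `D_S,N` given selection of S is
`t_S (E[X 1(X > Y*)]/Pr(X > Y*) - theta_S)` with `Y* = Y + b/(1-p_S)`; the
probability and restricted moment are one-dimensional integrals of a normal
density times a normal distribution function, which `prob_select_s()` and
`trunc_moment_x_select_s()` evaluate by adaptive quadrature (absolute
tolerance `1e-10`). The complementary moment is available exactly as
`E[X 1(X <= Y*)] = theta_S - E[X 1(X > Y*)]` and is cross-checked against
direct quadrature of the complementary integrand in the test suite.

Two structural facts, both verified to quadrature accuracy by
`bias_components_f()`: the prevalence-weighted component biases cancel,
`p_S Bias(D_S,N^F) = -(1-p_S) Bias(D_Sc,N^F)`, so the combined
full-population naive estimator `D_F,N` is conditionally *unbiased* under
proportional allocation; and the bias depends on the effects only through
`theta_S - theta_Sc`, with a non-zero margin shifting every curve by
`b/(1-p_S)` (so the bias of the branch-combined naive estimator peaks at
`theta_S = theta_Sc + b/(1-p_S)`).

### Numerical choices

`stats::integrate` transforms infinite ranges around the origin, so
integrands centered far from zero can be missed entirely; the quadrature
helper therefore shifts coordinates so the normal density is centered before
integrating, and falls back to a finite window of ±10 combined standard
deviations if the adaptive pass does not converge. Conditional bias is
reported as an *error*, not zero, when the conditioning probability
underflows (below `1e-12`), since the conditional quantity is then
numerically undefined.

## Rao–Blackwell conditionally unbiased estimators

Conditional on selecting S, the stage-2 mean `U` is unbiased for `theta_S`,
and `(Y, Z_S)` with `Z_S = (tau_U/sigma_X) X + (sigma_X/tau_U) U` is complete
and sufficient; the UMVUE is the conditional expectation `E[U | Y, Z_S, X >
Y*]`, which has the closed form

    D_S,U = D_S,N - tau_U^2 / sqrt(sigma_X^2 + tau_U^2) * phi(f_U)/Phi(f_U),
    f_U   = sqrt(sigma_X^2 + tau_U^2)/sigma_X^2 * (D_S,N - Y - b/(1 - S_X/n1)),

and analogously `D_S,U^F` (corrected upward) and `D_Sc,U^F` (downward) when F
is selected, combined as `D_F,U = p D_S,U^F + (1-p) D_Sc,U^F`. All
f-arguments use the observed fraction `S_X/n1` in the margin term, so a
single code path serves the known-prevalence case (where `S_X = p_S n1`
exactly) and the unknown-prevalence case (binomial `S_X`); the two modes
coincide identically at proportional counts, a property the tests assert.
With unknown prevalence the *unbiased* combination uses `p_hat = s_X/n1`
(each component is conditionally unbiased given `S_X`, and
`E[p_hat D_S,U^F] = p_S theta_S` by iterated expectation), while the *naive*
combination uses the pooled `p_hat* = (s_X + s_V)/(n1 + n2)`.

Rather than trusting the closed forms, the package carries brute-force
oracles (`rb_oracle_selected_s()`, `rb_oracle_selected_f()`) that recompute
the defining conditional expectations by one-dimensional quadrature over the
stage-2 mean, expressing the selection constraint through the sufficient
statistic. The tests require agreement to `1e-8` on a grid of observed
values and — the operational meaning of sufficiency — invariance of the
oracle to the probe mean placed in its integrand.

### Mills-ratio stability

`phi(f)/Phi(f)` is computed as `exp(dnorm(f, log = TRUE) - pnorm(f, log.p =
TRUE))`. The naive quotient underflows to `0/0` for `f` below about −38;
the log-scale form is accurate for arbitrarily negative arguments (it
approaches `-f` asymptotically), which matters because extreme selection
margins or futility bounds push the f-arguments far into the tail.

## Futility rule

A bound `B` stops the trial when `max(x, z) < B`. Conditional on
continuation, the truncation regions change: when S is selected the
threshold inside `f_U` becomes `max(B, Y + b/(1-p_S))`; when F is selected
the S-component becomes doubly truncated,

    D_S,U^F = D_S,N^F + tau_V^2/sqrt(sigma_X^2 + tau_V^2)
              * (phi(f_V) - phi(f_V^B)) / (Phi(f_V) - Phi(f_V^B)),

with `f_V^B` built from the lower threshold `(B - (1-p_S) Y)/p_S`, and the
`f_W` threshold becomes `max(X - b/(1-p_S), (B - p_S X)/(1-p_S))`. The sign
convention above is fixed by two independent requirements that the package
tests enforce: the expression must reduce to the plain Rao–Blackwell form as
`B -> -Inf`, and it must agree with the quadrature oracle over the doubly
truncated region. An empty truncation interval (observed data outside the
continuation region) raises an error rather than returning a 0/0. Futility
variants are implemented for known prevalence only — the unknown-prevalence
case is rejected as unsupported — and under a futility rule no claim of
unbiasedness is made for either full-population combination: the estimate
set carries an explicit warning flag instead.

## The Monte Carlo engine and what it emulates

`simulate_trials()` draws trials at the summary-statistic level — the five
stratum mean differences directly from their sampling distributions — which
is distributionally identical to, and much faster than, patient-level
simulation; `generate_patient_data()` provides the patient-level path (one
normal outcome per patient, stratified 1:1 arms) for validation, and
summarizing it reproduces the summary model exactly. In unknown-prevalence
mode the stage counts are binomial; draws that would empty a stratum (and so
leave a stratum variance undefined) are resampled and counted, making the
conditioning on a valid trial explicit. At the default study sizes
(`n = 200` per stage, prevalence 0.3–0.7) such draws are vanishingly rare,
so resampling cannot distort the reported moments measurably.

`run_mc_study()` reports, per selection branch and estimator, the
conditional mean, bias, MSE and `sqrt(MSE)/SE`, each with its Monte Carlo
standard error; branches never selected are reported as absent rather than
zero. All simulation-based test tolerances are stated in multiples of the
Monte Carlo standard error, never as absolute numbers, so reduced-replication
runs remain valid tests. Reproducibility is by a single root seed with draws
in a fixed order (stage-1 vectors, then branch-wise stage-2 vectors):
identical seed and configuration give bitwise-identical results.

Two standard-error normalizers are exposed for the S-branch. The default,
`sqrt(4 sigma^2/(p_S n1 + n2))`, is the exact variance of the pooled
two-stage mean difference in S; an alternative reading,
`sqrt(4 sigma^2/(p_S (n1 + n2)))`, divides the S-variance across the whole
trial. The default is used because it is the variance the pooled estimator
actually has, and it reproduces the standardized null bias of 0.32 that the
analytic study computes. The F-branch always uses
`sqrt(4 sigma^2/(n1 + n2))`.

### Study sizes used in the checks

The acceptance-level Monte Carlo checks run at 200,000 replications per
configuration with a fixed seed — large enough that the qualitative MSE
ordering (`MSE(D_S,U) > MSE(D_S,N)` at equal effects, the unbiased
combination paying an MSE premium over `D_F,N`, estimated prevalence costing
a small MSE increment when the effects differ) is resolved at several Monte
Carlo standard errors, while keeping the full suite in the low minutes.
Property tests use 20,000–100,000 replications. The analytic-bias
spot-checks are quadrature-based and effectively instantaneous.

## What the synthetic data do and do not show

The generator emulates the model under which the estimators are derived:
independent normal stratum mean differences with known variance, exact 1:1
stratified allocation, a pre-specified selection rule, and fixed stage-2
sample sizes. Passing tests therefore demonstrate internal correctness of
the formulas and their numerics, not robustness to violations real trials
can exhibit: unknown or non-constant outcome variance, arm imbalance,
non-normal outcomes, selection rules informed by safety or external data, or
data-dependent stage-2 sizes. None of those are supported, by design. Other
known limitations: exactly two strata (one subpopulation and its
complement); no hypothesis testing or confidence intervals; the futility
variants require known prevalence; and whether the unbiased combination
`D_F,U` is minimum-variance among combinations of unbiased components is an
open question — the package asserts only its unbiasedness, and only without
a futility rule.
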