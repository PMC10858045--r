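---
title: "Estimating sensitive-behaviour prevalence with the Extended Crosswise Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sensitive-behaviour prevalence with the Extended Crosswise Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecwm)
```

## The measurement model

A survey arm is described by how a respondent's latent carrier status maps
to the observed binary response. Under direct questioning (DQ) a truthful
carrier answers "Yes" and a non-carrier "No". Under the crosswise model
(CWM) the sensitive question is paired with a non-sensitive randomisation
question whose "Yes" prevalence $p$ is known from external statistics, and
the respondent reports only whether the two answers match (option A) or
differ (option B). Enumerating the four branches (carrier status $\times$
randomiser draw) gives the option-A probability at prevalence $\pi$:

$$\lambda(\pi) = \pi p + (1-\pi)(1-p) = (1-p) + (2p-1)\pi.$$

This is identified only when $p \neq 1/2$; `ecwm_design()` enforces that.
The extended CWM (ECWM) runs two groups with complementary probabilities
$p$ and $1-p$. Because the groups mirror each other, a respondent
population that systematically prefers one response option pushes the two
groups' implied prevalences apart in *opposite* directions — which is what
makes non-adherence detectable.

Key assumptions, shared with the rest of the crosswise literature:

* the randomisation probability $p$ is known without error;
* the randomisation question is independent of the sensitive attribute;
* adherent respondents answer the *combined* instruction truthfully
  (the design removes the incentive, not the ability, to lie);
* respondents are independent, so arm-level option-A counts are binomial.

## Estimators

`estimate_dq()` is the "Yes" proportion with binomial standard error.
`estimate_ecwm_group()` inverts the measurement model,

$$\hat\pi = \frac{\hat\lambda + p - 1}{2p - 1},\qquad
\mathrm{SE} = \frac{\sqrt{\hat\lambda(1-\hat\lambda)/n}}{|2p-1|},$$

the delta-method (here exact, the map is affine) standard error showing the
variance inflation the randomisation buys anonymity with. When
$\hat\lambda$ falls outside $[\min(p,1-p), \max(p,1-p)]$ the raw estimate
leaves $[0,1]$; it is clamped, flagged (`truncated`), and the raw value is
kept for diagnostics. A $10^{-12}$ guard keeps exact-boundary inputs from
being flagged through floating-point round-off. At $\hat\lambda \in
\{0,1\}$ the standard error is 0 — a degenerate case that propagates (the
two-proportion statistic refuses a zero joint variance rather than
reporting $\pm\infty$).

Confidence intervals are 95% Wald on the proportion scale, clamped to
$[0,1]$. This is the plainest defensible choice at these sample sizes; a
score or bootstrap interval would behave better near the boundary but adds
machinery the rest of the pipeline does not need.

## Pooling the two ECWM groups

With adherence established, a single prevalence is estimated by maximising
the joint two-group binomial log-likelihood

$$\ell(\pi) = \sum_{g=1}^{2} n_g\!\left[\hat\lambda_g \log \lambda_g(\pi)
  + (1-\hat\lambda_g)\log(1-\lambda_g(\pi))\right].$$

The binomial log-likelihood is concave in its mean and $\lambda_g$ is
affine in $\pi$, so $\ell$ is concave with a unique maximiser that always
lies weakly between the two group estimates. `pool_ecwm()` maximises it by
a safeguarded Newton iteration on the score with a shrinking bracket
(tolerance $10^{-12}$), over the *admissible* interval on which both
$\lambda_g$ stay inside $(0,1)$; the maximiser can legitimately sit outside
$[0,1]$ for extreme inputs and is then clamped and flagged exactly like the
group estimator. The test suite checks the maximiser against an
independent two-stage grid search at step $10^{-7}$.

Joint maximum likelihood was chosen for the point estimate over equal or
inverse-variance *averaging* of the group estimates: it is the estimator
the likelihood-ratio adherence test already implies (its $\ell_{common}$
is evaluated at this maximiser), and it degrades gracefully when one group
is truncated. The pooled standard error is the inverse-variance
combination $(1/\mathrm{se}_1^2 + 1/\mathrm{se}_2^2)^{-1/2}$ of the group
standard errors — for complementary designs the two per-observation
variances coincide ($\lambda_2 = 1-\lambda_1$), so this equals the
single-sample crosswise standard error at the combined $n$.

## The adherence test

`adherence_lr_test()` computes $G^2 = 2[\ell_{sep} - \ell_{common}]$, where
$\ell_{sep}$ evaluates each group's binomial log-likelihood at its own MLE
($\lambda = \hat\lambda_g$, with the $0\log 0 = 0$ convention) and
$\ell_{common}$ at the pooled maximiser above. Evaluating $\ell_{common}$
over the full admissible interval — not clamped to $[0,1]$ — is what
guarantees $G^2 \ge 0$ and the $\chi^2_1$ null calibration; the clamped
estimate is a reporting decision, not a likelihood restriction. The test
suite verifies the size empirically: over 10,000 simulated adherent
surveys at $n = 500$ per group the rejection rate at $\alpha = 0.05$ falls
inside $[0.04, 0.06]$.

A significant test blocks pooling (and all downstream analysis of that
item). The direction of the violation is then diagnosed: in the group with
the larger absolute deviation between observed and expected option-A
counts under the common-prevalence model, a positive deviation indicates
preference for option A, a negative one for option B. At the common MLE
the two groups' deviations share a sign (the score weights have opposite
signs), so the diagnosis is coherent: both groups seeing "too few A"
points at the group where that shortfall is strongest. This directional
readout is deliberately heuristic plumbing — the test itself is the
inferential statement.

Design pairs are accepted when their randomisation probabilities are
complementary *or* equal: flipping one group's response codes
(`flip_group_coding()`: $n_A \to n - n_A$, $p \to 1-p$) is an involution
that leaves every estimator and $G^2$ invariant, and a flipped pair shares
one $p$. Anything else is a design mismatch and errors.

## Comparing DQ and ECWM

`compare_dq_ecwm()` uses the unpooled two-proportion statistic

$$z = \frac{\hat\pi_{ECWM} - \hat\pi_{DQ}}
  {\sqrt{\mathrm{se}_{DQ}^2 + \mathrm{se}_{ECWM}^2}},$$

two-sided against the standard normal. The variances are model-based and
unpooled because the two estimators have structurally different variances
— the crosswise one carries the randomisation inflation — so a
pooled-proportion variance would be wrong under either hypothesis. This
formula is documented as *the* formula the package computes; no attempt is
made to reverse-engineer alternative published test statistics.

## Measurement-model logistic regression

`fit_rr_logistic()` maximises
$\sum_i y_i \log q_i + (1-y_i)\log(1-q_i)$ with
$q_i = c_i + d_i\,\sigma(x_i'\beta)$, where $(c,d) = (0,1)$ for DQ rows and
$(1-p, 2p-1)$ for crosswise rows (after internally flipping any arm whose
$p$ is complementary to the reference arm's — the likelihood is invariant
to which arm is flipped, and the tests check it). For every $\beta$, $q$
stays inside the closed interval between $c$ and $c+d$, a strict subset of
$(0,1)$ for interior crosswise designs, so the objective is evaluable
everywhere; DQ is the degenerate case of ordinary logistic regression, and
the all-DQ fit matches `glm()` to $10^{-6}$.

Numerical choices: damped Newton–Raphson with *analytic* gradient and
Hessian, fixed zero start (fits are deterministic), step-halving on any
likelihood decrease, convergence at gradient norm $< 10^{-8}$, Wald
standard errors from the observed information at the optimum. The Hessian
is cheap and exact here, so full Newton was preferred to quasi-Newton
updates; it also supplies the information matrix the Wald inference needs
anyway. Coefficients beyond 30 on the log-odds scale trigger a separation
warning — reported, never "fixed".

The linear predictor always includes an intercept and, when both
questioning formats are present, the effect-coded format ($-1$ = DQ, $+1$
= ECWM) as a control term; with a single format the term is dropped (it
would be collinear with the intercept) and the fit notes it.
`test_format_moderation()` adds a covariate $\times$ format interaction and
reports its Wald test — a significant interaction is the signature of
social desirability distorting the directly-questioned responses for that
covariate. Analysis is complete-case on the item response and all terms;
inference is Wald only, with no multiple-testing correction across terms
or items (matching common reporting practice; users combining many items
and predictors should adjust externally).

Calibration, all seeded in the test suite: slope recovery within $\pm 0.1$
at $n = 20{,}000$; 95% Wald CI coverage of the slope within $[0.93, 0.97]$
over 500 replicates at $n = 2{,}000$; interaction null rejection near
$\alpha$ and power above 0.8 against a DQ-suppressed effect at
$n \approx 5{,}000$. These checks run the generator with truthful DQ
responses, because they test the measurement model itself — the model
assumes DQ observes the truth, and the regression's format term controls
for level differences, not for arbitrary DQ distortion of slopes.

## Planning: variance inflation and sample size

`variance_cwm()` is $\lambda(1-\lambda)/(n(2p-1)^2)$, reducing exactly to
the DQ variance at $p = 1$; `design_effect()` is its ratio to the DQ
variance, strictly decreasing in $|2p-1|$ and always $\ge 1$ — the price
of anonymity. `required_n()` sizes the two-arm DQ-vs-ECWM comparison by
the usual normal-approximation formula with model-based variances, the DQ
arm evaluated at the planning prevalence $\pi$ and the crosswise arm at
$\pi + \delta$ (the anticipated under-reporting gap), honouring an
ECWM-to-DQ allocation ratio that defaults to 2 — the crosswise variance
inflation is roughly compensated by doubling that arm. No continuity
correction is applied, consistent with the normal-approximation analysis
the sizes are planned for; a `worst_case` option replaces
$\lambda(1-\lambda)$ by $1/4$. The returned sizes achieve their nominal
power within $\pm 3$ points in a 2,000-replicate simulation in the test
suite.

## The synthetic-respondent generator

`simulate_survey()` generates the data-generating process the analysis
assumes, at the scale of the motivating design. The defaults *are* the
study conditions the package is built around: arms of 530 (DQ), 523
(ECWM1) and 524 (ECWM2) respondents; four sensitive items with prevalences
0.18, 0.11, 0.06 and 0.18; $p_1 = 0.256$ (a three-consecutive-month
birth-statistics randomisation question) with $p_2 = 1 - p_1$; and
one-sided DQ under-reporting at rate 0.7 — the value implied by a
directly-questioned prevalence near 5.7% against a crosswise prevalence
near 18.4% (carriers answering "Yes" at rate $\approx 0.31$). Non-carriers
never false-confess, the standard one-sided social-desirability
assumption.

Two distinct non-adherence mechanisms are modelled, because they are
distinguishable in principle and behave differently: *careless* responding
(uniform A/B, item by item — drives both group estimates towards the value
implied by $\lambda = 1/2$ regardless of the truth) and *systematic option
preference* (a fixed option always chosen on the affected items — the
failure mode the ECWM is designed to detect, and the one the adherence
test has its power against). A respondent flagged for both follows the
preference.

Each arm draws from its own seed substream, so identical seed and config
give byte-identical surveys and resizing one arm leaves the others'
records untouched. `simulate_ecwm_counts()` / `simulate_dq_counts()`
expose the exact binomial count-level margin of the same mechanisms
(including both non-adherence modes), which makes the larger calibration
studies cheap; a property test pins the record-level and count-level
marginals together. `study_scale_fixture()` is the fixed-seed 1,577-row
survey used for end-to-end tests: it adds a 30% option-B preference in
ECWM1 on the fourth item, so a full pipeline run shows DQ deflation on
every item, valid pooling on three, and one blocked non-adherent item.

What the generator deliberately does **not** emulate: quota sampling and
survey weighting, psychometric construction of the covariate scales (they
are drawn as standard normals or Bernoulli codes), item wording effects,
and any dependence between items beyond shared covariates. Passing
calibration tests therefore demonstrates the statistical machinery under
the model's own assumptions — not robustness to frame errors, weighting,
or comprehension failure, which no count-level method can certify from
the data alone.

## Report pipeline

`load_survey()` validates respondent CSVs against the per-arm response
alphabets (row-numbered errors, never coercion; missing responses are
preserved and excluded per item — complete-case within each analysis) and
rejects unidentified configs ($p_1 = 0.5$) at load time.
`run_full_pipeline()` runs the stages in their natural order — DQ
estimates, group estimates, adherence, pooling, comparison, optional
regression — and never pools, compares, or regresses an item whose
adherence test failed. Tables round proportions to 3 decimals (DQ
prevalences printed as percentages); the JSON bundle written by
`write_report()` keeps full precision, and a test asserts the rounded
tables equal their JSON twins. Each stage writes one structured log line
recording sizes and decisions (e.g. why an item's pooling was blocked).

## Problem sizes and determinism in the test suite

All stochastic checks are seeded. Sizes were chosen so each check is
informative at its stated tolerance: 10,000 replicates for test size
(Monte-Carlo SE $\approx 0.002$ against a $[0.04, 0.06]$ band), 1,000 for
estimator bias (SE of the mean $\approx 0.001$ against a 0.01 band), 500
fits for CI coverage, 200,000 draws for the variance oracle (relative
Monte-Carlo error $\approx 0.3\%$ against a 2% band), and $2\times10^5$
respondents per arm for law-of-large-numbers checks at 0.005.

## Known limitations

* Wald intervals degenerate at boundary counts ($\hat\lambda \in \{0,1\}$
  gives SE 0); extremely rare events need exact or score methods.
* The adherence test only detects non-adherence that manifests as a
  *systematic* option preference; symmetric carelessness biases both
  groups identically and is invisible to it (it shrinks estimates towards
  the $\lambda = 1/2$ value).
* The regression assumes the DQ arm observes the truth; if direct answers
  are distorted, the format main effect absorbs only a level shift, and
  slope estimates blend the two formats' associations — the moderation
  test exists precisely to flag that situation.
* $p$ is treated as known; uncertainty in the randomisation statistics is
  not propagated.
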