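---
title: "Methods: the euploidy model, the oocyte planner, and the development pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the euploidy model, the oocyte planner, and the development pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artcalc)
```

## The clinical question

In IVF/ICSI cycles with preimplantation genetic testing for aneuploidy
(PGT-A), a pragmatic intermediate endpoint is obtaining **at least one euploid
blastocyst** for transfer. Counseling and stimulation planning then hinge on a
single number: how many mature (metaphase-II, MII) oocytes does this couple
need so that the chance of at least one euploid blastocyst reaches a chosen
success probability $\pi$? `artcalc` answers that question with a published
per-oocyte probability model and elementary probability, and also ships the
statistical machinery by which such a model is developed and validated, so
the whole development path can be exercised end to end on simulated cohorts.

## The per-oocyte euploidy model

Each MII oocyte is treated as an independent Bernoulli trial that ends as a
euploid blastocyst with probability $p$, a function of female age and the
sperm source used for ICSI:

$$Y = a + b\,[\text{ejaculate-like}] + c\,[\text{ejaculate-like}]\,(A - A_0)
      + d\,[\text{NOA}]\,(A - A_0), \qquad p = \frac{1}{1+e^{-Y}},$$

with $A$ the female age in years and $A_0 = 38.9066$ the centering age. The
model distinguishes exactly two sperm groups: testicular sperm from men with
non-obstructive azoospermia (NOA) versus everything else (ejaculated sperm,
epididymal sperm, testicular sperm from obstructive azoospermia, and
testicular sperm from non-azoospermic men with high DNA fragmentation), which
all share the "ejaculate-like" coefficients. The shipped coefficient file
(`inst/extdata/table2.json`) holds $a = -2.6518$, $b = 0.2231659$,
$c = -0.2045457$, $d = -0.1530924$ with their standard errors.

Two details of this coding were genuinely open and are fixed here as package
choices:

* **Coding.** The intercept alone is the NOA group at the centering age; $b$
  and $c$ attach only to the ejaculate-like group, $d$ only to the NOA group.
  This literal reading reproduces the published overall yearly reductions in
  $p$ (14.4% and 12.1% over ages 24–45) to within 0.02 percentage points,
  which alternative codings do not beat.
* **Centering age.** The published material prints two centering ages
  (38.9066 in the equation header, 37.9384 in the term rows). The package
  ships the header value, which reproduces the published effect sizes; it is
  configurable in `art_coefficients()`.

A consequence of the fitted slopes worth knowing: the two linear predictors
cross near age 43. Up to there the NOA group has a strictly lower $p$; past
the crossing the curves are practically indistinguishable (the age effect has
absorbed the sperm-source effect), so the package's ordering checks stop at
age 43.

Ages are accepted on 18–50 (hard limits) and warned about outside 24–45, the
range over which the model reproduces the published effect sizes.

### Confidence limits

The 95% interval for $p$ is a Wald interval on the logit scale mapped through
the inverse logit: $Y \pm z_{1-\alpha/2}\,\mathrm{SE}(Y)$. Because only
per-term standard errors are published, `SE(Y)` defaults to the independence
(diagonal) approximation
$\mathrm{SE}(Y)^2 = s_a^2 + [\text{ej}]\,s_b^2 + ([\text{ej}](A-A_0))^2 s_c^2
+ ([\text{NOA}](A-A_0))^2 s_d^2$; whether the original intervals were Wald or
profile is not stated in the source material, so Wald was chosen as the
standard reporting form. Models refitted inside the package carry their full
coefficient covariance, and the exact delta-method variance
$g^\top \Sigma g$ is then used automatically.

## The planner

With $p$ fixed, the number of euploid blastocysts from $n$ oocytes is
Binomial$(n, p)$, so
$$\Pr(\ge 1 \text{ euploid}) = 1 - (1-p)^n \ge \pi
  \iff n \ge \frac{\log(1-\pi)}{\log(1-p)}.$$

`min_mii_for_success()` returns the smallest integer satisfying the
inequality. Numerical choices:

* **Boundary convention.** Exact integer quotients are kept: $p = 0.5$,
  $\pi = 0.75$ gives $n = 2$ because $1 - 0.5^2 = 0.75$ exactly. Comparisons
  use a relative tolerance of $10^{-12}$ so analytic boundaries are not lost
  to floating point.
* **Cap.** Requirements above 999 oocytes are capped with an "unrealistic
  target" warning; at advanced ages the formula produces numbers with no
  clinical meaning.
* **Degeneracies.** $p \le 0$ is an error ("success unattainable"); a
  confidence limit at zero makes the corresponding oocyte bound unbounded
  (reported as `Inf` with a warning) rather than silently large.

Confidence limits propagate through the monotone maps by endpoint evaluation:
$p \mapsto n$ is decreasing, so the oocyte interval uses the swapped
probability endpoints; the posttreatment revision $p \mapsto 1-(1-p)^{n}$ is
increasing and keeps endpoint order. Both propagations are valid because the
estimators are maximum likelihood and the maps are monotone.

The published worked examples (11 [9–13] oocytes at age 37 with $\pi = 0.8$,
etc.) are **not** reproducible from the published coefficient table under any
standard coding — direct evaluation gives $p \approx 0.115$ at age 37 and
hence $n = 14$ — and are mutually inconsistent; the production web calculator
evidently used a different coefficient set. They are treated as qualitative
illustrations, not targets.

## The development pipeline

The model-development machinery mirrors how such a calculator is built from a
PGT-A cohort and is exercised on synthetic cohorts.

**Aggregated-binomial stage fits.** Per-oocyte binary responses (euploid per
MII, 2PN per MII, blastocyst per 2PN, euploid per biopsied blastocyst) are
fitted by logistic regression on per-patient aggregated counts
(`cbind(k, m-k)`), which is likelihood-identical to the per-oocyte Bernoulli
expansion; the equivalence is verified in the tests. AICc uses the number of
Bernoulli trials as the sample size. Complete separation is detected and
reported rather than returning divergent coefficients; zero-denominator rows
are dropped with a warning.

**Negative-binomial count model.** The per-patient euploid count is fitted
with a log-link negative-binomial GLM with a single dispersion parameter
estimated jointly by ML (`MASS::glm.nb` behind the module surface). The
reported `dispersion` is $1/\theta$, so variance $= \mu + \text{dispersion}
\cdot \mu^2$ and 0 is the Poisson boundary. On equidispersed data the
$\theta$ iteration can diverge; the fit then falls back to the boundary
(Poisson) solution with a warning, accepted only when the Poisson Pearson
statistic confirms no overdispersion. Interval checks in the tests use
profile likelihood for the mean parameter and a log-normal Wald interval for
$\theta$.

**Adaptive LASSO with AICc stopping.** Candidates are standardised; an
unpenalised reference fit supplies weights $w_j = 1/|\hat\beta_j|^\gamma$
with $\gamma = 1$; the weighted L1 path is solved by coordinate descent
(`glmnet`), and the path point minimising
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ is selected, with $k$ the
active-set size plus intercept ("adjusted AIC" is read as the small-sample
corrected AICc, its standard meaning in the software used for the original
analysis). The path log-likelihood of the penalised fit is scored directly;
a relaxed-refit variant was evaluated during development and retained *more*
noise (an AIC-type penalty admits any variable whose refitted $z$ exceeds
$\sqrt 2$), so the plain path criterion is used. A structural property of any
AICc-flavoured stopping rule is worth stating plainly: a pure-noise covariate
clears the $|z| > \sqrt 2$ hurdle with probability $\approx 0.16$, so with
nine noise candidates roughly 1.4 enter on average and the chance of keeping
at most one spurious covariate is near 50%, not near 1. The selection tests
document this operating characteristic; AICc buys honest prediction-oriented
selection, not oracle sparsity.

**Holdout validation.** A seeded simple random 80/20 patient split (no
stratification); the model is fitted on the training split and the
per-oocyte ROC AUC — the tie-corrected Mann–Whitney statistic, implemented
directly and cross-checked against an exhaustive pair count and `pROC` in the
tests — is reported on both splits from expanded (score, outcome) pairs.

**Effect sizes.** The yearly effect of age is the ratio $p(t+1)/p(t)$ at
integer ages; the overall reduction is $100(1 - \text{geometric mean})$,
which telescopes to the two-endpoint closed form. The default range 24–45 is
the unique integer range reproducing both published reductions. As age grows
the ejaculate-group ratio converges to $e^{c} \approx 0.815$.

## The synthetic cohort generator

The generator emulates the development cohort's marginal structure, one
patient per row:

| quantity | model | calibration |
|---|---|---|
| female age | scaled Beta on [24, 45] | mean 38.9, concentration 10 (central 95% ≈ 32.6–43.5 vs reported 32.4–42.4) |
| sperm source | categorical | 71.5 / 4.9 / 23.6% (ejaculate / epididymis / testicle) |
| NOA among testicular | Bernoulli | 44/65 (reported NOA share of azoospermia) |
| oocytes retrieved | negative binomial | mean 8.2, size 10 (central 95% ≈ 2–17 vs reported 2.0–16.2) |
| MII per retrieved | binomial | rate 0.781 |
| stage chain | sequential binomials | 0.673, 0.489, 0.348 |

The published cohort table is internally inconsistent in places (sperm-source
counts exceed the patient total; MII mean 6.3 vs 8.2 × 0.781 = 6.40), so the
generator is calibrated to the *rates* and the chain is left exact; the
implied means (6.40 MII, 2.11 blastocysts, 0.74 euploid per patient) sit
within ~2% of the reported ones. The reported "95% CI" columns appear to be
empirical ranges, so distributional matching is approximate by design.

In `MODEL_DRIVEN` mode the euploid-per-MII outcome is drawn directly from the
logistic model and the intermediate counts are drawn as conditional binomials
so the ordering `euploid ≤ blastocyst ≤ 2PN ≤ MII ≤ retrieved` holds row by
row; the unconditional blastulation probability is clamped up to the model
probability where needed (young ages only). Patient-level heterogeneity
(Beta-perturbed stage probabilities, i.e. Beta-binomial marginals) is **off**
by default, honoring the constant-probability working assumption, and can be
enabled to stress the negative-binomial count fit.

What passing simulation tests do *not* show: real cohorts have correlated
covariates, informative missingness, clinic effects, and per-patient
clustering beyond what the Bernoulli chain induces. The synthetic holdout AUC
(~0.66–0.69 at the calibrated age spread) brackets plausibility only; the
published fitted AUC (0.716) is a property of the unpublished patient data,
as are the published log-likelihood importance of age (30.9, df = 2) and the
intermediate-stage reductions (17%/24%), none of which are reproducible at
desk scale.

## Problem sizes and determinism

Simulation-based checks use cohorts of 347–5,000 patients (25 replicate seeds
for recovery experiments; 50 for interval-coverage checks) and one
100,000-patient cohort for generator calibration — sizes at which every check
runs in seconds to a couple of minutes on a single core while leaving
Monte-Carlo error well below the asserted margins. Every stochastic function
takes an explicit seed and is bit-reproducible given one; the pipeline report
logs all seeds it consumed.
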