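---
title: "Methods: forced-response surveys of sensitive behaviours"
author: "rrforced"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forced-response surveys of sensitive behaviours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrforced)
```

## The problem

Self-reports of stigmatized behaviour — theft, illicit drug use, violence
against property, reckless driving, arson — are distorted by social
desirability bias: respondents withhold admissions they believe reflect
badly on them. Randomized response techniques counter this by interposing a
chance device between the question and the answer, so no individual answer
reveals individual status, while population prevalence remains estimable.

`rrforced` implements the forced-response variant end to end: the device,
the design-corrected prevalence estimator, the direct-versus-indirect
contrast that measures the bias, a misclassification-adjusted logistic
regression, and a synthetic-cohort simulator that makes every stage
testable. The package's defaults emulate the setting it was designed
around: a survey of 792 adult male inmates of a Spanish prison, aged 18–55,
half questioned directly and half through a 40-card Spanish deck.

## The device and its misclassification line

In a forced-response design the respondent draws a card (returned to the
deck afterwards, so draws are independent with replacement): a fraction
$p_1$ of cards force the answer "yes", $p_2$ force "no", and the remaining
$p_3 = 1 - p_1 - p_2$ request the truthful answer. The observed
yes-probability is affine in the true prevalence $\pi$:

$$\lambda = c + d\,\pi, \qquad c = p_1,\; d = p_3 .$$

The 40-card deck (numbers 1–2 force yes, 3–4 force no, 5–7 and the figures
are genuine) gives $(p_1, p_2, p_3) = (0.2, 0.2, 0.6)$, hence
$(c, d) = (0.2, 0.6)$. These probabilities are *derived* from the deck
composition by `deck_design(8, 8, 24)`, not assumed. Direct questioning is
the degenerate member $(c, d) = (0, 1)$, which lets both arms share one
code path. Two parametrizations of forced-response devices circulate in the
literature (deck proportions versus a conditional forced-yes probability);
they agree on the $(c, d)$ line, which is the only thing estimation and
regression consume, so the package stores the deck triple and exposes
$(c, d)$.

Only forced-response-family devices are supported; other randomizing
devices (Warner wheels, dice, item counts) are out of scope.

## Prevalence estimation

With observed yes-rate $\hat\lambda$ (a weighted mean under optional
positive sampling weights, reducing to the sample proportion under equal
weights — the Horvitz–Thompson estimator under simple random sampling), the
prevalence estimator inverts the line:

$$\hat\pi = \frac{\hat\lambda - c}{d}, \qquad
  \hat V(\hat\pi) = \frac{\hat\lambda(1-\hat\lambda)}{(n-1)\,d^2}.$$

Design choices worth stating explicitly:

* **Variance.** The equal-weight simple-random-sampling form without
  finite-population correction, labelled as such in reports. Published
  tables of this kind rarely state the exact sampling-design correction
  used; reproducing any particular printed variance requires the microdata,
  so the package commits to the transparent closed form above. Division by
  $d^2$ is the *privacy premium*: at equal $n$ the forced-response
  estimator's variance exceeds the direct-questioning one for every $\pi$
  (asserted from the closed forms in the test suite).
* **Interval.** A Wald interval around the *untruncated* estimate,
  truncated to $[0,1]$. Truncation (rather than a logit-scale interval) is
  deliberate: near-ceiling prevalences with upper bounds of exactly 1.0000
  are the natural output of this estimator, and the truncated Wald form is
  what `prevalence_from_summary()` reproduces from published
  (estimate, variance) pairs.
* **Truncation.** Point estimates are reported truncated to $[0,1]$;
  `estimate_raw` is preserved because the z-test below must use the
  untruncated scale (truncation would bias contrasts near the boundary).
* **Degenerate inputs.** $n < 2$ is an error globally ($\hat V$ undefined);
  in subgroup tables such cells are emitted flagged with an absent
  variance. $d = 0$ designs are rejected at construction.
* Reports print 4 decimals by default.

Empirical calibration, recomputed by `scripts/acceptance.R` and the test
suite rather than quoted here: at $n = 396$, $\pi = 0.58$ under the study
device, the nominal 95% interval covers at its nominal rate (±1.5
percentage points over 5,000 simulated surveys) and the estimator is
unbiased to within 0.01 over 2,000 surveys.

## The direct-versus-indirect contrast

The two arms are independent samples, so the bias signal is tested with

$$z = \frac{\hat\pi_{RR} - \hat\pi_{DQ}}
           {\sqrt{\hat V_{RR} + \hat V_{DQ}}}$$

on the untruncated estimates, with a two-sided normal p-value. The source
analyses of this design report only p-values for the contrast without
naming the test; the independent-arm z-test is an assumption of this
package, stated as such. No multiple-testing correction is applied across
the five behaviours (matching the reporting convention the package
emulates).

Effect size is Cohen's $h = 2(\arcsin\sqrt{p_2} - \arcsin\sqrt{p_1})$, the
standard measure for two proportions. Published tables in this area
sometimes print a "Cohen's d" column for proportion contrasts whose values
are not reproducible by $h$, pooled-SD $d$, or log-odds $d$; the package
makes no attempt to match any such column and always reports $h$.

## Misclassification-adjusted logistic regression

Each respondent $i$ carries a device line $(c_i, d_i)$ — $(0,1)$ in the
direct arm, the deck's $(0.2, 0.6)$ in the indirect arm — and a latent
status probability $\mu_i = \mathrm{logit}^{-1}(x_i^{\mathsf T}\beta)$. The
observed answer is Bernoulli with probability
$\lambda_i = c_i + d_i\,\mu_i$, giving the log-likelihood

$$\ell(\beta) = \sum_i y_i\log \lambda_i + (1-y_i)\log(1-\lambda_i).$$

Both arms enter one joint fit, with the questioning method also present as
a covariate capturing residual reporting differences — the only reading
under which a "method: forced" coefficient row makes sense, and the one the
package adopts.

Numerical choices:

* **Optimizer.** Newton with step-halving from $\beta = 0$, using the
  analytic gradient and Hessian; BFGS rescue if the Hessian loses negative
  definiteness. Convergence is declared at gradient max-norm $< 10^{-8}$.
  $\mu_i$ is clipped to $[10^{-12}, 1-10^{-12}]$ so boundary rows with
  $c_i = 0$ keep finite terms.
* **Inference.** Standard errors from the inverse observed information at
  the optimum; per-coefficient Wald z and two-sided p-values;
  $\exp(\beta)$ odds ratios; AIC $= 2k - 2\ell$.
* **Selection.** Bidirectional stepwise on AIC, whole categorical blocks
  moving together, stopping at a local minimum. The method term is never
  dropped: it is the design variable of interest, significant or not.
* **Goodness of fit.** Pearson
  $X^2 = \sum_i (y_i-\lambda_i^*)^2 / (\lambda_i^*(1-\lambda_i^*))$
  referred to $\chi^2_{n-k}$. With ungrouped binary data this reference is
  approximate only: the statistic's variance depends on the fitted
  probabilities (each term's variance vanishes at $\lambda^* = 0.5$), so
  its p-values are *not* uniform under a correct model — they concentrate
  around 0.5 for mid-range probabilities. The statistic is reported
  because it is the conventional summary for this model family; the test
  suite anchors it by exact agreement with the classical Pearson statistic
  in the $(c,d)=(0,1)$ reduction rather than by a uniformity claim.
* The $(c,d) = (0,1)$ reduction reproduces an IRLS `glm` logistic fit to
  $10^{-6}$ in every coefficient — the module's strongest correctness
  anchor, exercised in the acceptance suite.

## The synthetic cohort

The simulator exists so the whole pipeline can be validated without
microdata (none are deposited for the survey the defaults emulate). It
generates, per respondent: categorical covariates drawn *without
replacement* from the configured count marginals (realized counts match
exactly); age from a truncated normal on [18, 55] with mean 37.01, SD
9.317, rounded to years; sentence length from a log-normal moment-matched
to mean 69.76, SD 72.626 months; obsessive-compulsive severity from a
normal truncated to [0, 40] with mean 7.34, SD 7.121, rounded to points.
The three continuous choices are distributional stand-ins — only means and
SDs are documented for the emulated survey — and truncation/rounding
shifts realized moments slightly; tests therefore check bounds and rough
moments, not exact ones.

Two marginals required a decision: the documented marital-status and crime
counts each sum to 790, not 792. The defaults assign the two unclassified
respondents to the residual/largest category (`single` 376→378, crime
`other` 235→237) so marginals total $n$; all other covariates use the
documented counts unchanged.

Latent true statuses come from a per-behaviour logistic model whose slope
coefficients default to published regression point estimates where
available (zero otherwise) and whose intercept is *calibrated by
root-finding at generation time* so the cohort-average latent probability
equals the target prevalence — the indirect-arm estimates 0.8329 (theft),
0.9983 (drugs), 0.5867 (violence), 0.9418 (speeding), 0.2679 (arson).
Statuses are independent across behaviours given covariates;
cross-behaviour correlation is not modelled (unquantified in the emulated
survey).

Observed answers follow a one-sided lying model: under direct questioning
a true positive admits with probability `dq_report_rate` (defaults
0.6918/0.7033/0.5117/0.7661/0.2800, the ratios of the emulated survey's
direct to indirect estimates) and a true negative never falsely confesses
— the reading under which an indirect-minus-direct gap means withheld
admissions. Indirect-arm respondents are assumed fully device-compliant;
no cheating parameter is modelled. Consequently the direct-arm estimator
converges to $\pi \times$ `dq_report_rate`, not $\pi$ — exactly the gap
the comparison module measures — and passing tests demonstrate internal
consistency of the machinery under this mechanism, *not* that real
respondents lie this way: real data may show false confessions,
device non-compliance, and correlated behaviours.

Arm assignment is a seeded uniform permutation with
`round(n * arm_split)` respondents indirect (round-half-to-even; 792 at a
0.5 split gives 396/396 — arm sizes are an assumption, as the emulated
survey never printed them). All stochastic stages accept explicit seeds;
`simulate_survey()` and `run_pipeline()` derive independent per-stage
substreams from one master seed, so adding a stage never perturbs earlier
draws and a logged seed reproduces every number exactly.

## Problem sizes in the validation suite

The simulation-backed checks use the sizes at which their Monte Carlo
error makes the assertion sharp: 5,000 surveys of $n = 396$ for interval
coverage; 5,000 two-arm surveys of $n = 792$ for the null size of the
z-test; 2,000 surveys for estimator bias; 200 replications of 2,000-row
mixed-arm datasets for coefficient recovery; 200 replications for stepwise
noise removal (the theoretical removal rate of an AIC comparison on a null
term is $P(\chi^2_1 < 2) \approx 0.84$); 100 full-cohort surveys for
detection power. Device-level Monte Carlo checks use $10^5$ draws with a
$3\sqrt{\lambda(1-\lambda)/n}$ tolerance.

## Known limitations

* The variance estimator ignores finite-population correction and any
  stratification; complex survey designs beyond a generic weight vector
  are out of scope.
* The regression is fixed-effects only; no random effects, penalization,
  or Bayesian alternatives.
* The Pearson p-value's chi-square reference is approximate for ungrouped
  binary data (see above); grouped-data or Hosmer–Lemeshow-style checks
  are not implemented.
* The Y-BOCS module scores only the 10-item total severity (0–40) and its
  bands — low 8–15, moderate 16–23, severe 24–31, very severe 32–40, with
  0–7 labelled "subthreshold", a package-defined label for totals below
  the lowest published band. The 64-item symptom checklist is out of
  scope.
* Figures are not produced; the numbers behind subgroup plots come from
  `subgroup_estimates()` and plotting is left to the user.
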