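---
title: "Measuring approximate-number acuity with a drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring approximate-number acuity with a drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansacuity)
```

## The measurement problem

Humans can compare the numerosities of two dot arrays without counting, via
the approximate number system (ANS). Individual differences in the precision
of this system are usually summarised by a Weber fraction `w`, estimated by
fitting ratio-wise accuracy in a two-array comparison task. The trouble is
that accuracy alone confounds representational precision with the
speed–accuracy policy a participant happens to adopt: a hasty responder
looks imprecise, a cautious one looks acute. Response times carry the
information needed to separate the two, and a sequential-sampling model is
the standard tool for doing so.

`ansacuity` implements that decomposition for the classic numerosity
comparison design (dot counts 9–21; ratios 4:3, 7:6, 9:8, 10:9; 750 ms
displays; a 3 s response window; 12 blocks of 64 trials). Its core estimator
is a drift-diffusion model in which the mean drift toward the correct
response in a condition with numerosities $n_L > n_S$ is

$$v_{L:S} = v_S \,(\log n_L - \log n_S),$$

so a single participant-level *drift scale* $v_S$ plays the role of ANS
acuity across all four ratio conditions, while separate parameters absorb
response caution (boundary separation $a$), encoding/motor time
($T_{er}$, range $s_T$), and across-trial variability in drift ($\eta$,
shared across conditions — the log-scale, fixed-variability representation),
starting point (range $s_Z$, mean fixed at $a/2$), plus a contaminant
proportion $p_O$. The within-trial diffusion coefficient is fixed at
$s = 0.1$; it is a gauge, not a substantive parameter — multiplying $a$,
$s_Z$, $v_S$, $\eta$ and $s$ by a common factor leaves every prediction
unchanged (this invariance is tested).

The classical estimator is also provided: under the log-scale Weber model
the error rate for a ratio condition is the mass below zero of a Gaussian
with mean $\log n_L - \log n_S$ and standard deviation $\sqrt{2}\,w$, i.e.
$\tfrac12\,\mathrm{erfc}\!\big((\log n_L - \log n_S)/(2w)\big)$;
`fit_weber()` maximises the product of binomial likelihoods of the four
observed error counts. Maximum likelihood is used because it is the
statistically standard objective for binomial counts and coincides with
least-squares fits at the optimum for balanced designs; the search is a
bounded golden-section minimisation on $w \in [0.01, 2]$, wide enough to
bracket any plausible adult value. Natural logarithms are used throughout —
the drift-rate scaling only reproduces the conventional worked values
(e.g. $v_S = 1.16 \Rightarrow v_{4:3} = 0.33$) under natural log.

## The chi-square quantile fit

`fit_ddm()` estimates the seven free parameters per participant by the
chi-square quantile method. For each condition and response type the
0.1/0.3/0.5/0.7/0.9 empirical RT quantiles define six bins; response types
with 2–8 observations are collapsed to two bins split at the median, and
with fewer than 2 observations to a bare count (their RTs are not fit).
A fully populated participant therefore contributes 12 response frequencies
and 11 degrees of freedom per condition, 44 in total. The objective is
$\sum (O - E)^2 / E$ with expected frequencies from the model's
response-by-bin probabilities.

Numerical choices, all of which were genuinely open:

* **First-passage CDF.** The two-boundary Wiener first-passage CDF is
  computed from the eigenfunction (large-time) series with adaptive
  truncation to an absolute tolerance of $10^{-7}$ and a hard term cap
  (exceeding the cap raises an error rather than returning a degraded
  value). A small-time expansion is deliberately *not* used: at this task's
  geometry ($a \approx 0.09$, $s = 0.1$) the series converges in tens of
  terms for every decision time above a closed-form negligible-mass guard
  (times at which the crossing probability is provably below machine-level
  mass return 0 directly). The implementation is validated against
  Euler–Maruyama simulation by a Dvoretzky–Kiefer–Wolfowitz band test.
* **Across-trial integration.** Drift varies as a Gaussian across trials, so
  it is integrated by Gauss–Hermite quadrature — the natural rule for a
  Gaussian weight; the uniform starting-point dimension uses Gauss–Legendre.
  The non-decision-time average $\int F(t-u)\,du$ has a kink where $t - u$
  crosses zero, so its Gauss–Legendre nodes are rescaled per evaluation time
  to the subinterval where the integrand is nonzero, restoring spectral
  accuracy. With the default 13 nodes per non-degenerate dimension, doubling
  the node count moves no predicted bin probability by more than $10^{-5}$
  at typical parameters (tested). Quadrature rather than Monte Carlo keeps
  the objective surface deterministic for the optimizer.
* **Contaminants.** The contaminant process is uniform in RT over a window
  that defaults to each condition's observed RT range; contaminant trials
  keep the diffusion process's response, so choice probabilities are
  unaffected — the same convention the trial simulator uses. Expected
  frequencies are floored at $10^{-4}$ so that zero-probability bins at
  extreme parameter values cannot produce an infinite objective mid-search.
* **Optimisation.** Nelder–Mead with (default) five restarts. Box
  constraints are enforced by transform: $\log a$, $\log v_S$, $\log \eta$,
  $\log T_{er}$, and logistic maps keeping $s_Z < a$, $s_T < 2T_{er}$ and
  $p_O \in (0,1)$. Starts come from moment-style heuristics — the drift
  scale from the slope of logit accuracy on log ratio (for $z = a/2$,
  $\mathrm{logit}\,P = a v / s^2$), non-decision time just below the fast
  tail of the RT distribution — jittered across restarts; the best restart
  is polished with a longer run. Given a `seed` the whole fit is
  bit-reproducible. Empirical quantiles use linear interpolation between
  order statistics (R type 7); the convention is recorded in the bin
  structure because bin edges move by a few milliseconds across conventions.
  The collapse thresholds are read inclusively: 2–8 responses means
  $[2, 8]$, "below 2" means 0 or 1, applied per response type within a
  condition.

## The study simulator

`generate_cohort()` is a first-class generative model of the study, used for
validation and power exploration. Participant-level parameters are drawn as
independent truncated Gaussians centred on typical young-adult estimates for
this task — mean (SD): $a$ 0.093 (0.023), $s_Z$ 0.023 (0.018), $v_S$ 1.163
(0.471), $\eta$ 0.167 (0.110), $T_{er}$ 0.414 (0.081) s, $s_T$ 0.219
(0.109) s, $p_O$ 0.004 (0.010) — with invalid draws rejected; a covariance
matrix can be supplied instead for sensitivity studies. Each participant
completes a balanced design: every block fully crosses ratio × side of the
larger array × the two stimulus-control flags, with numerosity pairs drawn
uniformly from the admissible integer pairs in 9–21 (4:3: 12:9, 16:12,
20:15; 7:6: 14:12, 21:18; 9:8: 18:16; 10:9: 10:9, 20:18).

Trials are sampled by Euler–Maruyama integration with a 1e-4 s step plus a
Brownian-bridge crossing test at every step. The bridge test matters: the
plain scheme misses sub-step boundary excursions, and at this geometry the
resulting bias in accuracy is comparable to three Monte-Carlo standard
errors at $n = 10^6$ — exactly the resolution at which the simulator is
compared with the analytic predictions. With the bridge correction the two
routes agree within Monte-Carlo error and halving the step changes nothing
detectable (both tested). Responses slower than the 3 s window are recorded
as omitted (empty response) and dropped at validation with a logged count,
mirroring how the file reader treats no-response rows.

Math scores — the number of arithmetic problems solved in a timed block —
are generated as a latent linear function of the true drift scale with
target correlation 0.3 plus Gaussian noise, rounded and floored at zero,
with location 25 and spread 8 chosen as plausible for a timed adult
arithmetic task. The linear link is the weakest structure sufficient to
exercise the correlation analyses; nothing downstream depends on its form.

`generate_linear_scalar_cohort()` implements the rival *linear-scale,
scalar-variability* account as a contrast generator: mean drift is constant
across conditions and across-trial drift variability grows with the total
number of items ($\eta = 0.012 \times$ total, with constant drift 0.25 —
defaults chosen so the matched pairs land in the 0.68–0.83 accuracy band
typical of this task). Its diagnostic signature is that conditions with
*lower* accuracy produce *faster* mean RTs, whereas the log-scale model
predicts slower ones; the two generators are distinguished by the sign of
the RT difference on matched-difference numerosity pairs (12:9 vs 21:18 and
14:12 vs 20:18), and the test suite verifies both signs.

## Cohort analyses

`analyze_cohort()` and its components cover the standard battery:
split-half reliability from even/odd blocks with the Spearman–Brown
projection $2r/(1+r)$; Steiger's (1980) z for two dependent correlations
sharing one variable (written here directly from the formula and validated
by Monte-Carlo type-I calibration on trivariate Gaussians, since no
installed package provides it); OLS regression of math score on the drift
scale controlling for $\log w$ or for the inverse efficiency score
(mean RT / accuracy); reliability and math-correlation curves over
first-$k$-trials subsets (sizes 128–768, even/odd split defined on blocks);
and a half-cohort resampling analysis that repeatedly screens for
subsamples with a non-significant accuracy–RT correlation and compares the
two math correlations within them, seeded per draw by draw index so the
summary is invariant to participant row order. Two-sided p-values are used
throughout and no multiple-testing correction is applied. The accuracy–RT
screening correlation uses mean RT over all trials (correct and error).

## What the synthetic validation does and does not show

The test suite demonstrates, on cohorts drawn from the generator above:
drift-scale recovery (cross-participant correlation of true and recovered
$v_S$ of at least 0.8 at 20 participants × 768 trials), selective influence
(recovered $a$ tracks true $a$ and not true $v_S$), near-perfect coupling of
$\log w$ with accuracy, the model-comparison RT signature, and a resampling
pipeline in which the drift scale out-predicts the Weber fraction for math
in most accuracy–RT-null half-cohorts. Problem sizes used by the default
test run are deliberate package choices: $10^6$ trials per condition for
the analytic-versus-simulation comparison, 20 participants for recovery
(with 2 restarts per fit), 110 participants and 10,000 repetitions for the
resampling analysis, and reduced sizes elsewhere.

Because the generator *is* the fitted model (plus the study design), these
checks validate the estimation machinery, not the psychology: they cannot
detect misspecification that real data might show — non-Gaussian drift
variability, drift that depends on non-numerical stimulus cues (dot size,
density, convex hull), sequential effects, or fatigue. Non-numerical-cue
modelling is explicitly out of scope. Real-data caveats aside, a
participant at ceiling in every condition pins $w$ at its lower search
bound with a warning, and chance-level data pin it at the upper bound;
the diffusion fit requires at least two non-empty conditions.

## Known limitations

* Accuracy of the drift-scale estimate degrades for participants near
  ceiling (few errors leave the error-RT bins uninformative); the task
  design (ratios no easier than 4:3) keeps typical adults away from this
  regime.
* The contaminant model is a convention; $p_O$ is weakly identified at
  realistic values (~0.004) and its estimate should not be interpreted.
* Nelder–Mead with restarts is robust but not guaranteed global; the
  `converged` flag reports whether the polished run stopped improving.
* No hierarchical (cohort-level) estimation; participants are fitted
  independently.
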