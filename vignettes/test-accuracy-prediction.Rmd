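---
title: "From pooled test accuracy to predictions for new populations"
author: "accmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pooled test accuracy to predictions for new populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accmeta)
```

## The problem

A meta-analysis of diagnostic or prognostic test accuracy usually ends
with a pooled sensitivity and specificity. Those are averages over the
populations studied. When test accuracy is heterogeneous — different
clinical settings, patient spectra, measurement practice — the accuracy
in any *one* new clinic can sit far from the average, and the pooled
numbers alone say nothing about how far. A clinician choosing whether to
adopt a test, and how to convert its result into a probability of
disease, needs three further things:

1. a *predictive* statement about the accuracy the test will have in a
   new population (prediction intervals, joint prediction regions,
   probabilities of exceeding minimum acceptable values);
2. an explicit rule for turning the meta-analysis into post-test
   probabilities (PPV, NPV) in that population; and
3. evidence that the rule *calibrates*: that predicted probabilities
   match observed risks when checked in data the rule never saw.

`accmeta` implements all three on top of study-level 2×2 counts.

## Models

### Bivariate accuracy model

With $r_{11i}$ true positives among $n_{1i}$ diseased and $r_{00i}$
true negatives among $n_{0i}$ non-diseased patients in study $i$:

$$r_{11i} \sim \mathrm{Bin}(n_{1i}, p_{1i}), \qquad
  r_{00i} \sim \mathrm{Bin}(n_{0i}, p_{0i}),$$
$$\begin{pmatrix}\mathrm{logit}\,p_{1i}\\ \mathrm{logit}\,p_{0i}\end{pmatrix}
  \sim N\!\left(\begin{pmatrix}\beta_1\\ \beta_0\end{pmatrix},
  \Omega\right),\qquad
  \Omega = \begin{pmatrix}\tau_1^2 & \rho\tau_1\tau_0\\
  \rho\tau_1\tau_0 & \tau_0^2\end{pmatrix}.$$

The binomial likelihood is kept exact (no continuity corrections, no
normal approximation of study logits), which matters for the small and
boundary-heavy studies typical of this literature.

`fit_bivariate_ml()` maximises the marginal likelihood by adaptive
Gauss–Hermite quadrature: a tensor grid (default $10\times10$ nodes)
recentred per study at the mode of the joint density of data and latent
effects, with the curvature there setting the scale. The inner mode
search uses analytic Newton steps, so the whole likelihood is a few
vectorised matrix operations per evaluation. Optimisation runs on the
unconstrained scale $(\beta_1, \beta_0, \log\tau_1, \log\tau_0,
\mathrm{atanh}\,\rho)$, Nelder–Mead followed by BFGS polish, with up to
five jittered restarts; convergence is declared at a relative
log-likelihood change below the optimiser defaults (about $10^{-10}$).
Starting values are logits of continuity-corrected pooled proportions —
the correction seeds the optimiser and never enters the likelihood.
Estimates move by less than $10^{-3}$ logit units when the grid grows
from $10^2$ to $20^2$ nodes on the packaged datasets (tested).

`fit_bivariate_bayes()` estimates the same model by Gibbs sampling
(JAGS), with $N(0, 100\,000)$ priors on $\beta_1, \beta_0$ and a
Wishart prior on $\Omega^{-1}$. The Wishart hyperparameters are a
genuine design choice: we default to scale $0.1 I$ with 2 degrees of
freedom — the smallest proper choice, weakly informative on the
between-study SDs over the range seen in accuracy meta-analyses — and
expose both through `priors` so a sensitivity analysis is a one-line
rerun. With few studies (the 5-study examples) the posterior for
$\tau$'s is noticeably prior-sensitive; the posterior medians for the
mean logits are not, and agree with maximum likelihood to well under
0.05 on the probability scale for all packaged datasets (tested).
Defaults follow the conventional long single run (10 000 burn-in,
100 000 retained), but two chains with split-$\widehat{R}$ are the
default so non-convergence is visible rather than assumed away.

### Statements about a new population

At each retained iteration the sampler also draws one *predictive* pair
$(\mathrm{logit}\,p_1^{new}, \mathrm{logit}\,p_0^{new}) \sim N((\beta_1,
\beta_0), \Omega)$ at that iteration's parameter values. Every
new-population statement is then a Monte Carlo summary of these draws,
with parameter uncertainty fully propagated: `prediction_interval()`
(equal-tailed), `joint_probability()` (the fraction of draws with both
margins above thresholds, with its Monte Carlo SE), and
`prediction_region()` (a highest-density contour found by 2-D binning
of the draws — no kernel smoothing, so no bandwidth to justify).

The frequentist counterpart `prediction_interval_t()` uses
$\hat\beta \pm t_{k-2}\sqrt{\hat\tau^2 + \mathrm{Var}(\hat\beta)}$; the
$t$ with $k-2$ degrees of freedom partially accounts for the estimated
between-study variance. The frequentist `prediction_region()` is an
ellipse on the logit plane with shape $\hat\Omega +
\mathrm{Var}(\hat\beta)$; the boundary radius is chi-square(2) by
default because the exact small-sample distribution of the bivariate
problem is not available in closed form, and a Hotelling-style
$F$-radius with $k-2$ degrees of freedom sits behind `type = "t"` for
users who prefer conservative small-$k$ regions. Probability
statements, by contrast, are refused for ML fits rather than computed
by plugging in point estimates: a point estimate has no predictive
distribution, and silently ignoring parameter uncertainty would
overstate certainty exactly where the method is meant to expose it.

### Post-test probabilities and their calibration

Three rules convert a meta-analysis into a PPV and NPV for a population
$L$:

* **Option A** (`option_a()`): Bayes' theorem at the summary
  sensitivity, specificity and *summary prevalence*, the latter pooled
  from cohort studies by a univariate binomial logit-normal model
  (`fit_prevalence_meta()`).
* **Option B** (`option_b()`): the same with the *local* prevalence of
  the target population. The API makes the caller state whether that
  prevalence is known or an observed-sample proxy, and records it.
* **Option C** (`fit_ppv_npv_metareg()` + `option_c_predict()`): a
  bivariate binomial model for PPV and NPV directly (diseased among
  test positives, non-diseased among test negatives) with study
  prevalence as a covariate on the natural scale. The covariate is
  centred internally at the mean observed prevalence and reported
  uncentred. A logit-prevalence covariate variant is deliberately not
  offered.

`run_iocv()` validates any of these by internal–external
cross-validation: omit a (cohort) study, rebuild the rule from the
rest, predict PPV/NPV for the omitted study, and compare expected
events $E = PPV\cdot n_+ + (1-NPV)\cdot n_-$ with observed events $O =
n_1$. Case-control studies are never omitted (their observed risk is
biased) but still inform the accuracy model in options A/B. Each
cycle's fits reuse the previous cycle's estimates as warm starts;
results are identical to cold starts within optimiser tolerance
(tested). The per-cycle $\ln(O/E)$ values, with SEs treating the
expected proportion as fixed
($s_L = \sqrt{(1-P_O)/(N P_O)}$), are pooled by DerSimonian–Laird
(`meta_oe()`), with a $t_{k-2}$ prediction interval for the O/E of a
new population, or by an MCMC analogue with a $U(0, 0.25)$ prior on
the between-study SD and posterior predictive probabilities such as
$P(0.9 < O/E < 1.1)$.

When a cycle has no events (or no non-events) in one test arm,
$\ln(O/E)$ has no SE; those cycles are excluded from the
normal-approximation pooling with a notice and handled by the *exact*
calibration model (`fit_exact_calibration()`): a random-intercept
binomial-logit model with the predicted logit-PPV (or NPV) as a fixed
offset,
$$r_L \sim \mathrm{Bin}(n_L, p_L), \quad
  \mathrm{logit}\,p_L = \alpha_L + \mathrm{logit}(pred_L), \quad
  \alpha_L \sim N(a, \tau_a^2).$$
$a$ is the average log odds ratio of observed to predicted odds — the
calibration-in-the-large, 0 when calibration is perfect on average.
The ML fit optimises $(a, \tau_a)$ with $\tau_a$ boxed at zero, so the
common no-heterogeneity boundary is an admissible estimate rather than
a numerical accident; when $\hat\tau_a = 0$ the SE of $\hat a$ is the
observed-information SE at the boundary. The Bayesian variant uses
$N(0, 1\,000\,000)$ on $a$ and $U(0, 1)$ on $\tau_a$; with five
studies the results are visibly prior-sensitive, which the model
reports rather than hides. Offsets at exactly 0 or 1 are clipped to
$\mathrm{logit}(10^{-6})$ with a warning.

### c statistics

For continuous tests, `c_statistic()` is the Mann–Whitney estimator
(midranks, so ties count one half), `bootstrap_se_c()` a
class-stratified bootstrap (the stratification keeps prevalence fixed,
so no replicate degenerates to a single class), and pooling is on the
raw $c$ scale — not logit — by `fit_re_moments()` /
`c_prediction_interval()` (truncation to $[0,1]$ happens at report
time; internal values are untruncated) or `bayes_c_meta()` with
$\mu_c \sim U(0.5, 1)$ and $\tau_c \sim U(0, 0.25)$.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws from exactly the generative model above:
bivariate normal accuracy latents, an independent logit-normal
prevalence, binomial sampling within studies. Its defaults are chosen
to resemble the ear-thermometry meta-analysis that motivates the
package — $\beta_1 = 0.62$, $\beta_0 = 4.0$ (summary sensitivity 0.65,
specificity 0.98), $\tau_1 = 0.9$, $\tau_0 = 0.8$, $\rho = -0.6$,
prevalence near one half with $\tau_\alpha = 0.45$, and 40–900
patients per study. Degenerate draws (no diseased or no non-diseased
patients) are redrawn with a capped retry budget rather than
conditioned on, for simplicity. `simulate_cstat_collection()` uses the
binormal model in which diseased scores are $N(\sqrt{2}\,
\Phi^{-1}(\theta_i), 1)$ against standard-normal non-diseased scores,
so the population AUC equals the latent $\theta_i$ exactly.

Because the simulator and the fitters share the same model family,
parameter-recovery tests demonstrate *internal* correctness — the
estimators find the truth that generated the data — not robustness to
real-world violations: non-normal random effects, threshold drift
correlated with prevalence, verification bias, or imperfect reference
standards are all outside the generative model, and passing tests say
nothing about them. The one deliberate extension is `prev_coupling`,
which links prevalence to the sensitivity latent for stress-testing
prevalence-aware prediction rules.

## Numerical and design notes

* Problem sizes in the test suite: parameter recovery uses up to 200
  simulated studies of 500–2000 patients; the calibrated-simulation
  check uses 20 studies of $10^5$ patients; MCMC unit tests run short
  chains (2000–20 000 draws) while the end-to-end reproduction tests
  use the full 10 000 + 100 000 schedule.
* The DerSimonian–Laird step is implemented in closed form (and
  cross-checked against `metafor::rma(method = "DL")` in the tests)
  because the prediction interval must use $t_{k-2}$ and the pooling
  must stay exactly reproducible inside the cross-validation engine.
* The univariate binomial logit-normal fitter behind
  `fit_prevalence_meta()` and `fit_exact_calibration()` shares one
  code path (the prevalence model is the offset model with offset 0).
  Generic mixed-model software struggles on these fits precisely where
  they are most needed — offsets with all-success arms; the in-package
  fitter handles the boundary explicitly and is cross-checked against
  `lme4::glmer` on interior data in the tests.
* Reported probabilities are full precision in objects and JSON, and
  rounded only in print methods.

## Known limitations

* No HSROC parameterisation and no summary ROC curve; no covariates on
  sensitivity/specificity; no trivariate accuracy–prevalence model.
* Normality of the random effects across studies is assumed
  throughout, including in every prediction interval; with fewer than
  about 10 studies the intervals are wide and (in the Bayesian case)
  prior-sensitive, and the package reports rather than suppresses
  this.
* Prediction intervals inherit the quality of the included studies:
  with biased studies they widen to cover bias, not just genuine
  setting-to-setting variation.
* Binary outcomes only; censored (time-to-event) outcomes are out of
  scope.

## A compact example

```{r example, eval = FALSE}
d <- load_fixture("temperature")
ml <- fit_bivariate_ml(d)
summary_accuracy(ml)
prediction_interval_t(ml, "sensitivity")

bay <- fit_bivariate_bayes(d, seed = 1)
joint_probability(bay, 0.8, 0.8)

rec <- run_iocv(d, option = "A")
meta_oe(rec)
fit_exact_calibration(rec, scope = "ppv")
```
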