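---
title: "Assurance for survival-endpoint trials: models, priors and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assurance for survival-endpoint trials: models, priors and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survassure)
```

## What assurance computes

Power conditions on one assumed treatment effect; assurance integrates
the probability of a successful trial over a prior for the effect:

$$\gamma = \int P(\mathrm{success} \mid \theta) f(\theta)\, d\theta .$$

Throughout this package "success" means the planned frequentist test
rejects at its two-sided level $\alpha$ *and* the estimate favours the
experimental arm (group 2): the success probability is the single
lower-tail term $\Phi(-\theta/\mathrm{se} - z_{1-\alpha/2})$, never the
two-sided $|\theta|$ form used for power. This makes assurance a hybrid
quantity: the analysis of the trial stays frequentist, the prior enters
only at the design stage. Two consequences shape every example below:

* assurance at any $N$ cannot exceed the prior probability that the
  experimental arm is truly superior (the *cap*), and converges to it
  as $N \to \infty$;
* a degenerate (point-mass) prior collapses assurance to the one-sided
  power at that point — the property the test suite uses to validate
  every Monte Carlo route against its analytic counterpart.

All three trial models share the accrual assumptions: patients enter
uniformly over $(0, R)$, follow-up ends at calendar time $T \ge R$, and
survival time runs on the patient clock, so a random patient's
administrative censoring time is uniform on $[T-R,\, T]$.

## The three analysis models

### Exponential

Hazards $\lambda_1, \lambda_2$; effect $\theta =
\log(\lambda_2/\lambda_1)$, the log of the median ratio. The event
probability under uniform accrual has the closed form

$$P_{ie} = 1 - \frac{e^{-\lambda_i (T-R)} - e^{-\lambda_i T}}
{\lambda_i R},$$

which the tests verify against direct numerical integration to
$10^{-10}$ across a log-spaced grid of rates. Power uses the asymptotic
variance $1/d_1 + 1/d_2$ with expected events $d_i = N_i P_{ie}$. The
formula is asymptotic in the *event count*, not the sample size: at
roughly 17 expected events in an arm the exact test rejects about 3
points more often than the formula predicts, so simulation validation
is performed at design points with at least ~45 events per arm. With
fewer events than that, treat the formula (and hence the assurance) as
approximate.

Priors are set on observables: $S_1(t_0) $ (beta by convention) and the
survival difference $\rho = S_2(t_0) - S_1(t_0)$ (normal), assumed
independent, with $\rho$ truncated per draw to $(-S_1, 1 - S_1)$.
Rates follow from $\lambda_i = -\log S_i(t_0) / t_0$.

### Weibull

Survivor $S(t) = e^{-\lambda t^{\kappa}}$. Two elicited rates at anchor
times $t_0 < t_0'$ identify the parameters,
$\kappa = \log(\log S_b / \log S_a)/\log(t_0'/t_0)$,
$\lambda = -\log S_a / t_0^{\kappa}$; the round trip through the
survivor function is exact to $10^{-10}$ and tested on random inputs.
The analysis compares mean survival with a Welch $t$-test
(Satterthwaite degrees of freedom — the standard meaning of "Welch").
Because the analysis uses sample means of survival times, it assumes
*complete observation*: the recruitment and follow-up lengths play no
role in this model, and the assurance simulation generates uncensored
times. That is a real restriction, not an implementation shortcut; a
censored-data Weibull likelihood analysis is out of scope.

The four elicited observables are $S_1(t_0)$ and the differences
$\delta_{11} = S_1(t_0) - S_1(t_0')$,
$\delta_{12} = S_2(t_0) - S_1(t_0)$,
$\delta_{22} = S_2(t_0) - S_2(t_0')$, a priori independent. Draws are
truncated sequentially — $\delta_{11}$ given $S_1(t_0)$, $\delta_{12}$
given $S_1(t_0)$, $\delta_{22}$ given the implied $S_2(t_0)$ — so every
rate stays in $(0,1)$ and each group's survivor decreases. The order
matters only through which constraint binds first; the sequential form
mirrors how the quantities are elicited. An odds-ratio
parameterisation (lognormal priors on within- and between-group odds
ratios) is available behind a flag; differences are the default.

### Proportional hazards / logrank

Hazard ratio $\phi = h_2/h_1$, $\theta = \log \phi$; Schoenfeld power
$\Phi(|\theta| \sqrt{N P_e Q_1 Q_2} - z_{1-\alpha/2})$ with $N$ the
total sample size. $P_e$ needs the control survivor curve only through
$\int_{T-R}^{T} S_1(u)\, du$, estimated by composite Simpson quadrature
($H$ odd nodes, weights $1,4,2,\dots,4,1$), and
$P_{2e}$ uses $S_1(u)^{e^{\theta}}$. The default $H = 11$ is the
convention under which the package's worked event probability equals
0.42; exact integration of the same step function gives 0.415, a
reminder that $P_e$ inherits the quadrature convention when the curve
is a Kaplan–Meier step function. Quadrature over/undershoot on step
functions is clipped to $[0,1]$ with a warning.

When no control data exist, beliefs about $P_{1e}$, $S_1(t_0)$ and
$\rho$ are elicited directly. Evaluating $P_{2e}$ then requires a curve
*shape*; the package takes the exponential curve reproducing the drawn
$P_{1e}$ under the design's accrual (solved by root finding on the
closed form). This is a deliberate, isolated modelling choice: only
$P_{1e}$ is elicited, and some shape must carry it to $P_{2e}$.

## Historical control data

### Gamma power prior (exponential model)

With exponential control survival, historical data enter through the
conjugate update
$\mathrm{Gamma}(s_0 + a_0 \sum d_i,\; r_0 + a_0 \sum t_i)$, the
historical likelihood raised to $a_0 \in [0,1]$. $a_0 = 0$ ignores the
data, $a_0 = 1$ borrows fully, and the posterior mean moves
monotonically between the two — the downweighting is how differences
between historical and new-trial populations are acknowledged.

### Dirichlet-process posterior (proportional hazards)

The control survivor function gets a Dirichlet-process prior with
precision $c_0$ and shape survivor $G$
($\alpha([t,\infty)) = c_0 G(t)$): on any partition of the time axis
the interval probabilities are Dirichlet with parameters
$c_0\{G(t_{k-1}) - G(t_k)\}$. $G$ is exponential by default, its rate
solved from one elicited anchor (e.g. a 50% five-month survival gives
rate $\log 2 / 5$); $c_0$ is the weight of that opinion in
pseudo-observations — $c_0 = 1$ against 8 real observations is
data-dominant, $c_0 \to \infty$ recovers $G$.

Right censoring is handled by Gibbs sampling: censoring times are cut
points of the partition, so each censored subject's unobserved event
lies in some later interval; conditional on the probabilities the
allocation is multinomial with $\eta_{j,k} = p_j / \sum_{l>k} p_l$, and
conditional on complete counts the Dirichlet update is conjugate. With
no censoring the chain collapses to i.i.d. conjugate draws, which the
tests exploit: the Gibbs marginals must match the direct Dirichlet
posterior (Kolmogorov distance < 0.02).

Numerical conventions here, each with a reason:

* **Partition starts at 0**, not at $T-R$, so observations earlier than
  the follow-up window (the pilot data have events at 0.8 and 3.1,
  before $T-R = 5$) still inform the posterior; quadrature nodes remain
  confined to $[T-R, T]$.
* **Coinciding cut points are merged** (a censoring time equal to a
  node), with a message; for the pilot data and $H = 11$ this yields 14
  cut points / 15 intervals.
* **Step convention**: $S_1(t)$ at a cut point is the tail sum of
  interval probabilities beyond it (right-continuous, matching the
  Kaplan–Meier convention); $t_0$ is inserted as a cut point so no
  interpolation is ever needed. Ties between events and censorings at
  one time are resolved events-first, likewise the product-limit
  convention.
* **Initialisation at the prior means**, burn-in 1000 of 11000
  iterations by default, no thinning: the chain is a low-dimensional
  Dirichlet and mixes in tens of iterations; the defaults are
  deliberately generous and overridable.

## Elicitation and fitting

Two judgement formats are supported: quartiles and trial-roulette chips
(equal-width bins, chip share = probability). Both are fitted by least
squares *on the probability scale* — minimise
$\sum_k (F(q_k) - p_k)^2$ for quartiles and the same over bin masses
for roulette — one objective for both formats, since reasonable
alternatives (quantile-scale loss) differ only when the family cannot
match the judgements anyway. The optimiser is BFGS from moment-matched
starting values with two variance-perturbed restarts, polished by
Nelder–Mead (beta sum-of-squares surfaces can be flat); parameters are
log-transformed where positive. Realisable judgements are recovered
essentially exactly (SSQ < $10^{-6}$ in the tests); for inconsistent
judgements the achieved SSQ is attached to the fitted prior as
feedback, which is how an elicitation session should decide whether the
fit is adequate.

Truncation of any prior is by renormalisation via the inverse CDF —
draws are mapped through $F^{-1}(U(F(l), F(u)))$ — never by clipping or
rejection, so truncated sampling is exact and rejection-free even when
bounds depend on another draw (as they do for $\rho$ and the
$\delta$'s). A point prior with bounds excluding its value is an error,
as is a truncation interval carrying no mass.

## Monte Carlo conventions

* Defaults: $M = 10^5$ for the analytic-success-probability models
  (exponential, logrank), $M = 2000$ for the Weibull model, where each
  iteration simulates a full trial of $N_1 + N_2$ survival times
  (chunked to bound memory at ~5 million draws).
* The reported standard error is the conservative binomial
  $\sqrt{\hat\gamma(1-\hat\gamma)/M}$.
* Curves over $N$ reuse one set of prior draws (common random numbers),
  so Monte Carlo noise shifts a curve coherently instead of roughening
  it; with the same seed a curve reproduces exactly.
* Every stochastic function takes an explicit `seed` and restores the
  caller's RNG state afterwards; nothing depends on global seeding.
* The MC route for a normal-$\theta$, fixed-$P_e$ logrank assurance is
  cross-checked against 64-point Gauss–Hermite quadrature of the same
  integral to $10^{-3}$.

## What the simulated data do and do not emulate

`simulate_survival_data()` generates exactly the design's stochastic
mechanism: uniform entry, exponential or Weibull survival,
administrative censoring at $T$. That suffices to validate the event
probability formulas and the power formulas by brute force (simulated
rejection rates of the actual tests — the exponential MLE test, the
known-variance $z$-test, `survival::survdiff`'s logrank — agree with
the formulas within 2.5 Monte Carlo standard errors at three design
points each). It deliberately omits features of real trials: loss to
follow-up other than administrative censoring, non-uniform accrual,
covariates, and interim looks. Passing tests therefore certify the
calculations under the stated design assumptions, not robustness to
their violation.

Problem sizes used by the test and acceptance runs — chosen so each
Monte Carlo comparison has standard error well under its tolerance —
are: $10^6$ draws for prior-probability checks, 1200–4000 simulated
trials per power design point, 10000–20000 Gibbs draws for posterior
checks, and $M \le 10^4$ for assurance curves.

## Known limitations

* The exponential and logrank power formulas are asymptotic; with
  fewer than ~45 events per arm their error is visible (a few
  percentage points), and assurance inherits it.
* The Weibull mean-survival analysis assumes complete observation and
  normal-ish sample means; for shapes near 0.4 the skewness of survival
  times makes the normal approximation converge slowly, so
  extreme-power statements (power > 0.98) at moderate $N$ are the least
  reliable part of that model.
* With a tight prior on $\rho$ the proportional-hazards assurance
  tracks the Kaplan–Meier-based power curve closely at high power but
  can sit up to ~0.09 above it at mid power when the control posterior
  rests on very few observations (8 in the shipped pilot data): the
  success probability is convex in $\theta$ there, so posterior spread
  in the survivor curve raises the average. This is a genuine feature
  of averaging over baseline uncertainty, not Monte Carlo error.
* The prior superiority cap is estimated by Monte Carlo alongside the
  assurance; near-degenerate priors can make the cap estimate itself
  the dominant uncertainty.
* Multi-expert pooling and interactive elicitation interfaces are out
  of scope; judgement files are plain text and fits are reproducible
  functions of them.
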