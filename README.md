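# survassure

Assurance and power calculations for two-arm clinical trials with
time-to-event endpoints.

## The problem

A conventional sample-size calculation fixes the treatment effect at a
single assumed value and chooses the number of patients so that the
planned hypothesis test has a desired power, e.g.

$$P(\text{reject } H_0 \mid \theta = \theta_A) \ge \pi^*.$$

But the true effect is unknown at the planning stage, so power does not
answer the question the sponsor actually cares about: *what is the
probability that this trial will succeed?* The **assurance** of a trial
answers it by averaging the success probability over a prior
distribution for the effect,

$$\gamma = \int P(\text{success} \mid \theta)\, f(\theta)\, d\theta,$$

where "success" here means rejecting the null with the data favouring
the experimental arm. Assurance behaves very differently from power as
the sample size grows: it converges not to 1 but to the prior
probability that the experimental treatment is truly superior — you
cannot beat the prior.

`survassure` implements assurance for survival endpoints under three
analysis models, each with uniform patient accrual over a recruitment
window $(0, R)$ and total trial length $T$:

* **Exponential survival**, analysed with the asymptotic test of equal
  median survival: power
  $\pi^E = \Phi\bigl(|\theta| / \sqrt{1/(N_1 P_{1e}) + 1/(N_2 P_{2e})} -
  z_{1-\alpha/2}\bigr)$ with $\theta = \log(\lambda_2/\lambda_1)$ and
  per-group event probabilities
  $P_{ie} = 1 - \{e^{-\lambda_i(T-R)} - e^{-\lambda_i T}\}/(\lambda_i R)$.
* **Weibull survival**, analysed by comparing mean survival times with a
  Welch two-sample *t*-test; group parameters are recovered from
  elicited survival rates at two anchor times.
* **Proportional hazards** with a nonparametric control survivor
  function, analysed with the logrank test: Schoenfeld power
  $\pi^P = \Phi\bigl(|\theta|\sqrt{N P_e Q_1 Q_2} - z_{1-\alpha/2}\bigr)$,
  where $P_e$ comes from Simpson quadrature of the survivor curve over
  the follow-up window $[T-R, T]$.

Priors are built from expert judgements about *observable* survival
rates — quartiles or "trial roulette" chip allocations, fitted by least
squares — rather than about model parameters. For the proportional
hazards model, historical control data (right-censored) can be combined
with a Dirichlet-process prior on the control survivor function; a
Gibbs sampler (multinomial imputation of censored event intervals +
conjugate Dirichlet updates) produces posterior survivor draws that
feed directly into the assurance calculation. Exponential-model control
data can instead be borrowed through a conjugate gamma power prior.

## Worked example

A trial with a 3-year recruitment period and 2 further years of
follow-up; 60% of control patients are expected to survive 5 years, and
the experimental treatment is hoped to raise that by 20 points. An
expert's uncertainty is summarised as $S_1(5) \sim \mathrm{Beta}(60,40)$
and $\rho = S_2(5) - S_1(5) \sim N(0.2, 0.05)$:

```r
library(survassure)

design <- trial_design(R = 3, T = 5, N1 = 100, N2 = 100)
s1  <- prior_spec("beta", shape1 = 60, shape2 = 40)
rho <- prior_spec("normal", mean = 0.2, var = 0.05)

assurance_exponential(s1, rho, t0 = 5, design, M = 1e5, seed = 42)
#> <assurance_result> model = exponential
#>   assurance = 0.4708 (MC SE 0.0016, M = 1e+05)
#>   prior P(superiority) = 0.7688 (cap as N -> Inf)
#>   seed = 42
```

With 100 patients per arm there is only a 47% chance of a successful
trial, even though the power at the assumed rates
($\lambda_1 = 0.102$, $\lambda_2 = 0.0446$) is 73%. The curve shows the
cap at work — power races to 1, assurance flattens towards the 77%
prior probability that the new treatment is better at all:

```r
assurance_curve("exponential", list(s1 = s1, rho = rho, t0 = 5),
                design, N_grid = c(50, 100, 200, 400, 1000),
                M = 2e4, seed = 42, power_params = c(0.102, 0.0446))
#>      N assurance      se power
#> 1   50     0.336 0.00334 0.445
#> 2  100     0.473 0.00353 0.731
#> 3  200     0.572 0.00350 0.954
#> 4  400     0.637 0.00340 0.999
#> 5 1000     0.690 0.00327 1.000
```

A classical sample-size search for 80% power gives 119 patients per
group (`sample_size_for_power()`), a target the assurance can never
reach under this prior — exactly the insight the method is for.

The vignette (`vignettes/assurance-survival-trials.Rmd`) walks through
the Weibull and proportional-hazards analyses, including fitting priors
to elicited quartiles and running the Dirichlet-process Gibbs sampler
on the shipped 8-observation pilot dataset (`km_pilot_data()`).

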