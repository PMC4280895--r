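#' Exponential hazard rate from a survival rate
#'
#' Inverts the exponential survivor function `S(t0) = exp(-lambda * t0)`.
#'
#' @param S Survival rate at time `t0`, in (0, 1).
#' @param t0 Anchor time, positive.
#' @return Hazard rate `lambda = -log(S) / t0`.
#' @examples
#' lambda_from_survival(0.6, 5)  # 0.102
#' @export
lambda_from_survival <- function(S, t0) {
  if (any(S <= 0) || any(S >= 1)) stop("S must lie in (0, 1)", call. = FALSE)
  if (any(t0 <= 0)) stop("t0 must be positive", call. = FALSE)
  -log(S) / t0
}

#' Log median ratio for exponential survival
#'
#' The treatment effect is `theta = log(m1 / m2) = log(lambda2 / lambda1)`
#' where `m_i = log(2) / lambda_i` is the median survival time in group i.
#' `theta < 0` means the experimental group (group 2) survives longer.
#'
#' @param lambda1,lambda2 Hazard rates of the control and experimental
#'   groups.
#' @return The log median ratio.
#' @export
theta_exponential <- function(lambda1, lambda2) {
  if (any(lambda1 <= 0) || any(lambda2 <= 0)) {
    stop("hazard rates must be positive", call. = FALSE)
  }
  log(lambda2 / lambda1)
}

#' Probability of observing the event during the trial (exponential)
#'
#' With uniform entry over (0, R) and administrative censoring at T, a
#' patient with exponential hazard `lambda` has follow-up `T - a` for
#' entry time `a ~ U(0, R)`, so the event probability is
#' \deqn{P_e = 1 - \frac{1}{R}\int_0^R e^{-\lambda (T-a)}\,da
#'           = 1 - \frac{e^{-\lambda (T-R)} - e^{-\lambda T}}{\lambda R}.}
#'
#' @param lambda Hazard rate (vectorised).
#' @param design A [trial_design()].
#' @return Event probability in (0, 1).
#' @examples
#' d <- trial_design(R = 3, T = 5, N1 = 100)
#' event_prob_exponential(0.102, d)
#' @export
event_prob_exponential <- function(lambda, design) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  R <- design$R; T <- design$T
  1 - (exp(-lambda * (T - R)) - exp(-lambda * T)) / (lambda * R)
}

# asymptotic SE of the log median-ratio estimate: 1/d1 + 1/d2 with
# expected events d_i = N_i * P_ie
theta_se_exponential <- function(lambda1, lambda2, design) {
  p1e <- event_prob_exponential(lambda1, design)
  p2e <- event_prob_exponential(lambda2, design)
  sqrt(1 / (design$N1 * p1e) + 1 / (design$N2 * p2e))
}

#' Power of the two-sided exponential survival test
#'
#' Asymptotic power of the two-sided level-`alpha` test of equal median
#' survival, based on the log median-ratio statistic with variance
#' `1/d1 + 1/d2` (`d_i` the expected event count in group i):
#' \deqn{\pi^E = \Phi\!\left(\frac{|\theta|}{\sqrt{1/(N_1 P_{1e}) +
#'   1/(N_2 P_{2e})}} - z_{1-\alpha/2}\right).}
#'
#' @param lambda1,lambda2 Hazard rates (vectorised).
#' @param design A [trial_design()].
#' @return Power in (0, 1); equals `alpha/2` when the rates are equal.
#' @export
power_exponential <- function(lambda1, lambda2, design) {
  theta <- theta_exponential(lambda1, lambda2)
  se <- theta_se_exponential(lambda1, lambda2, design)
  z <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm(abs(theta) / se - z)
}

# one-sided success probability: reject H0 with the estimate favouring
# the experimental arm (theta_hat below the lower critical value)
success_prob_exponential <- function(lambda1, lambda2, design) {
  theta <- theta_exponential(lambda1, lambda2)
  se <- theta_se_exponential(lambda1, lambda2, design)
  z <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm(-theta / se - z)
}

#' Assurance under the exponential survival model
#'
#' Monte Carlo estimate of the unconditional probability that the trial
#' rejects the null hypothesis of equal median survival *with the data
#' favouring the experimental arm*. Per iteration: draw
#' `(S1(t0), S2(t0))` from the joint elicited prior
#' ([sample_joint_rates()]), convert to hazard rates, and accumulate the
#' one-sided asymptotic success probability.
#'
#' Alternatively, a gamma distribution for the control hazard rate (for
#' example a power-prior posterior from [power_prior_control_rate()]) can
#' replace the elicited `s1_prior`: the control rate is then drawn from
#' the gamma and mapped to `S1(t0) = exp(-lambda1 * t0)` before the
#' difference `rho` is applied.
#'
#' @param s1_prior Prior for the control survival rate S1(t0), supported
#'   on (0, 1). Ignored when `lambda1_prior` is supplied.
#' @param rho_prior Prior for the survival difference
#'   `rho = S2(t0) - S1(t0)`; truncated per draw so S2(t0) stays in (0,1).
#' @param t0 Anchor time of the elicited survival rates.
#' @param design A [trial_design()].
#' @param M Number of Monte Carlo iterations.
#' @param seed Optional integer seed.
#' @param lambda1_prior Optional `gamma_prior` for the control hazard
#'   rate (see [power_prior_control_rate()]).
#' @return An [assurance_result()]; `superiority` is the Monte Carlo
#'   estimate of the prior probability `P(S2(t0) > S1(t0))`, the cap the
#'   assurance cannot exceed.
#' @examples
#' d <- trial_design(R = 3, T = 5, N1 = 150)
#' s1 <- prior_spec("beta", shape1 = 60, shape2 = 40)
#' rho <- prior_spec("normal", mean = 0.2, var = 0.05)
#' assurance_exponential(s1, rho, t0 = 5, d, M = 10000, seed = 1)
#' @export
assurance_exponential <- function(s1_prior, rho_prior, t0, design,
                                  M = 1e5, seed = NULL,
                                  lambda1_prior = NULL) {
  stopifnot(M >= 1, t0 > 0)
  with_seed_(seed, {
    draws <- draw_exponential_rates_(s1_prior, rho_prior, t0, M,
                                     lambda1_prior)
    gam <- mean(success_prob_exponential(draws$lambda1, draws$lambda2,
                                         design))
    assurance_result(gam, M, superiority = mean(draws$rho > 0),
                     model = "exponential", seed = seed)
  })
}

# shared draw step (also used by assurance_curve with common random numbers)
draw_exponential_rates_ <- function(s1_prior, rho_prior, t0, M,
                                    lambda1_prior = NULL) {
  if (is.null(lambda1_prior)) {
    r <- sample_joint_rates(s1_prior, rho_prior, M)
  } else {
    stopifnot(inherits(lambda1_prior, "gamma_prior"))
    lam1 <- stats::rgamma(M, shape = lambda1_prior$shape,
                          rate = lambda1_prior$rate)
    s1 <- exp(-lam1 * t0)
    lo <- pmax(-s1, rho_prior$lower %||% -Inf)
    hi <- pmin(1 - s1, rho_prior$upper %||% Inf)
    rho <- sample_prior(rho_prior, M, lower = lo, upper = hi)
    r <- data.frame(s1 = s1, s2 = s1 + rho, rho = rho)
  }
  r$lambda1 <- lambda_from_survival(r$s1, t0)
  r$lambda2 <- lambda_from_survival(r$s2, t0)
  r
}

#' Power-prior update for the control hazard rate
#'
#' Conjugate gamma update of the exponential control-arm hazard from
#' historical data, with the historical likelihood raised to a weight
#' `a0` in [0, 1] (a power prior). `a0 = 0` returns the baseline prior
#' unchanged; `a0 = 1` is full borrowing.
#'
#' @param data A [survival_data()] of historical control observations.
#' @param a0 Downweighting power in [0, 1].
#' @param shape0,rate0 Baseline gamma hyperparameters (default a vague
#'   `Gamma(0.001, 0.001)`).
#' @return A `gamma_prior` list with `shape` and `rate`; its mean
#'   `shape/rate` moves monotonically from the baseline mean at `a0 = 0`
#'   to the full-data posterior mean at `a0 = 1`.
#' @examples
#' h <- survival_data(time = c(4, 10, 16), status = c(1, 1, 1))
#' power_prior_control_rate(h, a0 = 1, shape0 = 1e-9, rate0 = 1e-9)
#' @export
power_prior_control_rate <- function(data, a0, shape0 = 0.001,
                                     rate0 = 0.001) {
  stopifnot(inherits(data, "survival_data"), nrow(data) >= 1)
  if (a0 < 0 || a0 > 1) stop("a0 must lie in [0, 1]", call. = FALSE)
  structure(
    list(shape = shape0 + a0 * sum(data$status),
         rate = rate0 + a0 * sum(data$time)),
    class = "gamma_prior"
  )
}
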