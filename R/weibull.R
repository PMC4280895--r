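#' Weibull parameters from survival rates at two times
#'
#' Under the survivor function `S(t) = exp(-lambda * t^kappa)`, two
#' survival rates `S_a = S(t0)` and `S_b = S(t0p)` with `t0 < t0p`
#' determine the parameters:
#' \deqn{\kappa = \frac{\log\{\log S_b / \log S_a\}}{\log(t_0'/t_0)},
#'   \qquad \lambda = -\log(S_a) / t_0^\kappa.}
#'
#' @param S_a,S_b Survival rates at `t0` and `t0p`; `0 < S_b < S_a < 1`
#'   (survivor functions decrease).
#' @param t0,t0p Anchor times, `0 < t0 < t0p`.
#' @return Named vector `c(shape = kappa, scale = lambda)`. Note `scale`
#'   is the lambda of `exp(-lambda t^kappa)`; the corresponding
#'   `stats::rweibull` scale is `lambda^(-1/kappa)`.
#' @examples
#' weibull_from_two_rates(0.2, 0.1, 1, 2)  # shape 0.52, scale 1.61
#' @export
weibull_from_two_rates <- function(S_a, S_b, t0, t0p) {
  if (any(t0 <= 0) || any(t0p <= t0)) {
    stop("need 0 < t0 < t0p", call. = FALSE)
  }
  if (any(S_a <= 0) || any(S_a >= 1) || any(S_b <= 0) || any(S_b >= S_a)) {
    stop("need 0 < S_b < S_a < 1 (survivor function must decrease)",
         call. = FALSE)
  }
  kappa <- unname(log(log(S_b) / log(S_a)) / log(t0p / t0))
  lambda <- unname(-log(S_a) / t0^kappa)
  if (length(kappa) == 1L) c(shape = kappa, scale = lambda)
  else cbind(shape = kappa, scale = lambda)
}

#' Mean and variance of a Weibull survival time
#'
#' For `S(t) = exp(-lambda * t^kappa)`:
#' \deqn{\mu = \lambda^{-1/\kappa}\,\Gamma(1 + 1/\kappa), \qquad
#'   \sigma^2 = \lambda^{-2/\kappa}\left\{\Gamma(1 + 2/\kappa) -
#'   \Gamma(1 + 1/\kappa)^2\right\}.}
#'
#' @param shape,scale Weibull parameters (kappa, lambda), positive.
#'   Shapes below `1e-3` are rejected: the moment formulas overflow as
#'   `kappa -> 0`.
#' @return Named vector (or matrix, for vector input) with `mean` and
#'   `var`.
#' @examples
#' weibull_moments(0.52, 1.61)  # mean 0.75
#' @export
weibull_moments <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0)) {
    stop("shape and scale must be positive", call. = FALSE)
  }
  if (any(shape < 1e-3)) {
    stop("shape below 1e-3: moments overflow", call. = FALSE)
  }
  shape <- unname(shape); scale <- unname(scale)
  mu <- scale^(-1 / shape) * gamma(1 + 1 / shape)
  v <- scale^(-2 / shape) * (gamma(1 + 2 / shape) - gamma(1 + 1 / shape)^2)
  if (length(mu) == 1L) c(mean = mu, var = v) else cbind(mean = mu, var = v)
}

#' Power of the two-sided test of equal mean survival (Weibull)
#'
#' Normal-approximation power for comparing mean survival times of two
#' Weibull groups with (population) variances treated as known:
#' \deqn{\pi^W = \Phi\!\left(\frac{|\mu_1-\mu_2|}
#'   {\sqrt{\sigma_1^2/N_1 + \sigma_2^2/N_2}} - z_{1-\alpha/2}\right).}
#' This analysis observes complete survival times; the design's
#' recruitment and follow-up lengths play no role here.
#'
#' @param shape1,scale1,shape2,scale2 Weibull parameters per group.
#' @param design A [trial_design()] (only `N1`, `N2`, `alpha` are used).
#' @return Power in (0, 1).
#' @export
power_weibull <- function(shape1, scale1, shape2, scale2, design) {
  m1 <- weibull_moments_vec_(shape1, scale1)
  m2 <- weibull_moments_vec_(shape2, scale2)
  se <- sqrt(m1$var / design$N1 + m2$var / design$N2)
  z <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm(abs(m1$mean - m2$mean) / se - z)
}

weibull_moments_vec_ <- function(shape, scale) {
  list(mean = scale^(-1 / shape) * gamma(1 + 1 / shape),
       var = scale^(-2 / shape) *
         (gamma(1 + 2 / shape) - gamma(1 + 1 / shape)^2))
}

#' Elicited priors for the Weibull assurance model
#'
#' Beliefs are elicited about four observable quantities (assumed
#' independent before truncation): the control survival rate `S1(t0)`
#' and, in the default `"difference"` form, the three survival-rate
#' differences
#' `d11 = S1(t0) - S1(t0p)`, `d12 = S2(t0) - S1(t0)` and
#' `d22 = S2(t0) - S2(t0p)`. In the `"odds_ratio"` form the three
#' quantities are instead odds ratios (typically with lognormal priors):
#' `odds(S1(t0p))/odds(S1(t0))`, `odds(S2(t0))/odds(S1(t0))` and
#' `odds(S2(t0p))/odds(S2(t0))`.
#'
#' @param s1_prior Prior for S1(t0), supported on (0, 1).
#' @param d11_prior,d12_prior,d22_prior Priors for the differences (or
#'   odds ratios).
#' @param t0,t0p Anchor times, `t0 < t0p`.
#' @param form `"difference"` (default) or `"odds_ratio"`.
#' @return Object of class `"weibull_priors"`.
#' @export
weibull_priors <- function(s1_prior, d11_prior, d12_prior, d22_prior,
                           t0, t0p, form = c("difference", "odds_ratio")) {
  stopifnot(t0 > 0, t0p > t0)
  form <- match.arg(form)
  supp <- prior_support(s1_prior)
  if (supp[1] < 0 || supp[2] > 1) {
    stop("s1_prior must be supported on (0, 1)", call. = FALSE)
  }
  structure(
    list(s1 = s1_prior, d11 = d11_prior, d12 = d12_prior, d22 = d22_prior,
         t0 = t0, t0p = t0p, form = form),
    class = "weibull_priors"
  )
}

#' Sample the four survival rates implied by the elicited priors
#'
#' Sequential construction, truncating each difference (by
#' renormalisation) so that every rate lies in (0, 1) and each group's
#' survivor function decreases: `d11` is truncated to `(0, S1(t0))`
#' given the drawn `S1(t0)`; `d12` to `(-S1(t0), 1 - S1(t0))`; `d22` to
#' `(0, S2(t0))` given the implied `S2(t0)`. In the odds-ratio form the
#' within-group ratios are truncated to `(0, 1)` instead.
#'
#' @param priors A [weibull_priors()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Data frame with columns `s1_t0`, `s1_t0p`, `s2_t0`, `s2_t0p`.
#' @export
sample_rates_from_deltas <- function(priors, n, seed = NULL) {
  stopifnot(inherits(priors, "weibull_priors"))
  with_seed_(seed, {
    s1 <- sample_prior(priors$s1, n)
    if (priors$form == "difference") {
      d11 <- sample_prior(priors$d11, n,
                          lower = pmax(rep(0, n), priors$d11$lower %||% 0),
                          upper = pmin(s1, priors$d11$upper %||% 1))
      s1p <- s1 - d11
      d12 <- sample_prior(priors$d12, n,
                          lower = pmax(-s1, priors$d12$lower %||% -Inf),
                          upper = pmin(1 - s1, priors$d12$upper %||% Inf))
      s2 <- s1 + d12
      d22 <- sample_prior(priors$d22, n,
                          lower = pmax(rep(0, n), priors$d22$lower %||% 0),
                          upper = pmin(s2, priors$d22$upper %||% 1))
      s2p <- s2 - d22
    } else {
      odds <- function(s) s / (1 - s)
      anti <- function(o) o / (1 + o)
      psi11 <- sample_prior(priors$d11, n, lower = 0, upper = 1)
      s1p <- anti(psi11 * odds(s1))
      psi12 <- sample_prior(priors$d12, n)
      s2 <- anti(psi12 * odds(s1))
      psi22 <- sample_prior(priors$d22, n, lower = 0, upper = 1)
      s2p <- anti(psi22 * odds(s2))
    }
    data.frame(s1_t0 = s1, s1_t0p = s1p, s2_t0 = s2, s2_t0p = s2p)
  })
}

#' Assurance under the Weibull survival model
#'
#' Monte Carlo estimate of the probability that a Welch two-sample
#' t-test on mean survival rejects with the experimental mean larger.
#' Per iteration: (1) draw the four survival rates from the elicited
#' priors, (2) convert each group's pair of rates to Weibull parameters
#' ([weibull_from_two_rates()]), (3) simulate `N1 + N2` complete
#' survival times, (4) compute group sample means and variances and
#' apply Welch's t-test (Satterthwaite degrees of freedom). Survival
#' times are fully observed in this analysis, so the design's
#' recruitment and follow-up lengths are unused.
#'
#' @param priors A [weibull_priors()].
#' @param design A [trial_design()] (uses `N1`, `N2`, `alpha`; requires
#'   at least 2 patients per group).
#' @param M Number of Monte Carlo iterations.
#' @param seed Optional integer seed.
#' @return An [assurance_result()]; `superiority` is the prior
#'   probability that the experimental mean survival exceeds the control
#'   mean, computed from the drawn Weibull parameters.
#' @examples
#' wp <- weibull_priors(
#'   prior_spec("point", value = 0.2), prior_spec("point", value = 0.1),
#'   prior_spec("point", value = 0.1), prior_spec("point", value = 0.1),
#'   t0 = 1, t0p = 2)
#' assurance_weibull(wp, trial_design(3, 5, N1 = 50), M = 200, seed = 1)
#' @export
assurance_weibull <- function(priors, design, M = 2000, seed = NULL) {
  stopifnot(M >= 1)
  if (design$N1 < 2 || design$N2 < 2) {
    stop("need at least 2 patients per group for a t-test", call. = FALSE)
  }
  with_seed_(seed, {
    rates <- sample_rates_from_deltas(priors, M)
    par1 <- weibull_from_two_rates(rates$s1_t0, rates$s1_t0p,
                                   priors$t0, priors$t0p)
    par2 <- weibull_from_two_rates(rates$s2_t0, rates$s2_t0p,
                                   priors$t0, priors$t0p)
    mom1 <- weibull_moments_vec_(par1[, "shape"], par1[, "scale"])
    mom2 <- weibull_moments_vec_(par2[, "shape"], par2[, "scale"])
    success <- welch_trial_success_(par1, par2, design, M)
    assurance_result(mean(success), M,
                     superiority = mean(mom2$mean > mom1$mean),
                     model = "weibull", seed = seed)
  })
}

# simulate M trials (chunked to bound memory) and return the Welch-test
# success indicator: reject at level alpha with mean2 > mean1
welch_trial_success_ <- function(par1, par2, design, M) {
  N1 <- design$N1; N2 <- design$N2
  success <- logical(M)
  chunk <- max(1L, floor(5e6 / (N1 + N2)))
  for (start in seq(1L, M, by = chunk)) {
    idx <- start:min(start + chunk - 1L, M)
    m <- length(idx)
    x1 <- matrix(stats::rweibull(m * N1,
                                 shape = par1[idx, "shape"],
                                 scale = par1[idx, "scale"]^
                                   (-1 / par1[idx, "shape"])),
                 nrow = m)
    x2 <- matrix(stats::rweibull(m * N2,
                                 shape = par2[idx, "shape"],
                                 scale = par2[idx, "scale"]^
                                   (-1 / par2[idx, "shape"])),
                 nrow = m)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- (rowSums(x1^2) - N1 * m1^2) / (N1 - 1)
    v2 <- (rowSums(x2^2) - N2 * m2^2) / (N2 - 1)
    se2 <- v1 / N1 + v2 / N2
    tstat <- (m2 - m1) / sqrt(se2)
    nu <- se2^2 / ((v1 / N1)^2 / (N1 - 1) + (v2 / N2)^2 / (N2 - 1))
    crit <- stats::qt(1 - design$alpha / 2, df = nu)
    success[idx] <- tstat > crit
  }
  success
}
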