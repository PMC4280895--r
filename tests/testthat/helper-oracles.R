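# Independent brute-force oracles used to validate the analytic power
# formulas and assurance routines. These deliberately re-derive
# quantities from first principles (numerical integration, full trial
# simulation, stock tests) rather than calling the package's formulas.

# numeric-integration event probability under uniform entry
oracle_event_prob <- function(lambda, R, T) {
  1 - stats::integrate(function(a) exp(-lambda * (T - a)), 0, R,
                       rel.tol = 1e-12)$value / R
}

# simulate one arm: observed time + status under uniform entry and
# administrative censoring, as an n_sim x N matrix pair
sim_arm <- function(rtime, N, R, T, n_sim) {
  t_surv <- matrix(rtime(n_sim * N), n_sim, N)
  follow <- T - matrix(stats::runif(n_sim * N, 0, R), n_sim, N)
  list(obs = pmin(t_surv, follow), status = t_surv <= follow)
}

# rejection rate of the exponential log-median-ratio test over n_sim
# simulated trials; one_sided counts only rejections favouring arm 2
oracle_exp_rejection_rate <- function(lambda1, lambda2, design, n_sim,
                                      seed, one_sided = FALSE) {
  withr::with_seed(seed, {
    a1 <- sim_arm(function(n) stats::rexp(n, lambda1), design$N1,
                  design$R, design$T, n_sim)
    a2 <- sim_arm(function(n) stats::rexp(n, lambda2), design$N2,
                  design$R, design$T, n_sim)
    d1 <- rowSums(a1$status); d2 <- rowSums(a2$status)
    ok <- d1 > 0 & d2 > 0
    lam1 <- d1 / rowSums(a1$obs); lam2 <- d2 / rowSums(a2$obs)
    z <- log(lam2 / lam1) / sqrt(1 / d1 + 1 / d2)
    crit <- stats::qnorm(1 - design$alpha / 2)
    rej <- if (one_sided) ok & z < -crit else ok & abs(z) > crit
    mean(rej)
  })
}

# Weibull moments by numerical integration of the survivor function
# (mu = int S dt, E[T^2] = 2 int t S dt); lambda is the rate in
# S(t) = exp(-lambda t^kappa)
oracle_weibull_moments <- function(kappa, lambda) {
  S <- function(t) exp(-lambda * t^kappa)
  mu <- stats::integrate(S, 0, Inf, rel.tol = 1e-10)$value
  m2 <- 2 * stats::integrate(function(t) t * S(t), 0, Inf,
                             rel.tol = 1e-10)$value
  c(mean = mu, var = m2 - mu^2)
}

# rejection rate of the known-variance z-test on mean survival with
# complete Weibull observation
oracle_weibull_z_rejection_rate <- function(kappa1, lambda1, kappa2,
                                            lambda2, design, n_sim,
                                            seed) {
  withr::with_seed(seed, {
    mom1 <- oracle_weibull_moments(kappa1, lambda1)
    mom2 <- oracle_weibull_moments(kappa2, lambda2)
    x1 <- matrix(stats::rweibull(n_sim * design$N1, shape = kappa1,
                                 scale = lambda1^(-1 / kappa1)),
                 n_sim, design$N1)
    x2 <- matrix(stats::rweibull(n_sim * design$N2, shape = kappa2,
                                 scale = lambda2^(-1 / kappa2)),
                 n_sim, design$N2)
    z <- (rowMeans(x2) - rowMeans(x1)) /
      sqrt(mom1["var"] / design$N1 + mom2["var"] / design$N2)
    mean(abs(z) > stats::qnorm(1 - design$alpha / 2))
  })
}

# one-sided Welch success rate (stock t.test, reject AND mean2 > mean1)
oracle_welch_success_rate <- function(kappa1, lambda1, kappa2, lambda2,
                                      design, n_sim, seed) {
  withr::with_seed(seed, {
    succ <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      x1 <- stats::rweibull(design$N1, kappa1, lambda1^(-1 / kappa1))
      x2 <- stats::rweibull(design$N2, kappa2, lambda2^(-1 / kappa2))
      tt <- stats::t.test(x2, x1)
      succ[i] <- tt$p.value < design$alpha && mean(x2) > mean(x1)
    }
    mean(succ)
  })
}

# logrank rejection rate over simulated proportional-hazards trials
# with exponential baseline (stock survival::survdiff)
oracle_logrank_rejection_rate <- function(lambda1, theta, design, n_sim,
                                          seed) {
  lambda2 <- lambda1 * exp(theta)
  withr::with_seed(seed, {
    rej <- logical(n_sim)
    grp <- rep(1:2, c(design$N1, design$N2))
    for (i in seq_len(n_sim)) {
      t_surv <- c(stats::rexp(design$N1, lambda1),
                  stats::rexp(design$N2, lambda2))
      follow <- design$T - stats::runif(design$N1 + design$N2, 0,
                                        design$R)
      obs <- pmin(t_surv, follow)
      st <- as.integer(t_surv <= follow)
      sd <- survival::survdiff(survival::Surv(obs, st) ~ grp)
      rej[i] <- (1 - stats::pchisq(sd$chisq, 1)) < design$alpha
    }
    mean(rej)
  })
}

# direct conjugate Dirichlet posterior draws of the survivor function
# at chosen cut-point indices when there is no censoring
oracle_dirichlet_survivor_draws <- function(alpha, d, n_draws, idx, seed) {
  withr::with_seed(seed, {
    a <- alpha + d
    g <- matrix(stats::rgamma(n_draws * length(a), shape = rep(a,
      each = n_draws)), n_draws, length(a))
    p <- g / rowSums(g)
    surv <- 1 - t(apply(p, 1, cumsum))
    surv[, idx, drop = FALSE]
  })
}
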