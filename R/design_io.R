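#' Smallest per-group sample size achieving a target power
#'
#' Finds the smallest integer per-group sample size `N` with
#' `power_fn(N) >= target`, by doubling to bracket the target and then
#' integer bisection; `power_fn` must be nondecreasing in `N` over the
#' searched range.
#'
#' @param power_fn Function of the per-group sample size returning a
#'   power (or assurance) value.
#' @param target Required probability, in (0, 1).
#' @param n_max Upper search bound; an error is thrown if `power_fn`
#'   never reaches `target` below it.
#' @return The smallest integer `N` with `power_fn(N) >= target`.
#' @examples
#' d0 <- trial_design(R = 3, T = 5, N1 = 2)
#' sample_size_for_power(function(N) {
#'   power_exponential(0.102, 0.0446, design_with_n(d0, N))
#' }, target = 0.8)
#' @export
sample_size_for_power <- function(power_fn, target, n_max = 1e6) {
  stopifnot(target > 0, target < 1)
  if (power_fn(1) >= target) return(1L)
  hi <- 2
  while (power_fn(hi) < target) {
    hi <- hi * 2
    if (hi > n_max) {
      stop("target probability not reachable with N <= ", n_max,
           call. = FALSE)
    }
  }
  lo <- hi %/% 2                      # power(lo) < target <= power(hi)
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (power_fn(mid) >= target) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Assurance and power as a function of sample size
#'
#' Evaluates the assurance over a grid of per-group sample sizes using
#' common random numbers: the prior draws are made once and reused for
#' every `N`, so the curve is smooth in `N` (Monte Carlo jitter shifts
#' the whole curve, not individual points). For the Weibull model the
#' prior draws are shared but each `N` needs freshly simulated trials.
#'
#' @param model `"exponential"`, `"weibull"` or `"logrank"`.
#' @param priors Model-specific prior specification:
#'   * exponential -- `list(s1 = , rho = , t0 = )`;
#'   * weibull -- a [weibull_priors()] object;
#'   * logrank -- either `list(draws = <survivor_draws>, rho = )` or
#'     `list(p1e = , s1 = , rho = )` (no-data case, exponential-shape
#'     curve through the drawn `p1e`).
#' @param design A [trial_design()]; `N1`/`N2` are replaced by the grid
#'   values (equal allocation along the curve).
#' @param N_grid Integer vector of per-group sample sizes.
#' @param M Monte Carlo iterations shared across the grid.
#' @param seed Optional integer seed.
#' @param power_params Optional fixed parameters at which to add an
#'   analytic power column: exponential -- `c(lambda1, lambda2)`;
#'   weibull -- `c(shape1, scale1, shape2, scale2)`; logrank --
#'   `c(theta, pe)`.
#' @return A data frame of class `"assurance_curve"` with columns `N`,
#'   `assurance`, `se` (and `power` when `power_params` is given);
#'   attribute `superiority` holds the prior superiority cap.
#' @examples
#' s1 <- prior_spec("beta", shape1 = 60, shape2 = 40)
#' rho <- prior_spec("normal", mean = 0.2, var = 0.05)
#' d <- trial_design(R = 3, T = 5, N1 = 10)
#' assurance_curve("exponential", list(s1 = s1, rho = rho, t0 = 5),
#'                 d, N_grid = c(50, 100, 200), M = 2000, seed = 1,
#'                 power_params = c(0.102, 0.0446))
#' @export
assurance_curve <- function(model = c("exponential", "weibull", "logrank"),
                            priors, design, N_grid, M = 1e4, seed = NULL,
                            power_params = NULL) {
  model <- match.arg(model)
  stopifnot(all(N_grid >= 1), all(N_grid == round(N_grid)))
  with_seed_(seed, {
    out <- switch(model,
      exponential = {
        dr <- draw_exponential_rates_(priors$s1, priors$rho, priors$t0, M)
        sup <- mean(dr$rho > 0)
        a <- vapply(N_grid, function(N) {
          mean(success_prob_exponential(dr$lambda1, dr$lambda2,
                                        design_with_n(design, N)))
        }, numeric(1))
        pw <- if (!is.null(power_params)) {
          vapply(N_grid, function(N) {
            power_exponential(power_params[1], power_params[2],
                              design_with_n(design, N))
          }, numeric(1))
        }
        list(assurance = a, power = pw, superiority = sup)
      },
      weibull = {
        rates <- sample_rates_from_deltas(priors, M)
        par1 <- weibull_from_two_rates(rates$s1_t0, rates$s1_t0p,
                                       priors$t0, priors$t0p)
        par2 <- weibull_from_two_rates(rates$s2_t0, rates$s2_t0p,
                                       priors$t0, priors$t0p)
        mom1 <- weibull_moments_vec_(par1[, "shape"], par1[, "scale"])
        mom2 <- weibull_moments_vec_(par2[, "shape"], par2[, "scale"])
        sup <- mean(mom2$mean > mom1$mean)
        a <- vapply(N_grid, function(N) {
          mean(welch_trial_success_(par1, par2, design_with_n(design, N), M))
        }, numeric(1))
        pw <- if (!is.null(power_params)) {
          vapply(N_grid, function(N) {
            power_weibull(power_params[1], power_params[2], power_params[3],
                          power_params[4], design_with_n(design, N))
          }, numeric(1))
        }
        list(assurance = a, power = pw, superiority = sup)
      },
      logrank = {
        dp <- draw_logrank_theta_pe_(priors, design, M)
        a <- vapply(N_grid, function(N) {
          mean(success_prob_logrank(dp$theta, dp$pe,
                                    design_with_n(design, N)))
        }, numeric(1))
        pw <- if (!is.null(power_params)) {
          vapply(N_grid, function(N) {
            power_logrank(power_params[1], power_params[2],
                          design_with_n(design, N))
          }, numeric(1))
        }
        list(assurance = a, power = pw, superiority = dp$superiority)
      }
    )
    curve <- data.frame(N = as.integer(N_grid), assurance = out$assurance,
                        se = sqrt(out$assurance * (1 - out$assurance) / M))
    if (!is.null(out$power)) curve$power <- out$power
    structure(curve, superiority = out$superiority, M = M, model = model,
              class = c("assurance_curve", "data.frame"))
  })
}

# shared (theta, pe) draws for the logrank curve, with or without
# posterior survivor draws
draw_logrank_theta_pe_ <- function(priors, design, M) {
  if (!is.null(priors$draws)) {
    draws <- priors$draws
    grid <- draws$grid
    n_avail <- nrow(draws$S)
    idx <- if (M <= n_avail) seq_len(M) else
      sample(rep(seq_len(n_avail), length.out = M))
    s1_t0 <- draws$S_t0[idx]
    rho <- sample_prior(priors$rho, M,
                        lower = pmax(-s1_t0 + 1e-12,
                                     priors$rho$lower %||% -Inf),
                        upper = pmin(1 - s1_t0 - 1e-12,
                                     priors$rho$upper %||% Inf))
    theta <- theta_from_rates(s1_t0, rho)
    R <- design$R
    p1e <- pmin(pmax(1 - as.vector(
      draws$S[idx, , drop = FALSE] %*% grid$weights) * grid$h / 3 / R,
      0), 1)
    p2e <- vapply(seq_len(M), function(j) {
      min(max(1 - simpson_integral(draws$S[idx[j], ]^exp(theta[j]),
                                   grid) / R, 0), 1)
    }, numeric(1))
    list(theta = theta, pe = design$Q1 * p1e + design$Q2 * p2e,
         superiority = mean(rho > 0))
  } else {
    r <- sample_joint_rates(priors$s1, priors$rho, M)
    theta <- theta_from_rates(r$s1, r$rho)
    p1e <- sample_prior(priors$p1e, M, lower = 1e-12, upper = 1 - 1e-12)
    lam <- rate_from_event_prob(p1e, design)
    p2e <- event_prob_exponential(lam * exp(theta), design)
    list(theta = theta, pe = design$Q1 * p1e + design$Q2 * p2e,
         superiority = mean(r$rho > 0))
  }
}

#' Simulate a two-arm-style survival dataset with uniform accrual
#'
#' Entry times are uniform on `(0, R)`; survival times come from the
#' specified model; observation is administratively censored at
#' calendar time `T`, so the observed time on the patient clock is
#' `min(survival, T - entry)`.
#'
#' @param n Number of patients.
#' @param model `"exponential"` or `"weibull"`.
#' @param params For exponential, `c(rate = )` (or a single number);
#'   for weibull, `c(shape = , scale = )` with `scale` the lambda of
#'   `S(t) = exp(-lambda t^kappa)`.
#' @param R Recruitment length (0 gives simultaneous entry).
#' @param T Total trial length; `Inf` observes every event.
#' @param seed Optional integer seed.
#' @return A [survival_data()].
#' @examples
#' simulate_survival_data(5, "exponential", 0.102, R = 3, T = 5, seed = 1)
#' @export
simulate_survival_data <- function(n, model = c("exponential", "weibull"),
                                   params, R, T, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 1, R >= 0, T >= R)
  with_seed_(seed, {
    entry <- if (R > 0) stats::runif(n, 0, R) else rep(0, n)
    t_surv <- switch(model,
      exponential = {
        rate <- unname(params[1])
        stopifnot(rate > 0)
        stats::rexp(n, rate)
      },
      weibull = {
        shape <- unname(params[["shape"]])
        scale <- unname(params[["scale"]])
        stopifnot(shape > 0, scale > 0)
        stats::rweibull(n, shape = shape, scale = scale^(-1 / shape))
      }
    )
    follow <- T - entry
    survival_data(time = pmin(t_surv, follow),
                  status = as.integer(t_surv <= follow))
  })
}

#' Write results to plain-text files
#'
#' `write_assurance_result()` serialises an [assurance_result()] as
#' `key = value` lines; `write_curve()` writes an [assurance_curve()]
#' as a tab-delimited table. Both re-read cleanly with base tools.
#'
#' @param x The object to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assurance_result <- function(x, path) {
  stopifnot(inherits(x, "assurance_result"))
  lines <- c(
    paste("model =", x$model),
    paste("estimate =", format(x$estimate, digits = 15)),
    paste("se =", format(x$se, digits = 15)),
    paste("M =", format(x$M, digits = 15)),
    paste("superiority =", format(x$superiority, digits = 15)),
    paste("seed =", if (is.null(x$seed)) "NA" else x$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_assurance_result
#' @export
write_curve <- function(x, path) {
  stopifnot(inherits(x, "assurance_curve"))
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
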