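test_that("two survival rates determine the Weibull parameters", {
  p1 <- weibull_from_two_rates(0.2, 0.1, 1, 2)
  expect_equal(unname(round(p1, 2)), c(0.52, 1.61))
  p2 <- weibull_from_two_rates(0.3, 0.2, 1, 2)
  expect_equal(unname(round(p2, 2)), c(0.42, 1.20))
  # exponential special case
  expect_equal(unname(weibull_from_two_rates(exp(-1), exp(-2), 1, 2)),
               c(1, 1))
  expect_error(weibull_from_two_rates(0.2, 0.3, 1, 2), "decrease")
})

test_that("survivor evaluation round-trips the parameter recovery", {
  set.seed(31)
  for (i in 1:20) {
    s_a <- runif(1, 0.2, 0.95)
    s_b <- runif(1, 0.01, s_a - 0.05)
    t0 <- runif(1, 0.5, 3); t0p <- t0 + runif(1, 0.5, 4)
    p <- weibull_from_two_rates(s_a, s_b, t0, t0p)
    expect_equal(exp(-p["scale"] * t0^p["shape"]), s_a,
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(exp(-p["scale"] * t0p^p["shape"]), s_b,
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("Weibull moments match integration and simulation", {
  # worked design point: mean survival 0.75 / 1.89 in the two groups
  p1 <- weibull_from_two_rates(0.2, 0.1, 1, 2)
  p2 <- weibull_from_two_rates(0.3, 0.2, 1, 2)
  expect_equal(weibull_moments(p1["shape"], p1["scale"])[["mean"]],
               0.75, tolerance = 2e-3)
  expect_equal(weibull_moments(p2["shape"], p2["scale"])[["mean"]],
               1.89, tolerance = 2e-3)
  # against the survivor-integration oracle
  for (par in list(c(0.52, 1.61), c(0.42, 1.20), c(2, 0.5))) {
    expect_equal(unname(weibull_moments(par[1], par[2])),
                 unname(oracle_weibull_moments(par[1], par[2])),
                 tolerance = 1e-7)
  }
  # against Monte Carlo draws
  set.seed(32)
  n <- 1e6
  x <- rweibull(n, shape = 0.52, scale = 1.61^(-1 / 0.52))
  mom <- weibull_moments(0.52, 1.61)
  expect_equal(mean(x), mom[["mean"]],
               tolerance = 3 * sqrt(mom[["var"]] / n) / mom[["mean"]])
  # exponential reduction
  expect_equal(unname(weibull_moments(1, 0.25)), c(4, 16))
  expect_error(weibull_moments(1e-4, 1), "overflow")
})

test_that("mean-survival power is alpha/2 under the null, monotone in N", {
  d <- trial_design(3, 5, N1 = 50)
  expect_equal(power_weibull(0.52, 1.61, 0.52, 1.61, d), 0.025)
  pw <- vapply(c(20, 100, 500, 5000), function(N) {
    power_weibull(0.52, 1.61, 0.42, 1.20, design_with_n(d, N))
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[4], 0.999)
})

test_that("analytic power matches the z-test simulation oracle", {
  d <- design_with_n(trial_design(3, 5, N1 = 2), 200)
  n_sim <- 4000
  rate <- oracle_weibull_z_rejection_rate(0.52, 1.61, 0.42, 1.20, d,
                                          n_sim, seed = 33)
  pw <- power_weibull(0.52, 1.61, 0.42, 1.20, d)
  expect_equal(rate, pw, tolerance = 2.5 * sqrt(pw * (1 - pw) / n_sim) / pw)
})

test_that("delta sampling reconstructs the four survival rates", {
  wp <- weibull_priors(prior_spec("point", value = 0.2),
                       prior_spec("point", value = 0.1),
                       prior_spec("point", value = 0.1),
                       prior_spec("point", value = 0.1),
                       t0 = 1, t0p = 2)
  r <- sample_rates_from_deltas(wp, 5, seed = 34)
  expect_equal(unique(r$s1_t0), 0.2)
  expect_equal(unique(r$s1_t0p), 0.1)
  expect_equal(unique(r$s2_t0), 0.3)
  expect_equal(unique(r$s2_t0p), 0.2)
})

test_that("sampled rates always decrease within group and stay in (0,1)", {
  wp <- weibull_priors(
    fit_prior_quartiles(c(0.15, 0.2, 0.23), "beta"),
    fit_prior_quartiles(c(0.08, 0.11, 0.15), "beta"),
    fit_prior_quartiles(c(0.05, 0.1, 0.14), "normal"),
    fit_prior_quartiles(c(0.05, 0.1, 0.12), "beta"),
    t0 = 1, t0p = 2)
  r <- sample_rates_from_deltas(wp, 2e4, seed = 35)
  expect_true(all(r$s1_t0p < r$s1_t0))
  expect_true(all(r$s2_t0p < r$s2_t0))
  expect_true(all(unlist(r) > 0 & unlist(r) < 1))
  # a tight difference prior induces positive dependence between arms
  expect_gt(cor(r$s2_t0, r$s1_t0), 0)
})

test_that("odds-ratio parameterisation also yields valid decreasing rates", {
  wp <- weibull_priors(
    prior_spec("beta", shape1 = 8, shape2 = 32),
    prior_spec("lognormal", meanlog = -0.7, varlog = 0.05),
    prior_spec("lognormal", meanlog = 0.5, varlog = 0.05),
    prior_spec("lognormal", meanlog = -0.7, varlog = 0.05),
    t0 = 1, t0p = 2, form = "odds_ratio")
  r <- sample_rates_from_deltas(wp, 5000, seed = 36)
  expect_true(all(r$s1_t0p < r$s1_t0))
  expect_true(all(r$s2_t0p < r$s2_t0))
  expect_true(all(unlist(r) > 0 & unlist(r) < 1))
})

test_that("point-prior assurance equals one-sided Welch power", {
  wp <- weibull_priors(prior_spec("point", value = 0.2),
                       prior_spec("point", value = 0.1),
                       prior_spec("point", value = 0.1),
                       prior_spec("point", value = 0.1),
                       t0 = 1, t0p = 2)
  d <- trial_design(3, 5, N1 = 60)
  M <- 1500; n_sim <- 1500
  for (seeds in list(c(41, 141), c(42, 142))) {
    a <- assurance_weibull(wp, d, M = M, seed = seeds[1])
    oracle <- oracle_welch_success_rate(0.5166975, 1.6094379,
                                        0.4187541, 1.2039728, d,
                                        n_sim, seed = seeds[2])
    tol <- 2 * sqrt(a$estimate * (1 - a$estimate) * (1 / M + 1 / n_sim))
    expect_lt(abs(a$estimate - oracle), tol)
    expect_gt(a$estimate, 0); expect_lt(a$estimate, 1)
  }
})

test_that("weibull assurance respects the superiority cap", {
  wp <- weibull_priors(
    fit_prior_quartiles(c(0.15, 0.2, 0.23), "beta"),
    fit_prior_quartiles(c(0.08, 0.11, 0.15), "beta"),
    fit_prior_quartiles(c(0.05, 0.1, 0.14), "normal"),
    fit_prior_quartiles(c(0.05, 0.1, 0.12), "beta"),
    t0 = 1, t0p = 2)
  a <- assurance_weibull(wp, trial_design(3, 5, N1 = 200), M = 1000,
                         seed = 43)
  expect_lte(a$estimate, a$superiority + 3 * a$se)
  expect_error(assurance_weibull(wp, trial_design(3, 5, N1 = 1)),
               "at least 2")
})
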