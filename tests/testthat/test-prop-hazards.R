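design_53 <- trial_design(R = 5, T = 10, N1 = 100)

test_that("log hazard ratio from survival rates at the anchor time", {
  expect_equal(theta_from_rates(0.525, 0.175), -0.591, tolerance = 1e-3)
  expect_equal(theta_from_rates(0.3, 0), 0)
  # S2 = S1^exp(theta) inverts the relation
  th <- theta_from_rates(0.525, 0.175)
  expect_equal(0.525^exp(th), 0.7, tolerance = 1e-10)
  expect_error(theta_from_rates(0.9, 0.2), "0, 1")
})

test_that("composite Simpson rule is exact for constants and cubics", {
  d1 <- trial_design(R = 1, T = 1, N1 = 10)
  g5 <- quadrature_grid(d1, H = 5)
  expect_equal(simpson_integral(rep(3, 5), g5), 3)
  expect_equal(simpson_integral(g5$nodes^3, g5), 0.25)
  expect_error(quadrature_grid(d1, H = 4), "odd")
})

test_that("Simpson on the pilot Kaplan-Meier step curve (H = 11)", {
  g <- quadrature_grid(design_53, H = 11)
  km <- kaplan_meier(km_pilot_data())
  # hand evaluation: nodes 5:10 by 0.5 take KM values 0.7, 0.525 x 8,
  # 0.2625 x 2; weighted sum 14.6125, times h/3 = 1/6
  expect_equal(simpson_integral(predict(km, g$nodes), g),
               14.6125 / 6, tolerance = 1e-12)
})

test_that("event probabilities from the control curve behave at limits", {
  g <- quadrature_grid(design_53, H = 11)
  expect_equal(event_probabilities(rep(1, 11), -0.5, design_53, g)$pe, 0)
  expect_equal(event_probabilities(rep(0, 11), -0.5, design_53, g)$pe, 1)
  km <- kaplan_meier(km_pilot_data())
  ep <- event_probabilities(predict(km, g$nodes),
                            theta_from_rates(0.525, 0.175),
                            design_53, g)
  expect_equal(ep$p1e, 0.5129, tolerance = 1e-4)
  expect_equal(ep$p2e, 0.3331, tolerance = 1e-3)
  expect_equal(ep$pe, 0.42, tolerance = 0.01)
  expect_error(event_probabilities(seq(0, 1, length.out = 11), 0,
                                   design_53, g), "nonincreasing")
})

test_that("event probabilities are monotone in theta and in the curve", {
  g <- quadrature_grid(design_53, H = 11)
  s_hi <- seq(0.9, 0.6, length.out = 11)
  s_lo <- s_hi - 0.2
  e1 <- event_probabilities(s_hi, -0.5, design_53, g)
  e2 <- event_probabilities(s_hi, 0.5, design_53, g)   # worse treatment
  expect_gt(e2$p2e, e1$p2e)
  e3 <- event_probabilities(s_lo, -0.5, design_53, g)
  expect_gt(e3$p1e, e1$p1e)
  expect_gt(e3$p2e, e1$p2e)
})

test_that("logrank power: null value, event-count sufficiency, monotone", {
  expect_equal(power_logrank(0, 0.4, design_53), 0.025)
  expect_equal(power_logrank(0, 0, design_53), 0.025)
  # N and Pe enter only through the expected event count d = N * Pe
  expect_equal(power_logrank(-0.6, 0.4, design_with_n(design_53, 100)),
               power_logrank(-0.6, 0.2, design_with_n(design_53, 200)))
  pw <- vapply(c(20, 50, 200, 2000), function(N) {
    power_logrank(-0.591, 0.42, design_with_n(design_53, N))
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("Schoenfeld power matches a simulated logrank test", {
  # exponential baseline through the pilot 7-month survival rate
  lam1 <- -log(0.525) / 7
  theta <- -0.591
  pe_fun <- function(d) {
    p1 <- oracle_event_prob(lam1, d$R, d$T)
    p2 <- oracle_event_prob(lam1 * exp(theta), d$R, d$T)
    d$Q1 * p1 + d$Q2 * p2
  }
  N <- sample_size_for_power(function(N) {
    d <- design_with_n(design_53, N)
    power_logrank(theta, pe_fun(d), d)
  }, target = 0.9)
  d <- design_with_n(design_53, N)
  n_sim <- 1200
  rate <- oracle_logrank_rejection_rate(lam1, theta, d, n_sim, seed = 51)
  expect_equal(rate, 0.9, tolerance = 2.5 * sqrt(0.9 * 0.1 / n_sim) / 0.9)
})

test_that("no-data assurance with a null point prior is alpha/2", {
  a <- assurance_logrank(prior_spec("point", value = 0.5),
                         prior_spec("point", value = 0.525),
                         prior_spec("point", value = 0),
                         design_53, M = 50, seed = 52)
  expect_equal(a$estimate, 0.025, tolerance = 1e-10)
  expect_equal(a$superiority, 0)
})

test_that("no-data assurance at pilot point priors equals one-sided power", {
  # P1e implied by the exponential curve through S1(7) = 0.525
  lam1 <- -log(0.525) / 7
  p1e <- oracle_event_prob(lam1, 5, 10)
  theta <- theta_from_rates(0.525, 0.175)
  p2e <- oracle_event_prob(lam1 * exp(theta), 5, 10)
  pe <- (p1e + p2e) / 2
  d <- design_with_n(design_53, 150)
  a <- assurance_logrank(prior_spec("point", value = p1e),
                         prior_spec("point", value = 0.525),
                         prior_spec("point", value = 0.175),
                         d, M = 20, seed = 53)
  expected <- pnorm(-theta * sqrt(300 * pe * 0.25) - qnorm(0.975))
  expect_equal(a$estimate, expected, tolerance = 1e-6)
})

test_that("assurance from survivor draws: null rho gives alpha/2, caps hold", {
  g <- quadrature_grid(design_53, H = 11)
  dr <- posterior_survivor_draws(km_pilot_data(),
                                 dp_prior(1, g_survival = 0.5, g_time = 5),
                                 g, t0 = 7, n_iter = 1500, burn_in = 500,
                                 seed = 54)
  a0 <- assurance_logrank_draws(dr, prior_spec("point", value = 0),
                                design_53, seed = 55)
  expect_equal(a0$estimate, 0.025, tolerance = 1e-10)
  a <- assurance_logrank_draws(dr, prior_spec("normal", mean = 0.175,
                                              var = 0.01),
                               design_53, M = 3000, seed = 56)
  expect_lte(a$estimate, a$superiority + 3 * a$se)
  # draws generated for a different accrual window are refused
  expect_error(assurance_logrank_draws(dr, prior_spec("point", value = 0),
                                       trial_design(2, 10, N1 = 50)),
               "different")
})

test_that("normal-theta assurance: MC agrees with Gauss-Hermite", {
  d <- design_with_n(design_53, 150)
  q <- assurance_logrank_normal_theta(-0.4, 0.04, 0.42, d, "quadrature")
  m <- assurance_logrank_normal_theta(-0.4, 0.04, 0.42, d, "mc",
                                      M = 4e5, seed = 57)
  expect_equal(m, q, tolerance = 3e-3 / q)
})
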