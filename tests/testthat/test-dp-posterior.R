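design_53 <- trial_design(R = 5, T = 10, N1 = 100)
grid_11 <- quadrature_grid(design_53, H = 11)

test_that("product-limit estimator matches hand calculation and limits", {
  km <- kaplan_meier(km_pilot_data())
  expect_equal(predict(km, 7), 0.525)
  expect_equal(predict(km, c(0.5, 0.9, 3.5)), c(1, 0.875, 0.7))
  # no censoring: 1 - empirical CDF
  d <- survival_data(time = c(1, 2, 3, 4), status = rep(1, 4))
  expect_equal(predict(kaplan_meier(d), c(0.5, 1, 2.5, 4)),
               c(1, 0.75, 0.5, 0))
  # all censored: survivor stays at 1
  dc <- survival_data(time = c(1, 2), status = c(0, 0))
  expect_equal(predict(kaplan_meier(dc), c(0, 5)), c(1, 1))
})

test_that("partition merges ties and counts records exhaustively", {
  expect_message(
    part <- build_partition(grid_11, km_pilot_data()),
    "merged"
  )
  # 11 nodes + censoring times {1.0, 2.7, 7.0, 12.1}, 7.0 tied with a node
  expect_equal(part$K, 14)
  expect_length(part$d, 15)
  expect_equal(sum(part$d) + sum(part$r), 8)
  expect_equal(sum(part$d), 4)          # the four observed events

  # no censored records: cut points are the quadrature nodes alone
  ev <- survival_data(time = c(6, 7.2, 8.3), status = c(1, 1, 1))
  p2 <- build_partition(grid_11, ev)
  expect_equal(p2$cut, grid_11$nodes)
  expect_equal(sum(p2$r), 0)
})

test_that("censored imputation conserves the record total", {
  part <- suppressMessages(build_partition(grid_11, km_pilot_data(),
                                           t0 = 7))
  prior <- dp_prior(1, g_survival = 0.5, g_time = 5)
  alpha <- survassure:::dp_alpha(prior, part)
  expect_equal(sum(alpha), 1, tolerance = 1e-12)   # sums to c0
  p <- alpha / sum(alpha)
  for (s in 1:25) {
    d_prime <- gibbs_impute_censored(p, part, seed = s)
    expect_equal(sum(d_prime), nrow(km_pilot_data()))
    expect_true(all(d_prime >= part$d))
  }
  # no censoring: d' is exactly d
  ev <- survival_data(time = c(6, 7.2), status = c(1, 1))
  pe <- build_partition(grid_11, ev)
  ae <- survassure:::dp_alpha(prior, pe)
  expect_equal(gibbs_impute_censored(ae / sum(ae), pe, seed = 1), pe$d)
})

test_that("imputation spreads a censored event by the multinomial law", {
  # single censored observation, uniform mass over the 4 later intervals
  d <- trial_design(R = 2, T = 3, N1 = 10)
  g <- quadrature_grid(d, H = 3)          # nodes 1, 2, 3
  dat <- survival_data(time = 1, status = 0)
  part <- suppressMessages(build_partition(g, dat))
  # intervals: (0,1], (1,2], (2,3], tail -> censored in interval 1
  p <- rep(0.25, 4)
  counts <- numeric(4)
  withr::with_seed(61, {
    for (i in 1:3000) {
      counts <- counts + gibbs_impute_censored(p, part)
    }
  })
  freq <- (counts - c(0, 0, 0, 0)) / 3000
  expect_equal(unname(freq[2:4]), rep(1 / 3, 3), tolerance = 0.05)
  expect_equal(freq[1], 0)                # never before the censoring time
})

test_that("Dirichlet update has the conjugate mean and prior limits", {
  part <- suppressMessages(build_partition(grid_11, km_pilot_data()))
  prior <- dp_prior(1, g_survival = 0.5, g_time = 5)
  alpha <- survassure:::dp_alpha(prior, part)
  # no data: draws average to the prior masses alpha / c0
  withr::with_seed(62, {
    draws <- replicate(4000, gibbs_update_p(numeric(length(alpha)), alpha))
  })
  expect_equal(rowMeans(draws), alpha, tolerance = 0.05)
  # huge precision: posterior concentrates at the prior masses
  strong <- dp_prior(1e6, g_survival = 0.5, g_time = 5)
  as <- survassure:::dp_alpha(strong, part)
  p <- gibbs_update_p(part$d, as, seed = 63)
  expect_equal(p, as / sum(as), tolerance = 0.01, ignore_attr = TRUE)
})

test_that("Gibbs marginal matches the direct conjugate posterior (J = 0)", {
  # uncensored data: no imputation is needed, so the Gibbs draws must
  # reproduce the plain Dirichlet posterior
  ev <- survival_data(time = c(5.6, 6.3, 6.3, 7.9, 8.4, 9.1, 11),
                      status = rep(1, 7))
  prior <- dp_prior(1, g_survival = 0.5, g_time = 5)
  dr <- posterior_survivor_draws(ev, prior, grid_11, t0 = 7,
                                 n_iter = 21000, burn_in = 1000,
                                 seed = 64)
  part <- dr$partition
  alpha <- survassure:::dp_alpha(prior, part)
  node_cols <- match(round(c(6, 7, 9), 6), round(part$cut, 6))
  direct <- oracle_dirichlet_survivor_draws(alpha, part$d, 20000,
                                            node_cols, seed = 65)
  for (j in seq_along(node_cols)) {
    gibbs_s <- dr$S[, match(c(6, 7, 9)[j], grid_11$nodes)]
    ks <- suppressWarnings(stats::ks.test(gibbs_s, direct[, j]))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("posterior survivor draws are valid curves near the KM estimate", {
  prior <- dp_prior(1, g_survival = 0.5, g_time = 5)
  dr <- posterior_survivor_draws(km_pilot_data(), prior, grid_11, t0 = 7,
                                 n_iter = 6000, burn_in = 1000, seed = 66)
  expect_true(all(dr$S >= 0 & dr$S <= 1))
  expect_true(all(apply(dr$S, 1, function(s) all(diff(s) <= 1e-12))))
  # weak prior, data-dominant: close to the product-limit value at t0
  expect_equal(mean(dr$S_t0), 0.525, tolerance = 0.1 / 0.525)
  # huge precision: posterior mean curve tracks G at every node
  strong <- posterior_survivor_draws(km_pilot_data(),
                                     dp_prior(1e6, g_survival = 0.5,
                                              g_time = 5),
                                     grid_11, t0 = 7, n_iter = 2000,
                                     burn_in = 500, seed = 67)
  G <- exp(-log(2) / 5 * grid_11$nodes)
  expect_equal(colMeans(strong$S), G, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("changing the seed moves draws but not the posterior mean", {
  prior <- dp_prior(1, g_survival = 0.5, g_time = 5)
  d1 <- posterior_survivor_draws(km_pilot_data(), prior, grid_11, t0 = 7,
                                 n_iter = 6000, burn_in = 1000, seed = 68)
  d2 <- posterior_survivor_draws(km_pilot_data(), prior, grid_11, t0 = 7,
                                 n_iter = 6000, burn_in = 1000, seed = 69)
  expect_false(identical(d1$S, d2$S))
  expect_lt(abs(mean(d1$S_t0) - mean(d2$S_t0)), 0.02)
})
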