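#' Dirichlet-process prior for the control survivor function
#'
#' The prior is determined by a precision `c0 > 0` and a shape survivor
#' function `G` via `alpha([t, Inf)) = c0 * G(t)`: on any partition of
#' the time axis the interval event probabilities are a priori Dirichlet
#' with parameters `c0 * {G(t_{k-1}) - G(t_k)}`. `G` encodes the
#' expert's central guess at the survivor curve and `c0` how many
#' observations' worth of weight it carries. By default `G` is
#' exponential, with its rate either given directly or solved from one
#' elicited anchor (`G(g_time) = g_survival`, so
#' `rate = -log(g_survival)/g_time`).
#'
#' @param c0 Precision (positive).
#' @param g_rate Exponential rate of `G`, or `NULL` to use the anchor.
#' @param g_survival,g_time Anchor for the exponential shape: the
#'   elicited survival rate at `g_time`.
#' @param g_fun Optional arbitrary survivor function `G(t)` (proper,
#'   nonincreasing, `G(0) = 1`); overrides the exponential shape.
#' @return An object of class `"dp_prior"` with `c0` and `G`.
#' @examples
#' dp_prior(c0 = 1, g_survival = 0.5, g_time = 5)  # rate log(2)/5
#' @export
dp_prior <- function(c0 = 1, g_rate = NULL, g_survival = NULL,
                     g_time = NULL, g_fun = NULL) {
  stopifnot(c0 > 0)
  if (is.null(g_fun)) {
    if (is.null(g_rate)) {
      if (is.null(g_survival) || is.null(g_time)) {
        stop("supply g_rate, or the anchor pair (g_survival, g_time), ",
             "or g_fun", call. = FALSE)
      }
      stopifnot(g_survival > 0, g_survival < 1, g_time > 0)
      g_rate <- -log(g_survival) / g_time
    }
    stopifnot(g_rate > 0)
    g_fun <- local({
      rate <- g_rate
      function(t) exp(-rate * t)
    })
  }
  structure(list(c0 = c0, G = g_fun, g_rate = g_rate), class = "dp_prior")
}

#' Partition of the time axis for the censored-data Gibbs sampler
#'
#' Merges the quadrature nodes with the data's distinct censoring times
#' (and, optionally, the anchor time `t0`) into ordered cut points
#' `t_1 < ... < t_K`, defining intervals `(0, t_1], (t_1, t_2], ...,
#' (t_K, Inf)`. The partition starts at 0 rather than at `T - R` so that
#' observations occurring before the quadrature window remain usable;
#' the quadrature nodes themselves stay confined to `[T - R, T]`.
#' Coinciding cut points (for example a censoring time equal to a node)
#' are merged, with a message.
#'
#' @param grid A [quadrature_grid()].
#' @param data A [survival_data()].
#' @param t0 Optional anchor time to include among the cut points.
#' @return An object of class `"partition"`: cut points `cut`, interval
#'   counts of observed events `d` and censorings `r` (length
#'   `length(cut) + 1`, last entry the tail interval), and the interval
#'   index of each record.
#' @examples
#' d <- trial_design(R = 5, T = 10, N1 = 100)
#' build_partition(quadrature_grid(d, 11), km_pilot_data(), t0 = 7)
#' @export
build_partition <- function(grid, data, t0 = NULL) {
  stopifnot(inherits(grid, "quadrature_grid"),
            inherits(data, "survival_data"))
  tau <- unique(data$time[data$status == 0])
  raw <- sort(c(grid$nodes, tau, t0))
  keep <- c(TRUE, diff(raw) > 1e-9)
  if (!all(keep)) {
    message("merged ", sum(!keep), " coinciding cut point(s)")
  }
  cut <- raw[keep]
  K <- length(cut)
  # interval k = (cut[k-1], cut[k]], with cut[0] = 0; K + 1 is the tail
  idx <- findInterval(data$time, cut, left.open = TRUE) + 1L
  d <- tabulate(idx[data$status == 1], nbins = K + 1L)
  r <- tabulate(idx[data$status == 0], nbins = K + 1L)
  structure(list(cut = cut, K = K, d = d, r = r, interval = idx),
            class = "partition")
}

# Dirichlet concentration parameters induced on a partition:
# alpha_k = c0 * {G(t_{k-1}) - G(t_k)}, tail alpha = c0 * G(t_K)
dp_alpha <- function(prior, partition) {
  Gcut <- prior$G(partition$cut)
  prior$c0 * -diff(c(prior$G(0), Gcut, 0))
}

# one Dirichlet draw by gamma normalisation
rdirichlet_ <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s == 0) stop("all Dirichlet concentration parameters are zero",
                   call. = FALSE)
  x / s
}

#' Gibbs step 1: impute interval membership of censored event times
#'
#' Conditional on the interval probabilities `p`, each of the `r_k`
#' observations censored in interval `k` has its (unobserved) event in a
#' later interval `j > k` with probability
#' `eta_{j,k} = p_j / sum_{l > k} p_l`; the allocation is multinomial.
#' Returns the revised event counts `d' = d + imputed events`, so the
#' total of `d'` always equals the number of records.
#'
#' @param p Interval probability vector (length `K + 1`, sums to 1).
#' @param partition A [build_partition()] result (supplies `d` and `r`).
#' @param seed Optional integer seed.
#' @return Integer vector `d'` of revised event counts per interval.
#' @export
gibbs_impute_censored <- function(p, partition, seed = NULL) {
  stopifnot(inherits(partition, "partition"),
            length(p) == partition$K + 1L,
            abs(sum(p) - 1) < 1e-8)
  with_seed_(seed, {
    d_prime <- partition$d
    K1 <- partition$K + 1L
    for (k in which(partition$r > 0)) {
      r_k <- partition$r[k]
      if (k == K1) {            # censored in the open tail: event is there too
        d_prime[K1] <- d_prime[K1] + r_k
        next
      }
      later <- (k + 1L):K1
      mass <- sum(p[later])
      if (mass <= 0) {
        warning("no probability mass beyond a censoring interval; ",
                "imputing to the tail", call. = FALSE)
        d_prime[K1] <- d_prime[K1] + r_k
      } else {
        z <- stats::rmultinom(1, size = r_k, prob = p[later])[, 1]
        d_prime[later] <- d_prime[later] + z
      }
    }
    d_prime
  })
}

#' Gibbs step 2: redraw the interval probabilities
#'
#' With complete (observed + imputed) event counts `d'` the Dirichlet
#' prior is conjugate: `p ~ Dirichlet(alpha + d')`.
#'
#' @param d_prime Revised event counts per interval.
#' @param alpha Dirichlet concentration parameters (same length).
#' @param seed Optional integer seed.
#' @return New probability vector summing to 1.
#' @export
gibbs_update_p <- function(d_prime, alpha, seed = NULL) {
  stopifnot(length(d_prime) == length(alpha), all(d_prime >= 0),
            all(alpha >= 0))
  with_seed_(seed, rdirichlet_(alpha + d_prime))
}

#' Posterior draws of the control survivor function (DP + Gibbs)
#'
#' Samples the control survivor function at the quadrature nodes (and at
#' the anchor time `t0`) from its posterior under a Dirichlet-process
#' prior given right-censored data. The sampler alternates
#' [gibbs_impute_censored()] (multinomial imputation of which interval
#' each censored subject's event fell in) and [gibbs_update_p()]
#' (conjugate Dirichlet redraw of the interval probabilities), starting
#' from the prior-mean probabilities. Survivor values are tail sums:
#' `S(t) = sum of p over intervals beyond the cut point at t` (the step
#' convention; `t0` must coincide with a cut point, which
#' [build_partition()] guarantees by inserting it).
#'
#' @param data A [survival_data()].
#' @param prior A [dp_prior()].
#' @param grid A [quadrature_grid()].
#' @param t0 Anchor time at which `S1(t0)` is also recorded.
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded (`n_iter > burn_in >= 0`).
#' @param seed Optional integer seed.
#' @return An object of class `"survivor_draws"`: matrix `S`
#'   (`n_iter - burn_in` rows, one column per node), vector `S_t0`, the
#'   `grid`, `t0`, the `partition` and the sampler settings. Every draw
#'   is nonincreasing across nodes with values in [0, 1].
#' @examples
#' d <- trial_design(R = 5, T = 10, N1 = 100)
#' dr <- posterior_survivor_draws(km_pilot_data(),
#'   dp_prior(c0 = 1, g_survival = 0.5, g_time = 5),
#'   quadrature_grid(d, 11), t0 = 7, n_iter = 600, burn_in = 100,
#'   seed = 1)
#' mean(dr$S_t0)
#' @export
posterior_survivor_draws <- function(data, prior, grid, t0,
                                     n_iter = 11000, burn_in = 1000,
                                     seed = NULL) {
  stopifnot(inherits(prior, "dp_prior"), n_iter > burn_in, burn_in >= 0)
  partition <- build_partition(grid, data, t0 = t0)
  alpha <- dp_alpha(prior, partition)
  # cut-point index of each quadrature node and of t0
  node_idx <- vapply(grid$nodes, function(u) {
    which(abs(partition$cut - u) < 1e-9)[1]
  }, integer(1))
  t0_idx <- which(abs(partition$cut - t0) < 1e-9)[1]
  if (anyNA(node_idx) || is.na(t0_idx)) {
    stop("quadrature nodes/t0 not found among the partition cut points",
         call. = FALSE)
  }
  with_seed_(seed, {
    p <- alpha / sum(alpha)              # prior means
    n_keep <- n_iter - burn_in
    S <- matrix(NA_real_, n_keep, grid$H)
    S_t0 <- numeric(n_keep)
    any_censored <- any(partition$r > 0)
    for (it in seq_len(n_iter)) {
      d_prime <- if (any_censored) {
        gibbs_impute_censored(p, partition)
      } else partition$d
      p <- gibbs_update_p(d_prime, alpha)
      if (it > burn_in) {
        tail_surv <- 1 - cumsum(p)       # S at each cut point
        S[it - burn_in, ] <- pmin(pmax(tail_surv[node_idx], 0), 1)
        S_t0[it - burn_in] <- min(max(tail_surv[t0_idx], 0), 1)
      }
    }
    structure(
      list(S = S, S_t0 = S_t0, grid = grid, t0 = t0,
           partition = partition, n_iter = n_iter, burn_in = burn_in,
           seed = seed),
      class = "survivor_draws"
    )
  })
}

#' @export
print.survivor_draws <- function(x, ...) {
  cat("<survivor_draws>", nrow(x$S), "posterior draws at", x$grid$H,
      "nodes on [", x$grid$nodes[1], ",", x$grid$nodes[x$grid$H], "]\n")
  cat(sprintf("  posterior mean S(t0 = %g) = %.4f\n", x$t0, mean(x$S_t0)))
  invisible(x)
}
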