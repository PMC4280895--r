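#' Specify an elicited prior distribution
#'
#' A `prior_spec` describes a univariate prior for an elicited quantity:
#' a beta, normal, lognormal or degenerate (point) distribution, with
#' optional truncation bounds. Truncation is by renormalisation of the
#' density to the interval (not clipping), and sampling from a truncated
#' prior uses the inverse-CDF method so no draws are rejected.
#'
#' @param family One of `"beta"`, `"normal"`, `"lognormal"`, `"point"`.
#' @param ... Family parameters: `shape1`, `shape2` (beta); `mean`, `var`
#'   (normal, `var` is the variance); `meanlog`, `varlog` (lognormal);
#'   `value` (point).
#' @param lower,upper Optional truncation bounds (`lower < upper`). The
#'   untruncated distribution must place positive mass in `(lower, upper)`.
#'
#' @return An object of class `"prior_spec"`.
#' @examples
#' prior_spec("beta", shape1 = 60, shape2 = 40)
#' prior_spec("normal", mean = 0.2, var = 0.05, lower = -1, upper = 1)
#' @export
prior_spec <- function(family = c("beta", "normal", "lognormal", "point"),
                       ..., lower = NULL, upper = NULL) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    beta = c("shape1", "shape2"),
    normal = c("mean", "var"),
    lognormal = c("meanlog", "varlog"),
    point = "value"
  )
  missing <- setdiff(need, names(params))
  if (length(missing) > 0L) {
    stop("family '", family, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  if (family == "beta" && (params$shape1 <= 0 || params$shape2 <= 0)) {
    stop("beta shapes must be positive", call. = FALSE)
  }
  if (family == "normal" && params$var <= 0) {
    stop("normal variance must be positive", call. = FALSE)
  }
  if (family == "lognormal" && params$varlog <= 0) {
    stop("lognormal log-variance must be positive", call. = FALSE)
  }
  spec <- structure(
    list(family = family, params = params, lower = lower, upper = upper),
    class = "prior_spec"
  )
  if (!is.null(lower) && !is.null(upper)) {
    if (lower >= upper) stop("lower must be < upper", call. = FALSE)
    if (family != "point" &&
        prior_cdf(spec, upper) - prior_cdf(spec, lower) <= 0) {
      stop("untruncated prior places no mass in (lower, upper)", call. = FALSE)
    }
    if (family == "point" &&
        (params$value <= lower || params$value >= upper)) {
      stop("point value lies outside the truncation bounds", call. = FALSE)
    }
  }
  spec
}

#' @export
print.prior_spec <- function(x, ...) {
  p <- paste(names(x$params), signif(unlist(x$params), 5),
             sep = " = ", collapse = ", ")
  cat("<prior_spec> ", x$family, "(", p, ")", sep = "")
  if (!is.null(x$lower) || !is.null(x$upper)) {
    cat(" truncated to (", x$lower %||% "-Inf", ", ",
        x$upper %||% "Inf", ")", sep = "")
  }
  if (!is.null(attr(x, "ssq"))) {
    cat("  [fit SSQ = ", signif(attr(x, "ssq"), 4), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Untruncated CDF of a prior specification
#'
#' Evaluates the cumulative distribution function of the *untruncated*
#' family member described by `spec`. Truncation bounds are ignored here;
#' they are applied in [sample_prior()] by inverse-CDF renormalisation.
#'
#' @param spec A [prior_spec()].
#' @param q Vector of quantiles.
#' @return Vector of probabilities.
#' @export
prior_cdf <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    beta = stats::pbeta(q, p$shape1, p$shape2),
    normal = stats::pnorm(q, p$mean, sqrt(p$var)),
    lognormal = stats::plnorm(q, p$meanlog, sqrt(p$varlog)),
    point = as.numeric(q >= p$value)
  )
}

#' Untruncated quantile function of a prior specification
#'
#' @param spec A [prior_spec()].
#' @param p Vector of probabilities.
#' @return Vector of quantiles.
#' @export
prior_quantile <- function(spec, p) {
  pp <- spec$params
  switch(spec$family,
    beta = stats::qbeta(p, pp$shape1, pp$shape2),
    normal = stats::qnorm(p, pp$mean, sqrt(pp$var)),
    lognormal = stats::qlnorm(p, pp$meanlog, sqrt(pp$varlog)),
    point = rep(pp$value, length(p))
  )
}

# support of the untruncated family
prior_support <- function(spec) {
  switch(spec$family,
    beta = c(0, 1),
    normal = c(-Inf, Inf),
    lognormal = c(0, Inf),
    point = rep(spec$params$value, 2L)
  )
}

# mean of the untruncated family (used for optimiser starting values etc.)
prior_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    beta = p$shape1 / (p$shape1 + p$shape2),
    normal = p$mean,
    lognormal = exp(p$meanlog + p$varlog / 2),
    point = p$value
  )
}

#' Sample from a (possibly truncated) prior
#'
#' Draws from the prior by inversion: `u ~ U(F(lower), F(upper))` mapped
#' through the quantile function, so truncation renormalises the density
#' rather than clipping draws to the bounds. `lower`/`upper` may be
#' vectors of length `n` for per-draw bounds (used when a constraint on
#' one quantity depends on the sampled value of another).
#'
#' @param spec A [prior_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @param lower,upper Truncation bounds; default those stored in `spec`.
#' @return Numeric vector of `n` draws, strictly inside the bounds.
#' @examples
#' sample_prior(prior_spec("beta", shape1 = 60, shape2 = 40), 5, seed = 1)
#' @export
sample_prior <- function(spec, n, seed = NULL,
                         lower = spec$lower, upper = spec$upper) {
  stopifnot(n >= 1)
  with_seed_(seed, {
    if (spec$family == "point") {
      v <- spec$params$value
      lo <- lower %||% -Inf; hi <- upper %||% Inf
      if (any(v <= lo) || any(v >= hi)) {
        stop("point prior value lies outside the truncation bounds",
             call. = FALSE)
      }
      rep(v, n)
    } else {
      supp <- prior_support(spec)
      lo <- pmax(lower %||% supp[1], supp[1])
      hi <- pmin(upper %||% supp[2], supp[2])
      plo <- prior_cdf(spec, lo)
      phi <- prior_cdf(spec, hi)
      if (any(phi - plo <= 0)) {
        stop("prior places no mass inside the truncation bounds",
             call. = FALSE)
      }
      u <- stats::runif(n, plo, phi)
      prior_quantile(spec, u)
    }
  })
}

#' Joint prior draws of control and experimental survival rates
#'
#' Implements the elicitation model for survival rates at an anchor time
#' t0: the control rate S1(t0) has its own prior; the difference
#' rho = S2(t0) - S1(t0) is a priori independent of S1(t0), but each draw
#' of rho is truncated (by renormalisation) to (-S1, 1 - S1) so that the
#' experimental rate S2(t0) = S1(t0) + rho always lies in (0, 1). The
#' truncation bounds are re-derived for every draw of S1(t0).
#'
#' @param s1_prior Prior for S1(t0); must be supported on (0, 1).
#' @param rho_prior Prior for the survival difference rho.
#' @param n Number of joint draws.
#' @param seed Optional integer seed.
#' @return A data frame with columns `s1`, `s2`, `rho`, all in (0, 1) for
#'   `s1`/`s2`.
#' @examples
#' s1 <- prior_spec("beta", shape1 = 60, shape2 = 40)
#' rho <- prior_spec("normal", mean = 0.2, var = 0.05)
#' draws <- sample_joint_rates(s1, rho, 1000, seed = 1)
#' mean(draws$s2 > draws$s1) # prior probability of superiority
#' @export
sample_joint_rates <- function(s1_prior, rho_prior, n, seed = NULL) {
  supp <- prior_support(s1_prior)
  if (supp[1] < 0 || supp[2] > 1) {
    stop("s1_prior must be supported on (0, 1)", call. = FALSE)
  }
  with_seed_(seed, {
    s1 <- sample_prior(s1_prior, n)
    lo <- pmax(-s1, rho_prior$lower %||% -Inf)
    hi <- pmin(1 - s1, rho_prior$upper %||% Inf)
    rho <- sample_prior(rho_prior, n, lower = lo, upper = hi)
    data.frame(s1 = s1, s2 = s1 + rho, rho = rho)
  })
}

# run expr under a temporary seed when one is supplied
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
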