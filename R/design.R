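#' Two-arm trial design
#'
#' Describes a two-arm randomised trial with uniform patient accrual over
#' `(0, R)` and administrative censoring at the total trial length `T`
#' (both on the calendar clock; survival time runs on the patient clock
#' from entry). Group 1 is the control arm, group 2 the experimental arm.
#'
#' @param R Recruitment period length; entry times are uniform on (0, R).
#' @param T Total trial length, `T >= R`; follow-up is `T - R` after the
#'   last entry.
#' @param N1,N2 Patients per group.
#' @param alpha Two-sided significance level of the trial's test.
#' @return An object of class `"trial_design"` with derived allocation
#'   proportions `Q1 = N1/(N1+N2)` and `Q2`.
#' @examples
#' trial_design(R = 3, T = 5, N1 = 100, N2 = 100)
#' @export
trial_design <- function(R, T, N1, N2 = N1, alpha = 0.05) {
  stopifnot(R > 0, T >= R, N1 >= 1, N2 >= 1, alpha > 0, alpha < 1)
  structure(
    list(R = R, T = T, N1 = N1, N2 = N2,
         Q1 = N1 / (N1 + N2), Q2 = N2 / (N1 + N2), alpha = alpha),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> recruitment R =", x$R, ", total length T =", x$T,
      "\n  N1 =", x$N1, ", N2 =", x$N2,
      sprintf("(Q1 = %.3f, Q2 = %.3f)", x$Q1, x$Q2),
      ", two-sided alpha =", x$alpha, "\n")
  invisible(x)
}

#' Copy a design with new per-group sample sizes
#'
#' Convenience for sample-size searches and curves: keeps `R`, `T` and
#' `alpha`, replaces `N1`/`N2`.
#'
#' @param design A [trial_design()].
#' @param N1,N2 New per-group sizes (`N2` defaults to `N1`).
#' @return A [trial_design()].
#' @export
design_with_n <- function(design, N1, N2 = N1) {
  trial_design(design$R, design$T, N1, N2, design$alpha)
}

#' Composite Simpson quadrature grid over the event-probability window
#'
#' Event probabilities under uniform accrual reduce to averages of the
#' survivor function over follow-up times `u` in `[T - R, T]`. This grid
#' holds `H` equally spaced nodes on that interval together with the
#' composite Simpson weights 1, 4, 2, 4, ..., 4, 1.
#'
#' @param design A [trial_design()].
#' @param H Number of nodes; must be odd and at least 3. The default 11
#'   is the convention used throughout the package's worked examples.
#' @return An object of class `"quadrature_grid"` with `nodes`, `weights`
#'   and step `h = R/(H-1)`.
#' @export
quadrature_grid <- function(design, H = 11) {
  if (H < 3 || H %% 2 == 0) stop("H must be odd and >= 3", call. = FALSE)
  nodes <- seq(design$T - design$R, design$T, length.out = H)
  weights <- c(1, rep(c(4, 2), length.out = H - 2L), 1)
  weights[H - 1L] <- 4   # pattern ends ..., 4, 1
  structure(list(H = H, nodes = nodes, weights = weights,
                 h = design$R / (H - 1)),
            class = "quadrature_grid")
}

#' Composite Simpson integral on a quadrature grid
#'
#' @param values Function values at the grid nodes (length `H`).
#' @param grid A [quadrature_grid()].
#' @return The composite Simpson estimate `(h/3) * sum(w * values)`;
#'   exact for cubics.
#' @examples
#' d <- trial_design(R = 1, T = 1, N1 = 10)
#' g <- quadrature_grid(d, H = 5)
#' simpson_integral(g$nodes^3, g) # integral of t^3 on [0,1] = 0.25
#' @export
simpson_integral <- function(values, grid) {
  stopifnot(inherits(grid, "quadrature_grid"), length(values) == grid$H)
  grid$h / 3 * sum(grid$weights * values)
}

#' Assurance estimate container
#'
#' @param estimate Monte Carlo assurance estimate in `[0, 1]`.
#' @param M Number of Monte Carlo iterations.
#' @param superiority Prior probability that the experimental treatment
#'   is truly superior -- the cap the assurance converges to as the
#'   sample size grows.
#' @param model Model tag: `"exponential"`, `"weibull"` or `"logrank"`.
#' @param seed Seed used, or `NULL`.
#' @return Object of class `"assurance_result"` with the binomial Monte
#'   Carlo standard error `sqrt(estimate * (1 - estimate) / M)`.
#' @keywords internal
#' @export
assurance_result <- function(estimate, M, superiority, model, seed = NULL) {
  stopifnot(estimate >= 0, estimate <= 1, M >= 1)
  structure(
    list(estimate = estimate,
         se = sqrt(estimate * (1 - estimate) / M),
         M = M, superiority = superiority, model = model, seed = seed),
    class = "assurance_result"
  )
}

#' @export
print.assurance_result <- function(x, ...) {
  cat(sprintf("<assurance_result> model = %s\n", x$model))
  cat(sprintf("  assurance = %.4f (MC SE %.4f, M = %g)\n",
              x$estimate, x$se, x$M))
  cat(sprintf("  prior P(superiority) = %.4f (cap as N -> Inf)\n",
              x$superiority))
  if (!is.null(x$seed)) cat("  seed =", x$seed, "\n")
  invisible(x)
}
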