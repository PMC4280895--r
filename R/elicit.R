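#' Trial-roulette judgement
#'
#' In the trial-roulette elicitation format the expert distributes chips
#' across equal-width bins spanning the plausible range of the quantity;
#' the proportion of chips in a bin is the elicited probability of the
#' quantity falling in that bin.
#'
#' @param lower,upper Range of plausible values (`lower < upper`).
#' @param chips Non-negative integer vector, one entry per bin; bins are
#'   equal-width subdivisions of `(lower, upper)`.
#' @return An object of class `"roulette_judgement"` with bin edges and
#'   elicited probabilities.
#' @examples
#' roulette_judgement(0, 0.5, chips = c(0, 1, 3, 6, 5, 3, 1, 1, 0, 0))
#' @export
roulette_judgement <- function(lower, upper, chips) {
  stopifnot(lower < upper, length(chips) >= 2, all(chips >= 0),
            all(chips == round(chips)))
  if (sum(chips) == 0) stop("at least one chip must be placed", call. = FALSE)
  if (sum(chips > 0) < 2) {
    stop("all chips in a single bin: the judgement is degenerate; ",
         "use a point prior instead", call. = FALSE)
  }
  edges <- seq(lower, upper, length.out = length(chips) + 1L)
  structure(
    list(edges = edges, chips = chips, total = sum(chips),
         probs = chips / sum(chips)),
    class = "roulette_judgement"
  )
}

#' Quartile judgement
#'
#' @param q25,q50,q75 Elicited lower quartile, median and upper quartile
#'   of the uncertain quantity (`q25 < q50 < q75`).
#' @return An object of class `"quartile_judgement"`.
#' @export
quartile_judgement <- function(q25, q50, q75) {
  stopifnot(q25 < q50, q50 < q75)
  structure(list(q = c(q25 = q25, q50 = q50, q75 = q75)),
            class = "quartile_judgement")
}

# parameter transforms: optimise unconstrained, map back to the family scale
par_to_spec <- function(family, par) {
  switch(family,
    beta = prior_spec("beta", shape1 = exp(par[1]), shape2 = exp(par[2])),
    normal = prior_spec("normal", mean = par[1], var = exp(par[2])),
    lognormal = prior_spec("lognormal", meanlog = par[1], varlog = exp(par[2]))
  )
}

# moment-matched starting values from a mean/variance summary
start_par <- function(family, m, v) {
  v <- max(v, 1e-8)
  switch(family,
    beta = {
      m <- min(max(m, 1e-3), 1 - 1e-3)
      v <- min(v, m * (1 - m) * 0.99)
      nu <- m * (1 - m) / v - 1
      log(c(m * nu, (1 - m) * nu))
    },
    normal = c(m, log(v)),
    lognormal = {
      m <- max(m, 1e-6)
      s2 <- log(1 + v / m^2)
      c(log(m) - s2 / 2, log(max(s2, 1e-8)))
    }
  )
}

ls_fit <- function(family, objective, m, v) {
  starts <- list(start_par(family, m, v),
                 start_par(family, m, v * 4),
                 start_par(family, m, v / 4))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, objective, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("least-squares fit failed to converge", call. = FALSE)
  # polish with Nelder-Mead from the best point (flat beta surfaces)
  best <- stats::optim(best$par, objective,
                       control = list(maxit = 2000, reltol = 1e-12))
  best
}

#' Fit a parametric prior to roulette judgements
#'
#' Chooses the family member whose bin probabilities (CDF differences at
#' the bin edges) are closest in least squares to the elicited chip
#' proportions. The achieved sum of squared differences is attached to
#' the result (attribute `"ssq"`) as feedback on the adequacy of the fit.
#'
#' @param judgement A [roulette_judgement()].
#' @param family `"beta"`, `"normal"` or `"lognormal"`.
#' @return A [prior_spec()] with attributes `ssq` (achieved sum of
#'   squares) and `fitted_probs` (fitted bin probabilities).
#' @examples
#' j <- roulette_judgement(0.1, 0.3, chips = c(1, 2, 4, 6, 4, 2, 1, 0, 0, 0))
#' fit_prior_roulette(j, "normal")
#' @export
fit_prior_roulette <- function(judgement,
                               family = c("beta", "normal", "lognormal")) {
  stopifnot(inherits(judgement, "roulette_judgement"))
  family <- match.arg(family)
  edges <- judgement$edges
  probs <- judgement$probs
  supp <- switch(family, beta = c(0, 1), normal = c(-Inf, Inf),
                 lognormal = c(0, Inf))
  occ <- which(probs > 0)
  if (edges[min(occ)] < supp[1] - 1e-12 ||
      edges[max(occ) + 1L] > supp[2] + 1e-12) {
    stop("family '", family, "' cannot cover the occupied bins", call. = FALSE)
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  m <- sum(mids * probs)
  v <- sum((mids - m)^2 * probs)
  objective <- function(par) {
    spec <- try(par_to_spec(family, par), silent = TRUE)
    if (inherits(spec, "try-error")) return(1e10)
    fitted <- diff(prior_cdf(spec, edges))
    sum((fitted - probs)^2)
  }
  best <- ls_fit(family, objective, m, v)
  spec <- par_to_spec(family, best$par)
  attr(spec, "ssq") <- best$value
  attr(spec, "fitted_probs") <- diff(prior_cdf(spec, edges))
  spec
}

#' Fit a parametric prior to elicited quartiles
#'
#' Fits by least squares on the probability scale: the parameters
#' minimise \eqn{\sum_p (F(q_p) - p)^2} over \eqn{p = 0.25, 0.5, 0.75},
#' the same objective used for roulette bins, so both judgement formats
#' are fitted under one convention.
#'
#' @param judgement A [quartile_judgement()] or a numeric vector
#'   `c(q25, q50, q75)`.
#' @param family `"beta"`, `"normal"` or `"lognormal"`.
#' @return A [prior_spec()] with attribute `ssq`.
#' @examples
#' # Table-style control survival-rate quartiles
#' fit_prior_quartiles(c(0.15, 0.2, 0.23), "beta")
#' @export
fit_prior_quartiles <- function(judgement,
                                family = c("beta", "normal", "lognormal")) {
  if (is.numeric(judgement) && length(judgement) == 3L) {
    judgement <- quartile_judgement(judgement[1], judgement[2], judgement[3])
  }
  stopifnot(inherits(judgement, "quartile_judgement"))
  family <- match.arg(family)
  q <- judgement$q
  supp <- switch(family, beta = c(0, 1), normal = c(-Inf, Inf),
                 lognormal = c(0, Inf))
  if (q[1] <= supp[1] || q[3] >= supp[2]) {
    stop("elicited quartiles lie outside the support of family '",
         family, "'", call. = FALSE)
  }
  target <- c(0.25, 0.5, 0.75)
  # moment summary from a normal read of the quartiles
  m <- q[[2]]
  v <- ((q[[3]] - q[[1]]) / (2 * stats::qnorm(0.75)))^2
  objective <- function(par) {
    spec <- try(par_to_spec(family, par), silent = TRUE)
    if (inherits(spec, "try-error")) return(1e10)
    sum((prior_cdf(spec, q) - target)^2)
  }
  best <- ls_fit(family, objective, m, v)
  spec <- par_to_spec(family, best$par)
  attr(spec, "ssq") <- best$value
  spec
}

#' Read judgement files
#'
#' Plain delimited text: a roulette file has one row per bin with columns
#' `lower, upper, chips`; a quartile file has a single row with columns
#' `q25, q50, q75`. A header line is optional.
#'
#' @param path Path to the file.
#' @return A [roulette_judgement()] or [quartile_judgement()].
#' @export
read_roulette <- function(path) {
  x <- utils::read.table(path, header = file_has_header_(path))
  stopifnot(ncol(x) >= 3)
  lo <- x[[1]]; hi <- x[[2]]; chips <- x[[3]]
  if (any(abs(lo[-1] - hi[-length(hi)]) > 1e-9)) {
    stop("roulette bins must be contiguous", call. = FALSE)
  }
  roulette_judgement(lo[1], hi[length(hi)], chips)
}

#' @rdname read_roulette
#' @export
read_quartiles <- function(path) {
  x <- utils::read.table(path, header = file_has_header_(path))
  stopifnot(ncol(x) >= 3, nrow(x) == 1)
  quartile_judgement(x[[1]][1], x[[2]][1], x[[3]][1])
}

file_has_header_ <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[,\t ]+")[[1]]
  any(is.na(suppressWarnings(as.numeric(fields))))
}
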