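#' Right-censored survival data
#'
#' @param time Non-negative, finite observation times (event or
#'   censoring time, on the patient clock).
#' @param status 1 = event observed, 0 = right-censored.
#' @return A data frame of class `"survival_data"` with columns `time`
#'   and `status`.
#' @examples
#' survival_data(time = c(0.8, 1.0, 3.1), status = c(1, 0, 1))
#' @export
survival_data <- function(time, status) {
  stopifnot(length(time) == length(status), length(time) >= 1,
            all(is.finite(time)), all(time >= 0),
            all(status %in% c(0, 1)))
  structure(data.frame(time = as.numeric(time), status = as.integer(status)),
            class = c("survival_data", "data.frame"))
}

#' Read survival data from a delimited text file
#'
#' Two columns: observation time and status (1 = event, 0 = censored);
#' whitespace-, comma- or tab-delimited, header optional.
#'
#' @param path Path to the file.
#' @return A [survival_data()].
#' @export
read_survival_data <- function(path) {
  x <- utils::read.table(path, header = file_has_header_(path),
                         sep = "", fill = FALSE)
  if (ncol(x) == 1L) {
    x <- utils::read.table(path, header = file_has_header_(path), sep = ",")
  }
  stopifnot(ncol(x) >= 2)
  survival_data(x[[1]], x[[2]])
}

#' Historical control-arm pilot data
#'
#' The eight right-censored observations used in the package's worked
#' proportional-hazards example: times 0.8, 1.0*, 2.7*, 3.1, 5.4, 7.0*,
#' 9.2 and 12.1 months (* = censored), a classic small dataset for
#' illustrating the product-limit estimator. Also shipped as
#' `inst/extdata/km_pilot.tsv`.
#'
#' @return A [survival_data()] with 8 records.
#' @examples
#' kaplan_meier(km_pilot_data())
#' @export
km_pilot_data <- function() {
  survival_data(time = c(0.8, 1.0, 2.7, 3.1, 5.4, 7.0, 9.2, 12.1),
                status = c(1, 0, 0, 1, 1, 0, 1, 0))
}

#' Kaplan-Meier (product-limit) estimate of the survivor function
#'
#' Thin wrapper around [survival::survfit()] that exposes the estimate
#' as a right-continuous step function evaluable at any `t >= 0` via
#' [predict()]. Ties between events and censorings at the same time are
#' handled events-first (the product-limit convention).
#'
#' @param data A [survival_data()].
#' @return An object of class `"kaplan_meier"` with components `time`,
#'   `surv`, `n_risk`, `n_event` (at event times) and the fitted step
#'   function.
#' @examples
#' km <- kaplan_meier(km_pilot_data())
#' predict(km, 7)  # 0.525
#' @export
kaplan_meier <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = data)
  ev <- fit$n.event > 0
  times <- fit$time[ev]
  surv <- fit$surv[ev]
  step <- if (length(times) == 0L) {
    function(t) rep(1, length(t))  # no events: survivor stays at 1
  } else {
    stats::stepfun(times, c(1, surv))
  }
  structure(
    list(time = times, surv = surv,
         n_risk = fit$n.risk[ev], n_event = fit$n.event[ev], step = step),
    class = "kaplan_meier"
  )
}

#' @export
print.kaplan_meier <- function(x, ...) {
  cat("<kaplan_meier> product-limit estimate with", length(x$time),
      "event time(s)\n")
  if (length(x$time) > 0) {
    print(data.frame(time = x$time, n_risk = x$n_risk,
                     n_event = x$n_event, surv = round(x$surv, 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier estimate
#'
#' @param object A [kaplan_meier()] fit.
#' @param times Times at which to evaluate the survivor estimate.
#' @param ... Unused.
#' @return Survivor probabilities at `times`.
#' @export
predict.kaplan_meier <- function(object, times, ...) {
  object$step(times)
}
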