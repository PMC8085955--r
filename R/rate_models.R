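#' Construct an experience-dependent task-rate model
#'
#' A rate model maps a technician's cumulative hours of experience on one
#' task to an expected throughput in specimens per minute (SPM). The curve
#' is polynomial (linear or quadratic), carries a rate limit that caps
#' (imaging, databasing) or floors (barcoding) predictions so no simulated
#' technician is unrealistically fast or slow, and an experience limit
#' beyond which the curve is not extrapolated.
#'
#' @param task Task name, one of [task_levels()].
#' @param coefficients Numeric vector of polynomial coefficients in
#'   increasing order: `c(intercept, slope)` for a linear curve,
#'   `c(intercept, slope, quadratic)` for a quadratic one. Units: SPM,
#'   SPM/hour, SPM/hour^2.
#' @param rate_limit Positive limit in SPM applied to every prediction.
#' @param limit_direction `"max"` if `rate_limit` is a ceiling, `"min"` if
#'   it is a floor.
#' @param experience_limit Hours beyond which the curve is frozen
#'   (default 64, the cumulative-hour threshold of the underlying data).
#'
#' @return An object of class `rate_model`.
#' @examples
#' m <- rate_model("imaging", c(1.9517, 0.02118), 4, "max")
#' predict(m, hours = c(0, 10, 64))
#' @export
rate_model <- function(task, coefficients, rate_limit,
                       limit_direction = c("max", "min"),
                       experience_limit = 64) {
  task <- match.arg(task, TASKS)
  limit_direction <- match.arg(limit_direction)
  coefficients <- as.numeric(coefficients)
  if (!length(coefficients) %in% c(2L, 3L)) {
    abort("`coefficients` must have length 2 (linear) or 3 (quadratic).")
  }
  if (!is.numeric(rate_limit) || rate_limit <= 0) {
    abort("`rate_limit` must be a positive number (SPM).")
  }
  if (experience_limit <= 0) {
    abort("`experience_limit` must be positive (hours).")
  }
  structure(
    list(
      task = task,
      form = if (length(coefficients) == 2L) "linear" else "quadratic",
      coefficients = coefficients,
      rate_limit = rate_limit,
      limit_direction = limit_direction,
      experience_limit = experience_limit
    ),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  co <- x$coefficients
  terms <- c(
    sprintf("%.5f", co[1]),
    sprintf("%+.5f x", co[2]),
    if (length(co) == 3L) sprintf("%+.5f x^2", co[3])
  )
  cat(sprintf("<rate_model: %s (%s)>\n", x$task, x$form))
  cat("  y =", paste(terms, collapse = " "), " [SPM; x in hours]\n")
  cat(sprintf("  rate %s %.2f SPM; experience limit %g h\n",
              if (x$limit_direction == "max") "<=" else ">=",
              x$rate_limit, x$experience_limit))
  invisible(x)
}

#' Predict the task rate at given experience
#'
#' Evaluates the polynomial curve at `hours` of cumulative experience.
#' With `clamp = TRUE` (default) the rate limit is applied and the
#' experience argument is frozen at `experience_limit + 1` hours, the last
#' whole simulated hour the observed data can support.
#'
#' @param object A [rate_model()].
#' @param hours Numeric vector of cumulative experience, in hours.
#' @param clamp Apply the rate limit and experience freeze?
#' @param ... Unused.
#' @return Numeric vector of rates in specimens per minute.
#' @export
predict.rate_model <- function(object, hours, clamp = TRUE, ...) {
  if (clamp) hours <- pmin(hours, object$experience_limit + 1)
  co <- object$coefficients
  y <- co[1] + co[2] * hours
  if (length(co) == 3L) y <- y + co[3] * hours^2
  if (clamp) {
    y <- if (object$limit_direction == "max") {
      pmin(y, object$rate_limit)
    } else {
      pmax(y, object$rate_limit)
    }
  }
  y
}

#' Published rate-curve models for the three digitization tasks
#'
#' The canonical fitted curves relating task rate (SPM) to cumulative task
#' experience (hours): imaging `y = 1.95170 + 0.02118x` capped at 4.00 SPM,
#' skeletal databasing `y = 2.55659 + 0.02760x` capped at 6.50 SPM, and
#' barcoding `y = 3.7216 + 0.09928x - 0.00175x^2` floored at 3.00 SPM, all
#' with a 64-hour experience limit. These are the default models for labor
#' projection, so projections do not depend on refitting any data.
#'
#' @return Named list of three [rate_model()] objects
#'   (`barcoding`, `imaging`, `skeletal_databasing`).
#' @export
canonical_rate_models <- function() {
  list(
    barcoding = rate_model("barcoding", c(3.7216, 0.09928, -0.00175),
                           rate_limit = 3.00, limit_direction = "min"),
    imaging = rate_model("imaging", c(1.95170, 0.02118),
                         rate_limit = 4.00, limit_direction = "max"),
    skeletal_databasing = rate_model("skeletal_databasing",
                                     c(2.55659, 0.02760),
                                     rate_limit = 6.50,
                                     limit_direction = "max")
  )
}
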