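#' Cumulative task experience per technician
#'
#' Within each (reporter, task) group, sorted by ascending session date
#' (ties keep input order), computes the technician's cumulative hours on
#' that task at report submission — i.e. including the session itself —
#' and the session's rate in specimens per minute.
#'
#' @param entries Cleaned session-report tibble.
#' @return The input with `cumulative_task_hours` and `rate` columns
#'   added, ordered by reporter, task, and date.
#' @examples
#' s <- tibble::tibble(entry_id = c("a", "b"), reporter_id = "t1",
#'                     session_date = as.Date(c("2017-01-01", "2017-01-02")),
#'                     collection_code = "TENN", task = "imaging",
#'                     minutes = c(120, 90), specimens = c(240, 210),
#'                     setback_text = "")
#' cumulative_task_hours(s)
#' @export
cumulative_task_hours <- function(entries) {
  as_tibble(entries) |>
    mutate(.orig = row_number()) |>
    arrange(.data$reporter_id, .data$task, .data$session_date, .data$.orig) |>
    group_by(.data$reporter_id, .data$task) |>
    mutate(cumulative_task_hours = cumsum(.data$minutes) / 60) |>
    ungroup() |>
    mutate(rate = .data$specimens / .data$minutes) |>
    select(-".orig")
}

#' Group session rates into shared experience bins
#'
#' Assigns each record with `cumulative_task_hours` below `limit` to a
#' half-open bin `[2k, 2k + 2)` and summarises the rate within each
#' (task, bin): unweighted mean, min, max, and entry count. Records at or
#' beyond the limit are excluded — beyond it too few technicians remain
#' for the bins to be representative.
#'
#' @param records Output of [cumulative_task_hours()].
#' @param bin_width Bin width in hours (default 2).
#' @param limit Experience threshold in hours (default 64).
#' @return Tibble with columns `task`, `bin_start`, `bin_end`,
#'   `n_entries`, `mean_rate`, `min_rate`, `max_rate`; empty bins are
#'   absent.
#' @export
bin_by_experience <- function(records, bin_width = 2, limit = 64) {
  stopifnot(bin_width > 0, limit > 0)
  records |>
    filter(.data$cumulative_task_hours < limit) |>
    mutate(bin_start = floor(.data$cumulative_task_hours / bin_width) *
             bin_width) |>
    summarise(
      n_entries = n(),
      mean_rate = mean(.data$rate),
      min_rate = min(.data$rate),
      max_rate = max(.data$rate),
      .by = c("task", "bin_start")
    ) |>
    mutate(bin_end = .data$bin_start + bin_width) |>
    select("task", "bin_start", "bin_end", "n_entries",
           "mean_rate", "min_rate", "max_rate") |>
    arrange(.data$task, .data$bin_start)
}

# Default rate limits by task, used when fitting returns a model for a
# task whose published limit is known.
default_rate_limits <- function(task) {
  switch(task,
         barcoding = list(limit = 3.00, direction = "min"),
         imaging = list(limit = 4.00, direction = "max"),
         skeletal_databasing = list(limit = 6.50, direction = "max"),
         NULL)
}

#' Fit a rate-vs-experience curve to binned rates
#'
#' Ordinary least squares of bin mean rate against bin midpoint
#' (`bin_start + bin_width / 2`), unweighted across bins. Linear fits
#' need at least 3 bins, quadratic at least 4. The returned model carries
#' the task's rate limit (the published extreme for the three primary
#' tasks unless overridden) and the experience limit.
#'
#' @param bins Binned rates for a single task from [bin_by_experience()].
#' @param form `"linear"` or `"quadratic"`.
#' @param rate_limit,limit_direction Optional overrides for the clamp;
#'   defaults come from the task's published limit.
#' @param experience_limit Hours (default 64).
#' @return A [rate_model()].
#' @export
fit_rate_model <- function(bins, form = c("linear", "quadratic"),
                           rate_limit = NULL, limit_direction = NULL,
                           experience_limit = 64) {
  form <- match.arg(form)
  task <- unique(bins$task)
  if (length(task) != 1L) {
    abort("`bins` must contain exactly one task.")
  }
  needed <- if (form == "linear") 3L else 4L
  if (nrow(bins) < needed) {
    abort(sprintf("need at least %d bins for a %s fit, got %d",
                  needed, form, nrow(bins)))
  }
  x <- bins$bin_start + (bins$bin_end - bins$bin_start) / 2
  y <- bins$mean_rate
  fit <- if (form == "linear") lm(y ~ x) else lm(y ~ x + I(x^2))
  co <- unname(coef(fit))
  lim <- default_rate_limits(task)
  if (is.null(rate_limit)) {
    if (is.null(lim)) abort("no default rate limit for this task; supply one.")
    rate_limit <- lim$limit
  }
  if (is.null(limit_direction)) {
    limit_direction <- if (is.null(lim)) "max" else lim$direction
  }
  rate_model(task, co, rate_limit, limit_direction, experience_limit)
}
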