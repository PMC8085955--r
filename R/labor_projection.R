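#' Effective production rate for the k-th hour of a contract
#'
#' The turnover simulation advances in whole hours. A technician working
#' their k-th hour on a task has k hours of cumulative experience at the
#' end of that hour, so the hour's production is the rate curve evaluated
#' at `min(k, experience_limit + 1)` hours — the curve is followed through
#' the hour that ends one hour past the experience limit and frozen
#' thereafter — with the model's rate limit applied, converted to
#' specimens per hour.
#'
#' @param model A [rate_model()].
#' @param k Hour index within a contract (1-based); may be a vector.
#' @return Specimens produced per hour, same length as `k`.
#' @examples
#' m <- canonical_rate_models()$imaging
#' effective_hourly_rate(m, 1)   # 60 * (1.95170 + 0.02118)
#' effective_hourly_rate(m, 100) # frozen at 65 h of experience
#' @export
effective_hourly_rate <- function(model, k) {
  stopifnot(inherits(model, "rate_model"), all(k >= 1))
  60 * predict(model, hours = k, clamp = TRUE)
}

#' Specimens produced over one full contract
#'
#' Total production of a single simulated technician who works `duration`
#' hours on one task, accumulating experience from zero.
#'
#' @param model A [rate_model()].
#' @param duration Contract duration in hours (non-negative integer).
#' @return Specimens produced (numeric; fractional specimens are kept so
#'   accumulation across contracts is exact).
#' @export
contract_production <- function(model, duration) {
  stopifnot(duration >= 0)
  if (duration == 0) return(0)
  sum(effective_hourly_rate(model, seq_len(duration)))
}

#' Simulate labor hours under technician turnover
#'
#' Advances production hour by hour. Each simulated technician works
#' `contract_duration` hours on the task and is then replaced by a novice:
#' the experience-dependent rate resets to hour 1 while cumulative
#' production carries over. Returns the first whole hour at which
#' cumulative production reaches `specimen_count`.
#'
#' @param model A [rate_model()].
#' @param contract_duration Hours one technician spends on the task before
#'   being replaced (positive integer).
#' @param specimen_count Target number of specimens (positive).
#' @return Labor hours required (positive integer).
#' @examples
#' simulate_labor_hours(canonical_rate_models()$barcoding, 15, 10000)
#' @export
simulate_labor_hours <- function(model, contract_duration, specimen_count) {
  stopifnot(contract_duration >= 1, specimen_count >= 1)
  hourly <- effective_hourly_rate(model, seq_len(contract_duration))
  per_contract <- sum(hourly)
  within <- cumsum(hourly)
  # Whole contracts completed strictly before the target is reached; the
  # tolerance keeps exact multiples on the completed side.
  tol <- 1e-9 * max(1, specimen_count)
  full <- max(0, floor((specimen_count - tol) / per_contract))
  remaining <- specimen_count - full * per_contract
  k <- match(TRUE, within >= remaining - tol)
  as.integer(full * contract_duration + k)
}

#' Labor-projection table across contract durations and specimen counts
#'
#' Runs [simulate_labor_hours()] for every combination of contract
#' duration, task, and specimen count, and adds a `Combined` row per
#' duration/count: the sum of the three task estimates, i.e. the labor to
#' barcode, image, and skeletally database the same specimens when each
#' task is staffed under its own contract duration.
#'
#' @param models Named list of [rate_model()]s, one per primary task
#'   (default [canonical_rate_models()]).
#' @param durations Contract durations in hours.
#' @param counts Specimen counts.
#' @return A tibble with columns `contract_duration`, `task` (the three
#'   tasks plus `"Combined"`), `specimen_count`, `hours`.
#' @examples
#' projection_table(durations = 15, counts = 10000)
#' @export
projection_table <- function(models = canonical_rate_models(),
                             durations = c(15, 30, 45, 60, 90, 135),
                             counts = c(10000, 20000, 30000, 40000, 50000,
                                        75000, 100000, 125000, 150000,
                                        200000, 250000, 300000, 500000)) {
  stopifnot(length(durations) >= 1, length(counts) >= 1)
  if (!setequal(names(models), PRIMARY_TASKS)) {
    abort("`models` must be a named list covering exactly the three primary tasks.")
  }
  grid <- tidyr::expand_grid(
    contract_duration = as.integer(durations),
    task = PRIMARY_TASKS,
    specimen_count = as.integer(counts)
  )
  per_task <- grid |>
    rowwise() |>
    mutate(hours = simulate_labor_hours(models[[.data$task]],
                                        .data$contract_duration,
                                        .data$specimen_count)) |>
    ungroup()
  combined <- per_task |>
    summarise(hours = sum(.data$hours),
              .by = c("contract_duration", "specimen_count")) |>
    mutate(task = "Combined")
  bind_rows(per_task, combined) |>
    mutate(task = factor(.data$task, levels = c(PRIMARY_TASKS, "Combined"))) |>
    arrange(.data$contract_duration, .data$task, .data$specimen_count) |>
    mutate(task = as.character(.data$task))
}

#' Reshape a projection table to the wide (counts-as-columns) layout
#'
#' @param table A tidy projection table from [projection_table()].
#' @return A tibble with one row per (contract duration, task) and one
#'   column per specimen count.
#' @export
projection_wide <- function(table) {
  table |>
    tidyr::pivot_wider(names_from = "specimen_count", values_from = "hours")
}

#' Labor savings from longer technician retention
#'
#' Fractional reduction in Combined labor hours when moving from the
#' shortest to the longest contract duration in a projection table, at a
#' given specimen count.
#'
#' @param table A projection table from [projection_table()] containing
#'   `Combined` rows.
#' @param count Specimen count to evaluate.
#' @return Fraction in `[0, 1)` (e.g. `0.19` means 19% fewer hours).
#' @export
retention_savings <- function(table, count) {
  combined <- table |>
    filter(.data$task == "Combined", .data$specimen_count == count)
  if (nrow(combined) == 0) {
    abort(sprintf("specimen count %s not present in the table", count))
  }
  short <- combined$hours[which.min(combined$contract_duration)]
  long <- combined$hours[which.max(combined$contract_duration)]
  (short - long) / short
}

#' Printed labor-projection reference table
#'
#' The published 6 x 13 projection grid (three tasks plus Combined, in
#' hours), shipped as a plain-text fixture for regression-testing the
#' simulator.
#'
#' @return A tidy tibble with columns `contract_duration`, `task`,
#'   `specimen_count`, `hours` (312 rows).
#' @export
reference_projection_table <- function() {
  path <- system.file("extdata", "projection_reference.csv",
                      package = "herblabor", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    contract_duration = readr::col_integer(),
                    task = readr::col_character(),
                    specimen_count = readr::col_integer(),
                    hours = readr::col_integer()
                  ))
}
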