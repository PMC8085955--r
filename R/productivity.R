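#' Project-wide productivity totals
#'
#' Bundles the totals needed to compute project-wide digitization rates:
#' per-task specimen totals for the three primary tasks and the hour
#' denominators at each cleaning stage.
#'
#' @param specimens Named numeric vector of total specimens per primary
#'   task (`barcoding`, `imaging`, `skeletal_databasing`).
#' @param hours_all Total reported hours across all tasks.
#' @param hours_primary Hours spent on the three primary tasks only
#'   (must not exceed `hours_all`).
#' @param stage `"pre_cleaning"` or `"post_cleaning"`.
#' @return An object of class `productivity_totals`.
#' @export
productivity_totals <- function(specimens, hours_all, hours_primary = NA_real_,
                                stage = c("pre_cleaning", "post_cleaning")) {
  stage <- match.arg(stage)
  if (!setequal(names(specimens), PRIMARY_TASKS)) {
    abort("`specimens` must name exactly the three primary tasks.")
  }
  if (any(specimens < 0) || hours_all < 0) {
    abort("totals must be non-negative.")
  }
  if (!is.na(hours_primary) && hours_primary > hours_all) {
    abort("`hours_primary` cannot exceed `hours_all`.")
  }
  structure(list(specimens = specimens[PRIMARY_TASKS],
                 hours_all = hours_all,
                 hours_primary = hours_primary,
                 stage = stage),
            class = "productivity_totals")
}

#' Project-wide digitization rate
#'
#' A specimen passes through all three primary tasks, so total specimens
#' digitized is taken as the arithmetic mean of the three per-task
#' specimen totals. Three conventions for the hour denominator are
#' supported: method A divides pre-cleaning specimens by all pre-cleaning
#' hours; method B divides post-cleaning specimens by all post-cleaning
#' hours; method C divides post-cleaning specimens by post-cleaning hours
#' on the primary tasks only.
#'
#' @param totals A [productivity_totals()] at the stage the method
#'   requires (pre-cleaning for A, post-cleaning for B and C).
#' @param method `"A"`, `"B"`, or `"C"`.
#' @return Unrounded rate in specimens per minute.
#' @examples
#' pre <- productivity_totals(
#'   c(barcoding = 306069, imaging = 306069, skeletal_databasing = 306069),
#'   hours_all = 7808, stage = "pre_cleaning")
#' project_wide_rate(pre, "A")
#' @export
project_wide_rate <- function(totals, method = c("A", "B", "C")) {
  stopifnot(inherits(totals, "productivity_totals"))
  method <- match.arg(method)
  wanted_stage <- if (method == "A") "pre_cleaning" else "post_cleaning"
  if (totals$stage != wanted_stage) {
    abort(sprintf("method %s requires %s totals.", method, wanted_stage))
  }
  digitized <- mean(totals$specimens)
  hours <- if (method == "C") totals$hours_primary else totals$hours_all
  if (is.na(hours) || hours <= 0) {
    abort("the required hour total is missing or zero; rate is undefined.")
  }
  digitized / (hours * 60)
}

#' Per-task digitization rate
#'
#' @param specimens Specimens processed.
#' @param hours Hours spent on the task.
#' @return Unrounded rate in specimens per minute.
#' @examples
#' task_rate(229333, 1660) # ~2.30 SPM
#' @export
task_rate <- function(specimens, hours) {
  if (any(hours <= 0)) abort("`hours` must be positive; rate is undefined.")
  specimens / (hours * 60)
}

#' Summarise setback incidence and impact
#'
#' Reports, overall and per task, how many entries carried a significant
#' setback, the hours they consumed, the mean session duration with and
#' without setbacks, and the share of pre-cleaning hours lost to
#' setbacks.
#'
#' @param all_entries The full (pre-cleaning) session table.
#' @param outcome The [clean_sessions()] outcome produced from
#'   `all_entries`.
#' @return A list with `overall` (one-row tibble) and `by_task` (tibble).
#'   Mean durations are `NaN` where a group has no sessions of that kind.
#' @export
setback_summary <- function(all_entries, outcome) {
  stopifnot(inherits(outcome, "cleaning_outcome"))
  setback_ids <- outcome$excluded$setback$entry_id
  tagged <- as_tibble(all_entries) |>
    mutate(is_setback = .data$entry_id %in% setback_ids)
  total_hours <- sum(tagged$minutes) / 60
  summarise_grp <- function(d) {
    summarise(
      d,
      n_setback = sum(.data$is_setback),
      setback_hours = sum(.data$minutes[.data$is_setback]) / 60,
      mean_minutes_setback = mean(.data$minutes[.data$is_setback]),
      mean_minutes_clean = mean(.data$minutes[!.data$is_setback])
    )
  }
  overall <- summarise_grp(tagged) |>
    mutate(setback_hour_share = .data$setback_hours / total_hours)
  by_task <- tagged |> group_by(.data$task) |> summarise_grp() |> ungroup()
  list(overall = overall, by_task = by_task)
}

#' Word frequencies across setback descriptions
#'
#' Normalizes each description ([normalize_free_text()]), splits on
#' whitespace, and counts tokens, sorted by descending count then
#' alphabetically.
#'
#' @param texts Character vector of setback descriptions.
#' @return Tibble with columns `token`, `count`.
#' @examples
#' word_frequencies(c("camera broke", "Camera settings!"))
#' @export
word_frequencies <- function(texts) {
  tokens <- unlist(strsplit(normalize_free_text(texts), " ", fixed = TRUE))
  tokens <- tokens[tokens != ""]
  if (length(tokens) == 0) {
    return(tibble(token = character(0), count = integer(0)))
  }
  tibble(token = tokens) |>
    count(.data$token, name = "count") |>
    arrange(desc(.data$count), .data$token)
}
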