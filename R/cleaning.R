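#' Normalize free-text setback descriptions
#'
#' Lowercases, strips punctuation (replaced by spaces), collapses runs of
#' whitespace, and trims. Total function: any input, including `NA`,
#' yields a canonical string (`NA` becomes `""`).
#'
#' @param text Character vector.
#' @return Character vector of canonical strings.
#' @examples
#' normalize_free_text("No Setbacks!")        # "no setbacks"
#' normalize_free_text("Camera—repair needed") # "camera repair needed"
#' @export
normalize_free_text <- function(text) {
  text <- ifelse(is.na(text), "", as.character(text))
  out <- stringr::str_to_lower(text)
  out <- stringr::str_replace_all(out, "[^\\p{L}\\p{N}\\s]+", " ")
  stringr::str_squish(out)
}

#' Classify a setback description as significant
#'
#' A report indicates a significant setback when its normalized setback
#' text is non-empty and does not match any acceptable "no setback"
#' phrase. A blank description counts as nothing to report.
#'
#' @param text Character vector of raw setback descriptions.
#' @param whitelist Canonical acceptable phrases (already normalized).
#' @return Logical vector: `TRUE` where the entry reports a setback.
#' @export
classify_setback <- function(text, whitelist = c("no", "none", "no setbacks")) {
  norm <- normalize_free_text(text)
  norm != "" & !norm %in% whitelist
}

#' Per-task rate statistics for swap detection
#'
#' Mean, standard deviation, and a low quantile of the specimens-per-minute
#' rate, computed per task over the supplied entries with positive
#' specimen counts. The "typical" mean and SD describe the candidate-clean
#' population, so they are computed over rates at or above the low
#' quantile: entries below it are exactly the swap suspects whose
#' corrupted rates would otherwise distort the reference statistics.
#'
#' @param entries Session-report tibble.
#' @param low_rate_quantile Probability defining the "suspiciously low"
#'   rate threshold (default 0.05).
#' @return Tibble with columns `task`, `mean_rate`, `sd_rate`, `low_rate`.
#' @export
task_rate_stats <- function(entries, low_rate_quantile = 0.05) {
  entries |>
    filter(.data$specimens > 0) |>
    mutate(rate = .data$specimens / .data$minutes) |>
    mutate(low_rate = quantile(.data$rate, low_rate_quantile, names = FALSE),
           .by = "task") |>
    filter(.data$rate >= .data$low_rate) |>
    summarise(
      mean_rate = mean(.data$rate),
      sd_rate = sd(.data$rate),
      low_rate = .data$low_rate[1],
      .by = "task"
    )
}

#' Detect swapped minutes/specimens entry errors
#'
#' An entry looks like a swapped-field error when its task rate
#' (specimens per minute) is suspiciously low — below the configured low
#' quantile for its task — while the inverse ratio (minutes per specimen)
#' is consistent with the task's typical rate, i.e. within
#' `tolerance_sd` standard deviations of the task mean. Entries with zero
#' specimens are never classified as swapped.
#'
#' @param entries Session-report tibble.
#' @param stats Per-task statistics from [task_rate_stats()].
#' @param tolerance_sd Width of the "typical rate" band in SDs (default 2).
#' @return Logical vector along the rows of `entries`.
#' @export
detect_swapped_entry <- function(entries, stats, tolerance_sd = 2) {
  joined <- entries |> left_join(stats, by = "task")
  rate <- joined$specimens / joined$minutes
  inverse <- ifelse(joined$specimens > 0,
                    joined$minutes / joined$specimens, NA_real_)
  flag <- joined$specimens > 0 &
    !is.na(joined$mean_rate) & !is.na(joined$sd_rate) &
    rate < joined$low_rate &
    abs(inverse - joined$mean_rate) <= tolerance_sd * joined$sd_rate
  flag & !is.na(flag)
}

#' Flag extreme numeric outliers
#'
#' Flags entries whose `minutes` or `specimens` value deviates from its
#' field mean by strictly more than `threshold_sd` standard deviations,
#' with mean and SD computed per task over the supplied entries. Fields
#' with zero variance (or a single entry) produce no flags.
#'
#' @param entries Session-report tibble.
#' @param threshold_sd Unitless threshold (default 5; "exceeding" is a
#'   strict inequality).
#' @return Character vector of flagged `entry_id`s.
#' @export
flag_field_outliers <- function(entries, threshold_sd = 5) {
  stopifnot(threshold_sd > 0)
  if (nrow(entries) == 0) return(character(0))
  flagged <- entries |>
    mutate(
      across(c("minutes", "specimens"),
             ~ {
               s <- sd(.x)
               if (is.na(s) || s == 0) rep(FALSE, length(.x))
               else abs(.x - mean(.x)) > threshold_sd * s
             },
             .names = "out_{.col}"),
      .by = "task"
    )
  flagged$entry_id[flagged$out_minutes | flagged$out_specimens]
}

#' Configuration for session-report cleaning
#'
#' @param acceptable_phrases Canonical phrases meaning "no setback".
#' @param excluded_reporters Reporter ids flagged as non-representative
#'   (identified by project investigation, not algorithmically — e.g.
#'   fraudulent or inaccurate reporters).
#' @param excluded_workflow_entries Entry ids from exceptionally
#'   non-representative workflows.
#' @param outlier_sd_threshold SD threshold for extreme outliers
#'   (default 5).
#' @param swap_low_rate_quantile Low-rate trigger quantile for swapped
#'   entry detection (default 0.05).
#' @param swap_tolerance_sd Typical-rate band width in SDs (default 2).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(acceptable_phrases = c("no", "none", "no setbacks"),
                            excluded_reporters = character(0),
                            excluded_workflow_entries = character(0),
                            outlier_sd_threshold = 5,
                            swap_low_rate_quantile = 0.05,
                            swap_tolerance_sd = 2) {
  if (outlier_sd_threshold <= 0) abort("`outlier_sd_threshold` must be > 0.")
  structure(
    list(acceptable_phrases = normalize_free_text(acceptable_phrases),
         excluded_reporters = as.character(excluded_reporters),
         excluded_workflow_entries = as.character(excluded_workflow_entries),
         outlier_sd_threshold = outlier_sd_threshold,
         swap_low_rate_quantile = swap_low_rate_quantile,
         swap_tolerance_sd = swap_tolerance_sd),
    class = "cleaning_config"
  )
}

CLEANING_CATEGORIES <- c("nonrepresentative_reporter",
                         "nonrepresentative_workflow",
                         "entry_error", "setback", "extreme_outlier")

#' Five-stage cleaning of session reports
#'
#' Partitions session reports into kept entries and five exclusion
#' categories, applied in a fixed order: (1) non-representative reporters
#' (config-listed), (2) non-representative workflow entries
#' (config-listed), (3) apparent entry errors via
#' [detect_swapped_entry()], (4) significant setbacks via
#' [classify_setback()], and (5) extreme outliers via
#' [flag_field_outliers()] computed on the survivors of stages 1–4.
#' Every input entry lands in exactly one partition.
#'
#' @param entries Session-report tibble.
#' @param config A [cleaning_config()].
#' @return An object of class `cleaning_outcome`: a list with `kept`
#'   (tibble), `excluded` (named list of tibbles, one per category), and
#'   `audit` (tibble of per-category entry counts and hour totals).
#' @export
clean_sessions <- function(entries, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  remaining <- as_tibble(entries)
  excluded <- list()

  take <- function(flag) {
    out <- remaining[flag, , drop = FALSE]
    remaining <<- remaining[!flag, , drop = FALSE]
    out
  }

  excluded$nonrepresentative_reporter <-
    take(remaining$reporter_id %in% config$excluded_reporters)
  excluded$nonrepresentative_workflow <-
    take(remaining$entry_id %in% config$excluded_workflow_entries)

  if (nrow(remaining) > 0) {
    # reference statistics describe the candidate-clean population, so
    # obvious extreme outliers are left out of them (they are still
    # categorized at stage 5)
    candidate <- remaining[
      !remaining$entry_id %in%
        flag_field_outliers(remaining, config$outlier_sd_threshold), ,
      drop = FALSE]
    if (nrow(candidate) == 0) candidate <- remaining
    stats <- task_rate_stats(candidate, config$swap_low_rate_quantile)
    excluded$entry_error <-
      take(detect_swapped_entry(remaining, stats, config$swap_tolerance_sd))
  } else {
    excluded$entry_error <- remaining
  }

  excluded$setback <-
    take(classify_setback(remaining$setback_text, config$acceptable_phrases))

  if (nrow(remaining) > 0) {
    out_ids <- flag_field_outliers(remaining, config$outlier_sd_threshold)
    excluded$extreme_outlier <- take(remaining$entry_id %in% out_ids)
  } else {
    excluded$extreme_outlier <- remaining
  }

  audit <- bind_rows(
    tibble(category = "kept",
           n_entries = nrow(remaining),
           hours = sum(remaining$minutes) / 60),
    bind_rows(lapply(CLEANING_CATEGORIES, function(cat) {
      tibble(category = cat,
             n_entries = nrow(excluded[[cat]]),
             hours = sum(excluded[[cat]]$minutes) / 60)
    }))
  ) |>
    mutate(hours = ifelse(is.na(.data$hours), 0, .data$hours))

  structure(list(kept = remaining, excluded = excluded, audit = audit),
            class = "cleaning_outcome")
}

#' @export
print.cleaning_outcome <- function(x, ...) {
  total <- sum(x$audit$n_entries)
  cat(sprintf("<cleaning_outcome: %d entries -> %d kept>\n",
              total, nrow(x$kept)))
  print(x$audit)
  invisible(x)
}
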