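#' Pipeline configuration
#'
#' Bundles the per-stage configuration for an end-to-end run: where the
#' sessions come from (a CSV on disk, or the synthetic generator), how
#' they are cleaned, how rates are binned and fitted, and which grid the
#' labor projection covers.
#'
#' @param input_sessions Path to a sessions CSV, or `NULL` to generate
#'   synthetic sessions.
#' @param output_dir Directory for all artifacts (created if needed).
#' @param generator A [generator_config()] (used when `input_sessions`
#'   is `NULL`).
#' @param cleaning A [cleaning_config()]. When sessions are generated and
#'   no reporters are explicitly excluded, the generator's fraudulent
#'   reporters are excluded automatically (mirroring how such reporters
#'   are identified by project oversight rather than by the data).
#' @param bin_width,experience_limit Binning parameters in hours.
#' @param durations,counts Projection grid.
#' @param model_source `"canonical"` (published curves; the default, so a
#'   projection needs no data at all) or `"fitted"` (curves refit to the
#'   cleaned input sessions).
#' @param seed Seed forwarded to the generator.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_sessions = NULL,
                            output_dir = tempfile("herblabor-run-"),
                            generator = generator_config(seed = seed),
                            cleaning = cleaning_config(),
                            bin_width = 2,
                            experience_limit = 64,
                            durations = c(15, 30, 45, 60, 90, 135),
                            counts = c(10000, 20000, 30000, 40000, 50000,
                                       75000, 100000, 125000, 150000,
                                       200000, 250000, 300000, 500000),
                            model_source = c("canonical", "fitted"),
                            seed = 1L) {
  model_source <- match.arg(model_source)
  if (!is.null(input_sessions) && !file.exists(input_sessions)) {
    abort(sprintf("input sessions file not found: %s", input_sessions))
  }
  structure(list(input_sessions = input_sessions,
                 output_dir = output_dir,
                 generator = generator,
                 cleaning = cleaning,
                 bin_width = bin_width,
                 experience_limit = experience_limit,
                 durations = durations,
                 counts = counts,
                 model_source = model_source,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: obtain sessions (generate or read),
#' clean them with audit accounting, compute cumulative experience, bin
#' and fit rate curves, run the turnover labor projection, and write a
#' productivity/setback report. Every intermediate artifact is written to
#' `config$output_dir` as CSV (models as JSON) and listed in the returned
#' manifest. Reruns with the same config and seed are identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages?
#' @return Invisibly, a list with `files` (named paths), `audit` (the
#'   cleaning audit tibble), and `models` (the models used for
#'   projection).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- function(name) file.path(config$output_dir, name)
  files <- list()

  # -- sessions -------------------------------------------------------
  if (is.null(config$input_sessions)) {
    say("generating synthetic sessions (seed %d)", config$generator$seed)
    gen <- generate_sessions(config$generator)
    sessions <- gen$sessions
    readr::write_csv(gen$labels, out("labels.csv"))
    files$labels <- out("labels.csv")
    cleaning <- config$cleaning
    if (length(cleaning$excluded_reporters) == 0 &&
        config$generator$fraudulent_reporter_count > 0) {
      fraud <- unique(sessions$reporter_id[
        sessions$entry_id %in%
          gen$labels$entry_id[gen$labels$label == "fraudulent_reporter"]])
      cleaning$excluded_reporters <- fraud
    }
  } else {
    say("reading sessions from %s", config$input_sessions)
    sessions <- read_sessions(config$input_sessions)
    cleaning <- config$cleaning
  }
  write_sessions(sessions, out("sessions.csv"))
  files$sessions <- out("sessions.csv")

  # -- cleaning -------------------------------------------------------
  outcome <- clean_sessions(sessions, cleaning)
  say("cleaning: kept %d of %d entries", nrow(outcome$kept), nrow(sessions))
  readr::write_csv(outcome$audit, out("audit.csv"))
  exclusions <- bind_rows(lapply(names(outcome$excluded), function(cat) {
    mutate(outcome$excluded[[cat]], category = cat)
  }))
  readr::write_csv(exclusions, out("exclusions.csv"))
  files$audit <- out("audit.csv")
  files$exclusions <- out("exclusions.csv")

  # -- experience model ----------------------------------------------
  records <- cumulative_task_hours(outcome$kept)
  bins <- bin_by_experience(records, config$bin_width,
                            config$experience_limit)
  readr::write_csv(bins, out("bins.csv"))
  files$bins <- out("bins.csv")

  models <- canonical_rate_models()
  if (config$model_source == "fitted") {
    say("fitting rate models to cleaned sessions")
    models <- lapply(setNames(PRIMARY_TASKS, PRIMARY_TASKS), function(tk) {
      fit_rate_model(filter(bins, .data$task == tk),
                     form = if (tk == "barcoding") "quadratic" else "linear",
                     experience_limit = config$experience_limit)
    })
  }
  model_df <- lapply(models, function(m) {
    list(task = m$task, form = m$form, coefficients = m$coefficients,
         rate_limit = m$rate_limit, limit_direction = m$limit_direction,
         experience_limit = m$experience_limit)
  })
  jsonlite::write_json(model_df, out("models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$models <- out("models.json")

  # -- labor projection ----------------------------------------------
  say("projecting labor over %d durations x %d counts",
      length(config$durations), length(config$counts))
  proj <- projection_table(models, config$durations, config$counts)
  readr::write_csv(proj, out("projection.csv"))
  readr::write_csv(projection_wide(proj), out("projection_wide.csv"))
  files$projection <- out("projection.csv")
  files$projection_wide <- out("projection_wide.csv")

  # -- productivity & setback report ---------------------------------
  report <- productivity_report(sessions, outcome)
  readr::write_csv(report$task_rates, out("task_rates.csv"))
  readr::write_csv(report$word_frequencies, out("setback_words.csv"))
  writeLines(report$text, out("report.txt"))
  files$report <- out("report.txt")
  files$task_rates <- out("task_rates.csv")
  files$setback_words <- out("setback_words.csv")

  manifest <- list(files = files, audit = outcome$audit, models = models)
  jsonlite::write_json(
    list(files = lapply(files, basename),
         audit = as.list(setNames(outcome$audit$n_entries,
                                  outcome$audit$category))),
    out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  files$manifest <- out("manifest.json")
  manifest$files <- files
  invisible(manifest)
}

#' Productivity and setback report for a cleaned data set
#'
#' Computes project-wide rates (methods A, B, C), per-task post-cleaning
#' rates, the setback summary, and the top setback word frequencies, and
#' renders them as plain text. Rates are rounded only here — 3 decimals
#' for project-wide, 2 for task rates — keeping the computational layer
#' unrounded.
#'
#' @param sessions The full (pre-cleaning) session table.
#' @param outcome The [clean_sessions()] outcome for `sessions`.
#' @param top_words How many setback tokens to list.
#' @return A list with `project_rates`, `task_rates`,
#'   `setback` (see [setback_summary()]), `word_frequencies`, and `text`
#'   (character vector of report lines).
#' @export
productivity_report <- function(sessions, outcome, top_words = 15) {
  sessions <- as_tibble(sessions)
  per_task_spec <- function(d) {
    v <- d |>
      filter(.data$task %in% PRIMARY_TASKS) |>
      summarise(s = sum(.data$specimens), .by = "task")
    setNames(v$s, v$task)[PRIMARY_TASKS]
  }
  fill0 <- function(x) {
    x[is.na(x)] <- 0
    x
  }
  pre <- productivity_totals(fill0(per_task_spec(sessions)),
                             hours_all = sum(sessions$minutes) / 60,
                             stage = "pre_cleaning")
  kept <- outcome$kept
  post <- productivity_totals(
    fill0(per_task_spec(kept)),
    hours_all = sum(kept$minutes) / 60,
    hours_primary = sum(kept$minutes[kept$task %in% PRIMARY_TASKS]) / 60,
    stage = "post_cleaning")
  project_rates <- tibble(
    method = c("A", "B", "C"),
    rate_spm = c(project_wide_rate(pre, "A"),
                 project_wide_rate(post, "B"),
                 project_wide_rate(post, "C"))
  )
  task_rates <- kept |>
    filter(.data$task %in% PRIMARY_TASKS) |>
    summarise(specimens = sum(.data$specimens),
              hours = sum(.data$minutes) / 60, .by = "task") |>
    mutate(rate_spm = task_rate(.data$specimens, .data$hours))
  setback <- setback_summary(sessions, outcome)
  wf <- word_frequencies(outcome$excluded$setback$setback_text)

  text <- c(
    "Digitization productivity report",
    "================================",
    "",
    "Project-wide rates (specimens/minute):",
    sprintf("  method %s: %.3f", project_rates$method,
            project_rates$rate_spm),
    "",
    "Post-cleaning task rates (specimens/minute):",
    sprintf("  %-20s %8d specimens over %7.0f h: %.2f",
            task_rates$task, task_rates$specimens, task_rates$hours,
            task_rates$rate_spm),
    "",
    sprintf("Setbacks: %d entries, %.0f h (%.1f%% of reported hours)",
            setback$overall$n_setback, setback$overall$setback_hours,
            100 * setback$overall$setback_hour_share),
    sprintf("  mean session %.0f min with setbacks vs %.0f min without",
            setback$overall$mean_minutes_setback,
            setback$overall$mean_minutes_clean),
    "",
    "Most frequent setback words:",
    sprintf("  %-12s %d", head(wf$token, top_words),
            head(wf$count, top_words))
  )
  list(project_rates = project_rates, task_rates = task_rates,
       setback = setback, word_frequencies = wf, text = text)
}
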