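# Phrase pools for the setback free-text field. Setback phrases echo the
# vocabulary technicians actually use (equipment, connectivity, training);
# benign phrases are casing/punctuation variants of the whitelist.
SETBACK_PHRASES <- c(
  "camera settings needed repair", "internet was down", "computer froze",
  "missing specimens in folder", "training blitz", "training new student",
  "sernec portal was slow", "skeletal entry tool slow", "barcode scanner broken",
  "label printer jammed", "collector name illegible", "missing barcodes",
  "camera battery died", "folders out of order", "imaging light box issue"
)
BENIGN_PHRASES <- c("no", "none", "No setbacks", "None.", "NO", "no setbacks!", "")

#' Configuration for the synthetic session-report generator
#'
#' Defines the statistical structure of a simulated digitization project:
#' how many technicians report, how long their sessions are, which rate
#' curves govern clean throughput, and the incidence of each anomaly the
#' cleaning stage must detect. Defaults emulate a project in which ~15% of
#' sessions hit a setback and setback sessions run ~32% longer (the
#' 133-vs-101-minute mean-duration contrast).
#'
#' @param n_technicians Number of reporting technicians.
#' @param sessions_per_technician Integer count, or length-2 range from
#'   which each technician's session count is drawn uniformly.
#' @param task_mix Named proportions over the four tasks, summing to 1.
#' @param session_minutes_mean,session_minutes_sd Session length
#'   distribution (minutes); lengths are truncated at 15 and rounded to
#'   the nearest 5, matching how technicians report time.
#' @param rate_curves Named list of [rate_model()]s for the three primary
#'   tasks (default [canonical_rate_models()]).
#' @param rate_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on individual session rates.
#' @param setback_probability Probability a session carries a significant
#'   setback (non-whitelisted free text, inflated duration).
#' @param setback_minutes_inflation Multiplier on session minutes when a
#'   setback occurs (default 1.32, the 133/101 duration ratio).
#' @param swap_error_probability Probability the minutes and specimens
#'   fields are exchanged (a data-entry error).
#' @param outlier_probability Probability a numeric field is corrupted to
#'   an extreme value.
#' @param fraudulent_reporter_count Number of technicians whose reports
#'   are internally inconsistent (their entire output is anomalous).
#' @param seed Integer seed; identical config and seed give identical
#'   output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_technicians = 30,
                             sessions_per_technician = c(8, 40),
                             task_mix = c(barcoding = 0.2, imaging = 0.35,
                                          skeletal_databasing = 0.35,
                                          other = 0.1),
                             session_minutes_mean = 101,
                             session_minutes_sd = 35,
                             rate_curves = canonical_rate_models(),
                             rate_noise_cv = 0.25,
                             setback_probability = 0.15,
                             setback_minutes_inflation = 1.32,
                             swap_error_probability = 0.01,
                             outlier_probability = 0.01,
                             fraudulent_reporter_count = 1,
                             seed = 1L) {
  if (n_technicians < 1 || n_technicians != round(n_technicians)) {
    abort("`n_technicians` must be a positive integer.")
  }
  if (!length(sessions_per_technician) %in% c(1L, 2L) ||
      any(sessions_per_technician < 1)) {
    abort("`sessions_per_technician` must be a positive count or range.")
  }
  if (!setequal(names(task_mix), TASKS)) {
    abort("`task_mix` must name exactly the four tasks.")
  }
  if (any(task_mix < 0) || abs(sum(task_mix) - 1) > 1e-9) {
    abort("`task_mix` proportions must be non-negative and sum to 1.")
  }
  probs <- c(setback_probability, swap_error_probability, outlier_probability)
  if (any(probs < 0 | probs > 1)) {
    abort("anomaly probabilities must lie in [0, 1].")
  }
  if (sum(probs) > 1) {
    abort("anomaly probabilities must sum to at most 1.")
  }
  if (session_minutes_mean <= 0 || session_minutes_sd < 0 ||
      rate_noise_cv < 0 || setback_minutes_inflation <= 0) {
    abort("session and noise parameters must be non-negative.")
  }
  if (fraudulent_reporter_count < 0 ||
      fraudulent_reporter_count >= n_technicians) {
    abort("`fraudulent_reporter_count` must be >= 0 and < `n_technicians`.")
  }
  structure(
    list(n_technicians = as.integer(n_technicians),
         sessions_per_technician = as.integer(sessions_per_technician),
         task_mix = task_mix[TASKS],
         session_minutes_mean = session_minutes_mean,
         session_minutes_sd = session_minutes_sd,
         rate_curves = rate_curves,
         rate_noise_cv = rate_noise_cv,
         setback_probability = setback_probability,
         setback_minutes_inflation = setback_minutes_inflation,
         swap_error_probability = swap_error_probability,
         outlier_probability = outlier_probability,
         fraudulent_reporter_count = as.integer(fraudulent_reporter_count),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Multiplicative lognormal noise with mean ~1 and coefficient of
# variation cv, truncated at two log-SDs. Rates are positive and
# right-skewed, but their tails are bounded so that a noisy clean session
# can never mimic an injected anomaly: anomaly classes stay separable.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  z <- qnorm(runif(n, pnorm(-2), pnorm(2)))
  exp(-sdlog^2 / 2 + sdlog * z)
}

round_to_5 <- function(x) pmax(5, round(x / 5) * 5)

#' Generate synthetic session reports with ground-truth anomaly labels
#'
#' Simulates a digitization project: each technician accumulates
#' experience per task across dated sessions, and a clean session's
#' specimen count follows `minutes x noise x f(cumulative hours)` where
#' `f` is the task's rate curve. Anomalies are injected per the config —
#' setbacks (non-whitelisted free text, inflated minutes), swapped
#' minutes/specimens fields, extreme numeric outliers, and fraudulent
#' reporters — and every entry receives exactly one ground-truth label so
#' detection stages can be scored.
#'
#' Swapped-field entries are generated noise-free (specimens exactly on
#' the rate curve) so that, once exchanged, the inverse ratio is typical
#' of the task and the entry is unambiguously recoverable.
#'
#' @param config A [generator_config()].
#' @return A list with `sessions` (tibble: `entry_id`, `reporter_id`,
#'   `session_date`, `collection_code`, `task`, `minutes`, `specimens`,
#'   `setback_text`) and `labels` (tibble: `entry_id`, `label`).
#' @examples
#' out <- generate_sessions(generator_config(n_technicians = 5, seed = 42))
#' table(out$labels$label)
#' @export
generate_sessions <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_seed(config$seed, {
    n_tech <- config$n_technicians
    spr <- config$sessions_per_technician
    n_sessions <- if (length(spr) == 1L) rep(spr, n_tech) else
      sample(seq(spr[1], spr[2]), n_tech, replace = TRUE)
    fraud_ids <- sprintf("tech%03d", seq_len(config$fraudulent_reporter_count))
    collections <- c("BEREA", "ETSU", "MTSU", "SWMT", "HTTU",
                     "UCHT", "TENN", "UTM", "UOS")

    per_tech <- lapply(seq_len(n_tech), function(i) {
      ns <- n_sessions[i]
      reporter <- sprintf("tech%03d", i)
      start <- as.Date("2016-06-01") + sample(0:900, 1)
      dates <- start + cumsum(sample(1:3, ns, replace = TRUE))
      tibble(
        reporter_id = reporter,
        session_date = dates,
        collection_code = sample(collections, 1),
        task = sample(TASKS, ns, replace = TRUE, prob = config$task_mix)
      )
    })
    sessions <- bind_rows(per_tech)
    n <- nrow(sessions)
    sessions$entry_id <- sprintf("S%05d", seq_len(n))

    # anomaly assignment: fraudulent reporters are anomalous wholesale;
    # the remaining entries draw one label each
    u <- runif(n)
    p_set <- config$setback_probability
    p_swap <- config$swap_error_probability
    p_out <- config$outlier_probability
    label <- ifelse(u < p_set, "setback",
             ifelse(u < p_set + p_swap, "swapped_fields",
             ifelse(u < p_set + p_swap + p_out, "extreme_outlier", "clean")))
    label[sessions$reporter_id %in% fraud_ids] <- "fraudulent_reporter"
    # swaps and outliers need specimen throughput to be meaningful;
    # the "other" task (curation etc.) reports none
    label[sessions$task == "other" &
            label %in% c("swapped_fields", "extreme_outlier")] <- "clean"
    # an extreme value is only detectable against its task's dispersion
    # while the share of corrupted entries in the task stays small; cap
    # injections at 2% per task so outliers cannot mask one another
    for (tk in PRIMARY_TASKS) {
      idx <- which(label == "extreme_outlier" & sessions$task == tk)
      cap <- floor(0.02 * sum(sessions$task == tk))
      if (length(idx) > cap) {
        label[sample(idx, length(idx) - cap)] <- "clean"
      }
    }
    sessions$label <- label

    # session minutes: normal truncated to [15, mean + 2.5 SD] (shifts
    # shorter than a quarter hour are not reported; marathon sessions are
    # reserved for injected outliers), reported to the nearest 5
    base_minutes <- round_to_5(pmin(
      config$session_minutes_mean + 2.5 * config$session_minutes_sd,
      pmax(15, rnorm(n, config$session_minutes_mean,
                     config$session_minutes_sd))))

    # cumulative experience per (reporter, task), evaluated at session end
    sessions$base_minutes <- base_minutes
    sessions <- sessions |>
      arrange(.data$reporter_id, .data$session_date, .data$entry_id) |>
      group_by(.data$reporter_id, .data$task) |>
      mutate(cum_hours = cumsum(.data$base_minutes) / 60) |>
      ungroup()

    noise <- rlnorm_cv(n, config$rate_noise_cv)
    noise[sessions$label == "swapped_fields"] <- 1  # keep swaps recoverable
    curve_rate <- vapply(seq_len(n), function(j) {
      task <- sessions$task[j]
      if (task == "other") return(0)
      predict(config$rate_curves[[task]], hours = sessions$cum_hours[j])
    }, numeric(1))
    rate <- curve_rate * noise
    # fraudulent reporters: internally inconsistent rates, far off-curve
    is_fraud <- sessions$label == "fraudulent_reporter"
    rate[is_fraud] <- curve_rate[is_fraud] *
      runif(sum(is_fraud), 0.1, 6)

    minutes <- sessions$base_minutes
    setback_text <- sample(BENIGN_PHRASES, n, replace = TRUE)

    # setbacks lengthen the session and leave a tell-tale description;
    # specimens follow the (longer) reported time, so the anomaly lives in
    # the duration and the text, keeping it disjoint from the rate-based
    # swap signature
    is_set <- sessions$label == "setback"
    minutes[is_set] <- round_to_5(minutes[is_set] *
                                    config$setback_minutes_inflation)
    setback_text[is_set] <- sample(SETBACK_PHRASES, sum(is_set),
                                   replace = TRUE)

    specimens <- round(minutes * rate)

    is_swap <- sessions$label == "swapped_fields"
    tmp <- minutes[is_swap]
    minutes[is_swap] <- pmax(1, specimens[is_swap])
    specimens[is_swap] <- tmp

    # outliers: the specimens field is corrupted to an extreme count
    # (extra digits typed), far beyond five SDs of any clean session yet
    # narrow in range so outliers cannot mask one another; the resulting
    # absurdly high rate is disjoint from the low-rate swap signature
    is_out <- sessions$label == "extreme_outlier"
    specimens[is_out] <- round(runif(sum(is_out), 40000, 60000))

    sessions$minutes <- as.numeric(minutes)
    sessions$specimens <- as.integer(pmax(
      0, ifelse(sessions$task == "other", 0, specimens)))
    sessions$setback_text <- setback_text

    out <- sessions |>
      arrange(.data$entry_id) |>
      select("entry_id", "reporter_id", "session_date", "collection_code",
             "task", "minutes", "specimens", "setback_text")
    labels <- sessions |>
      arrange(.data$entry_id) |>
      select("entry_id", "label")
    list(sessions = out, labels = labels)
  })
}

#' Read and write session-report tables
#'
#' Round-trip-lossless CSV I/O for the session schema (columns
#' `entry_id`, `reporter_id`, `session_date` in ISO 8601,
#' `collection_code`, `task`, `minutes`, `specimens`, `setback_text`).
#'
#' @param sessions A session-report tibble.
#' @param path File path.
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()`
#'   returns the tibble.
#' @export
write_sessions <- function(sessions, path) {
  readr::write_csv(sessions, path, na = "")
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      entry_id = readr::col_character(),
      reporter_id = readr::col_character(),
      session_date = readr::col_date(),
      collection_code = readr::col_character(),
      task = readr::col_character(),
      minutes = readr::col_double(),
      specimens = readr::col_integer(),
      setback_text = readr::col_character()
    )
  ) |>
    mutate(setback_text = tidyr::replace_na(.data$setback_text, ""))
}
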