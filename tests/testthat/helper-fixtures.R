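# Shared fixtures and small helpers for the suite.

# A minimal valid session table built by hand.
make_sessions <- function(minutes, specimens,
                          task = "imaging",
                          reporter_id = "tech001",
                          setback_text = "",
                          start_date = as.Date("2017-01-01")) {
  n <- length(minutes)
  tibble::tibble(
    entry_id = sprintf("E%03d", seq_len(n)),
    reporter_id = rep_len(reporter_id, n),
    session_date = start_date + seq_len(n),
    collection_code = "TENN",
    task = rep_len(task, n),
    minutes = as.numeric(minutes),
    specimens = as.integer(specimens),
    setback_text = rep_len(setback_text, n)
  )
}

# Cleaning config whose excluded reporters are taken from the generator's
# ground-truth fraudulent-reporter labels (these are identified by project
# oversight, not from the data, so tests hand them to the config).
config_from_labels <- function(gen) {
  fraud_entries <- gen$labels$entry_id[gen$labels$label == "fraudulent_reporter"]
  cleaning_config(
    excluded_reporters =
      unique(gen$sessions$reporter_id[gen$sessions$entry_id %in% fraud_entries])
  )
}

# Map a cleaning outcome back onto per-entry predicted labels.
predicted_labels <- function(gen, outcome) {
  pred <- stats::setNames(rep("clean", nrow(gen$labels)), gen$labels$entry_id)
  pred[outcome$excluded$setback$entry_id] <- "setback"
  pred[outcome$excluded$entry_error$entry_id] <- "swapped_fields"
  pred[outcome$excluded$extreme_outlier$entry_id] <- "extreme_outlier"
  pred[outcome$excluded$nonrepresentative_reporter$entry_id] <-
    "fraudulent_reporter"
  pred[outcome$excluded$nonrepresentative_workflow$entry_id] <-
    "nonrepresentative_workflow"
  unname(pred[gen$labels$entry_id])
}

# Closed-form specimens produced over one contract, built from the model's
# algebra rather than from effective_hourly_rate(): polynomial power sums
# with analytically located clamp boundaries. Serves as the independent
# oracle for the hourly accumulation loop.
closed_form_production <- function(model, duration) {
  co <- c(model$coefficients, 0, 0)[1:3]
  freeze <- model$experience_limit + 1
  curve <- function(x) co[1] + co[2] * x + co[3] * x^2
  clamp <- function(y) {
    if (model$limit_direction == "max") pmin(y, model$rate_limit)
    else pmax(y, model$rate_limit)
  }
  # hours whose experience argument moves along the curve
  moving <- min(duration, freeze)
  ks <- seq_len(moving)
  s1 <- moving * (moving + 1) / 2
  s2 <- moving * (moving + 1) * (2 * moving + 1) / 6
  # identify where the raw curve crosses the limit to split the sum
  raw <- curve(ks)
  clamped_mask <- if (model$limit_direction == "max") raw > model$rate_limit
                  else raw < model$rate_limit
  if (!any(clamped_mask)) {
    total_moving <- co[1] * moving + co[2] * s1 + co[3] * s2
  } else {
    free <- ks[!clamped_mask]
    total_moving <- co[1] * length(free) + co[2] * sum(free) +
      co[3] * sum(free^2) + sum(clamped_mask) * model$rate_limit
  }
  frozen_hours <- max(0, duration - freeze)
  60 * (total_moving + frozen_hours * clamp(curve(freeze)))
}
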