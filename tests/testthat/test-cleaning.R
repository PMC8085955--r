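test_that("free text normalizes to lowercase, punctuation-free, squished", {
  expect_equal(normalize_free_text("No Setbacks!"), "no setbacks")
  expect_equal(normalize_free_text("  NONE. "), "none")
  expect_equal(normalize_free_text("Camera—repair needed"),
               "camera repair needed")
  expect_equal(normalize_free_text(c("", NA, "a  b")), c("", "", "a b"))
})

test_that("setback classification is a whitelist complement on non-empty text", {
  expect_false(classify_setback("none"))
  expect_false(classify_setback("No setbacks!"))
  expect_true(classify_setback("training blitz at TENN"))
  expect_false(classify_setback(""))
  expect_false(classify_setback(NA_character_))
  expect_equal(classify_setback(c("no", "camera broke", "")),
               c(FALSE, TRUE, FALSE))
})

test_that("swap detection requires a low rate whose inverse is typical", {
  stats <- tibble::tibble(task = "imaging", mean_rate = 2.30,
                          sd_rate = 0.5, low_rate = 1.0)
  typical <- make_sessions(120, 276)          # 2.30 SPM, nothing unusual
  swapped <- make_sessions(276, 120)          # fields exchanged: 0.43 SPM
  slow <- make_sessions(600, 60)              # 0.10 SPM, inverse 10 atypical
  none <- make_sessions(100, 0)               # zero specimens: unclassifiable
  expect_false(detect_swapped_entry(typical, stats))
  expect_true(detect_swapped_entry(swapped, stats))
  # brute-force confirmation: swapping the fields back restores a rate
  # within the typical band
  expect_true(abs(swapped$minutes / swapped$specimens - 2.30) <= 2 * 0.5)
  expect_false(detect_swapped_entry(slow, stats))
  expect_false(detect_swapped_entry(none, stats))
})

test_that("task rate statistics describe the above-quantile population", {
  entries <- make_sessions(rep(100, 20), c(rep(230, 19), 10))
  stats <- task_rate_stats(entries, low_rate_quantile = 0.05)
  expect_equal(stats$mean_rate, 2.3)  # the 0.1 SPM suspect is set aside
  expect_equal(stats$sd_rate, 0)
})

test_that("field outliers are flagged per task with a strict threshold", {
  entries <- make_sessions(c(rep(60, 100), 6000), c(rep(120, 100), 120))
  expect_equal(flag_field_outliers(entries, 5), "E101")

  identical_entries <- make_sessions(rep(60, 10), rep(120, 10))
  expect_length(flag_field_outliers(identical_entries, 5), 0)

  # a value at exactly threshold SDs is not "exceeding"
  x <- c(rep(0, 9), 1)
  z <- (1 - mean(x)) / sd(x)
  at_boundary <- make_sessions(rep(100, 10), x * 100 + 100)
  expect_length(flag_field_outliers(at_boundary, z), 0)
  expect_equal(flag_field_outliers(at_boundary, z * 0.999), "E010")
})

test_that("cleaning conserves entries across partitions", {
  for (seed in c(2, 9, 31)) {
    gen <- generate_sessions(generator_config(seed = seed))
    oc <- clean_sessions(gen$sessions, config_from_labels(gen))
    n_excluded <- sum(vapply(oc$excluded, nrow, integer(1)))
    expect_equal(nrow(oc$kept) + n_excluded, nrow(gen$sessions))
    all_ids <- c(oc$kept$entry_id,
                 unlist(lapply(oc$excluded, function(x) x$entry_id)))
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_setequal(all_ids, gen$sessions$entry_id)
    expect_equal(sum(oc$audit$n_entries), nrow(gen$sessions))
    expect_equal(sum(oc$audit$hours), sum(gen$sessions$minutes) / 60)
  }
})

test_that("cleaning recovers injected anomaly labels exactly", {
  for (seed in c(1, 7, 18)) {
    gen <- generate_sessions(generator_config(seed = seed))
    oc <- clean_sessions(gen$sessions, config_from_labels(gen))
    expect_identical(predicted_labels(gen, oc), gen$labels$label,
                     label = sprintf("seed %d", seed))
  }
})

test_that("anomaly-free input is kept in full", {
  gen <- generate_sessions(generator_config(
    n_technicians = 8, sessions_per_technician = 15,
    setback_probability = 0, swap_error_probability = 0,
    outlier_probability = 0, fraudulent_reporter_count = 0, seed = 4))
  oc <- clean_sessions(gen$sessions)
  expect_equal(nrow(oc$kept), nrow(gen$sessions))
  expect_true(all(vapply(oc$excluded, nrow, integer(1)) == 0))
})

test_that("stage order puts setbacks ahead of outlier flagging", {
  base <- make_sessions(rep(100, 50), rep(230, 50))
  weird <- make_sessions(5000, 230, setback_text = "camera broke")
  weird$entry_id <- "E999"
  oc <- clean_sessions(dplyr::bind_rows(base, weird))
  expect_true("E999" %in% oc$excluded$setback$entry_id)
  expect_false("E999" %in% oc$excluded$extreme_outlier$entry_id)
})

test_that("config-listed reporters and workflow entries are set aside first", {
  sessions <- make_sessions(rep(100, 6), rep(230, 6),
                            reporter_id = c("a", "a", "b", "b", "c", "c"))
  oc <- clean_sessions(sessions, cleaning_config(
    excluded_reporters = "a", excluded_workflow_entries = "E003"))
  expect_equal(oc$excluded$nonrepresentative_reporter$entry_id,
               c("E001", "E002"))
  expect_equal(oc$excluded$nonrepresentative_workflow$entry_id, "E003")
  expect_equal(nrow(oc$kept), 3)
})

test_that("re-cleaning the kept partition excludes nothing in stages 1-4", {
  gen <- generate_sessions(generator_config(seed = 12))
  cfg <- config_from_labels(gen)
  oc <- clean_sessions(gen$sessions, cfg)
  again <- clean_sessions(oc$kept, cfg)
  expect_equal(nrow(again$excluded$nonrepresentative_reporter), 0)
  expect_equal(nrow(again$excluded$nonrepresentative_workflow), 0)
  expect_equal(nrow(again$excluded$entry_error), 0)
  expect_equal(nrow(again$excluded$setback), 0)
})

test_that("empty input gives an empty outcome with a zeroed audit", {
  empty <- make_sessions(numeric(0), integer(0))
  oc <- clean_sessions(empty)
  expect_equal(nrow(oc$kept), 0)
  expect_true(all(oc$audit$n_entries == 0))
  expect_true(all(oc$audit$hours == 0))
})
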