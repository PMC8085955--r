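test_that("cumulative hours accrue per technician and task, dated stably", {
  s <- make_sessions(c(120, 90), c(240, 210))
  r <- cumulative_task_hours(s)
  expect_equal(r$cumulative_task_hours, c(2.0, 3.5))
  expect_equal(r$rate, c(2.0, 210 / 90))

  one <- cumulative_task_hours(make_sessions(60, 138))
  expect_equal(one$cumulative_task_hours, 1.0)
  expect_equal(one$rate, 2.3)

  # interleaved technicians accumulate independently
  two <- dplyr::bind_rows(
    make_sessions(c(60, 60), c(100, 110), reporter_id = "t1"),
    make_sessions(c(30, 30), c(50, 55), reporter_id = "t2"))
  two$entry_id <- sprintf("E%03d", 1:4)
  two$session_date <- as.Date("2017-01-01") + c(1, 3, 2, 4)
  r2 <- cumulative_task_hours(two)
  expect_equal(r2$cumulative_task_hours[r2$reporter_id == "t1"], c(1, 2))
  expect_equal(r2$cumulative_task_hours[r2$reporter_id == "t2"], c(0.5, 1))

  # tasks accrue separately within one reporter
  mixed <- make_sessions(c(60, 60), c(100, 100))
  mixed$task <- c("imaging", "barcoding")
  r3 <- cumulative_task_hours(mixed)
  expect_true(all(r3$cumulative_task_hours == 1))

  # date ties keep input order
  tied <- make_sessions(c(60, 120), c(100, 200))
  tied$session_date <- rep(as.Date("2017-01-01"), 2)
  expect_equal(cumulative_task_hours(tied)$cumulative_task_hours, c(1, 3))
})

test_that("experience bins are half-open two-hour intervals below 64 h", {
  recs <- cumulative_task_hours(make_sessions(
    c(210, 30, 1620, 1980, 60), c(420, 90, 3240, 3960, 120)))
  # cumulative hours: 3.5, 4.0, 31.0, 64.0, 65.0
  bins <- bin_by_experience(recs)
  expect_equal(bins$bin_start, c(2, 4, 30))
  expect_equal(bins$bin_end, bins$bin_start + 2)
  expect_equal(sum(bins$n_entries), 3)  # records at/past 64 h excluded

  two_rates <- cumulative_task_hours(make_sessions(c(60, 30), c(120, 90)))
  b <- bin_by_experience(two_rates)
  expect_equal(b$n_entries, 2)
  expect_equal(b$mean_rate, 2.5)
  expect_equal(b$min_rate, 2.0)
  expect_equal(b$max_rate, 3.0)
})

test_that("every kept record below the threshold lands in exactly one bin", {
  gen <- generate_sessions(generator_config(seed = 14))
  recs <- cumulative_task_hours(gen$sessions)
  bins <- bin_by_experience(recs)
  expect_equal(sum(bins$n_entries), sum(recs$cumulative_task_hours < 64))
  expect_true(all(bins$bin_end <= 64))
  expect_true(all(bins$min_rate <= bins$mean_rate &
                    bins$mean_rate <= bins$max_rate))
})

test_that("noise-free bins return generating coefficients at machine precision", {
  mk_bins <- function(task, f, starts) {
    tibble::tibble(task = task, bin_start = starts, bin_end = starts + 2,
                   n_entries = 5, mean_rate = f(starts + 1),
                   min_rate = f(starts + 1), max_rate = f(starts + 1))
  }
  lin <- mk_bins("imaging", function(x) 1.0 + 0.5 * x, seq(0, 20, 2))
  fit <- fit_rate_model(lin, "linear")
  expect_equal(fit$coefficients, c(1.0, 0.5), tolerance = 1e-9)
  expect_equal(fit$rate_limit, 4.00)
  expect_equal(fit$limit_direction, "max")

  quad <- mk_bins("barcoding", function(x) 3.7 + 0.1 * x - 0.002 * x^2,
                  seq(0, 30, 2))
  fitq <- fit_rate_model(quad, "quadratic")
  expect_equal(fitq$coefficients, c(3.7, 0.1, -0.002), tolerance = 1e-9)
  expect_equal(fitq$rate_limit, 3.00)
  expect_equal(fitq$limit_direction, "min")
})

test_that("too few bins is a fitting error", {
  b <- tibble::tibble(task = "imaging", bin_start = c(0, 2),
                      bin_end = c(2, 4), n_entries = 1,
                      mean_rate = c(2, 2.1), min_rate = 2, max_rate = 2.2)
  expect_error(fit_rate_model(b, "linear"), "at least 3")
  expect_error(fit_rate_model(b, "quadratic"), "at least 4")
})

test_that("fitting recovers the generating imaging curve from noisy sessions", {
  cfg <- generator_config(
    n_technicians = 50, sessions_per_technician = 40,
    task_mix = c(barcoding = 0, imaging = 1, skeletal_databasing = 0,
                 other = 0),
    rate_noise_cv = 0.1,
    setback_probability = 0, swap_error_probability = 0,
    outlier_probability = 0, fraudulent_reporter_count = 0,
    seed = 2024)
  gen <- generate_sessions(cfg)
  bins <- bin_by_experience(cumulative_task_hours(gen$sessions))
  fit <- fit_rate_model(bins, "linear")
  expect_equal(fit$coefficients[1], 1.95170, tolerance = 0.05)
  expect_equal(fit$coefficients[2], 0.02118, tolerance = 0.05)
  expect_gt(fit$coefficients[2], 0)
})

test_that("synthetic sessions on the canonical curves yield their shapes back", {
  # enough sessions per technician that barcoding experience spans the
  # curve's inflection near 28 h, where the curvature is identifiable
  gen <- generate_sessions(generator_config(
    n_technicians = 60, sessions_per_technician = 60,
    task_mix = c(barcoding = 1 / 3, imaging = 1 / 3,
                 skeletal_databasing = 1 / 3, other = 0),
    seed = 5))
  oc <- clean_sessions(gen$sessions, config_from_labels(gen))
  bins <- bin_by_experience(cumulative_task_hours(oc$kept))
  for (tk in c("imaging", "skeletal_databasing")) {
    fit <- fit_rate_model(dplyr::filter(bins, task == tk), "linear")
    expect_gt(fit$coefficients[2], 0)
  }
  fitb <- fit_rate_model(dplyr::filter(bins, task == "barcoding"),
                         "quadratic")
  expect_lt(fitb$coefficients[3], 0)
})
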