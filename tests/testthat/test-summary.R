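make_log <- function(trial, days, values, measure = "m1", start = "2022-01-01") {
  log <- new_observation_log()
  minute <- 0
  last_day <- -1
  for (i in seq_along(days)) {
    minute <- if (days[i] == last_day) minute + 1 else 0
    last_day <- days[i]
    at <- sprintf("%sT08:%02d:00", format(as.Date(start) + days[i] - 1), minute)
    log <- record(log, trial, measure, values[i], at = at, start_date = start)
  }
  log
}

test_that("aggregation by day and by phase matches hand arithmetic", {
  trial <- make_trial()
  log <- make_log(trial, days = c(1, 1, 2), values = c(2, 4, 6))

  by_day <- aggregate_observations(log, trial, "m1", "day")
  expect_identical(by_day$index, c(1L, 2L))
  expect_identical(by_day$n, c(2L, 1L))
  expect_identical(by_day$mean, c(3, 6))

  by_phase <- aggregate_observations(log, trial, "m1", "phase")
  expect_identical(by_phase$index, 1L)
  expect_identical(by_phase$phase_label, "A")
  expect_identical(by_phase$mean, 4)  # (2+4+6)/3, pooled over observations

  empty <- aggregate_observations(new_observation_log(), trial, "m1", "day")
  expect_identical(nrow(empty), 0L)

  list_trial <- make_trial(measures = list(measure_list("yn", c("yes", "no"), id = "m1")))
  expect_error(aggregate_observations(new_observation_log(), list_trial, "m1"),
               class = "nof1_error_unsupported_grain")
})

test_that("phase means pool raw observations, not daily means (oracle)", {
  withr::with_seed(61, {
    for (k in 1:15) {
      trial <- make_trial(schedule = random_schedule(max_d = 5, max_p = 3))
      dur <- total_duration(trial$schedule)
      n <- sample(5:20, 1)
      days <- sort(sample(seq_len(dur), n, replace = TRUE))
      values <- round(rnorm(n, 5, 2), 3)
      log <- make_log(trial, days, values)

      by_phase <- aggregate_observations(log, trial, "m1", "phase")
      vals <- as.numeric(log$value)
      ords <- (log$day_index - 1) %/% trial$schedule$phase_duration_days + 1
      for (i in seq_len(nrow(by_phase))) {
        pooled <- vals[ords == by_phase$index[i]]
        expect_equal(by_phase$mean[i], mean(pooled))
        expect_identical(by_phase$n[i], length(pooled))
      }
      # by-day means equal raw means per day
      by_day <- aggregate_observations(log, trial, "m1", "day")
      for (i in seq_len(nrow(by_day))) {
        expect_equal(by_day$mean[i], mean(vals[log$day_index == by_day$index[i]]))
      }
    }
  })
})

test_that("list frequencies tally items and conserve counts", {
  trial <- make_trial(measures = list(measure_list("yn", c("yes", "no"), id = "m1")))
  log <- make_log(trial, days = c(1, 2, 3, 8), values = c("yes", "yes", "no", "yes"))

  by_phase <- list_frequencies(log, trial, "m1", "phase")
  a <- by_phase[by_phase$index == 1, ]
  expect_identical(sum(a$n), 3L)
  expect_identical(a$n[a$item == "yes"], 2L)
  expect_identical(a$n[a$item == "no"], 1L)
  b <- by_phase[by_phase$index == 2, ]
  expect_identical(sum(b$n), 1L)
  # phases without data are omitted
  expect_setequal(unique(by_phase$index), c(1L, 2L))

  # brute-force tally oracle at day grain
  by_day <- list_frequencies(log, trial, "m1", "day")
  tab <- table(log$day_index, log$value)
  for (i in seq_len(nrow(by_day))) {
    expect_identical(by_day$n[i],
                     as.integer(tab[as.character(by_day$index[i]), by_day$item[i]]))
  }

  expect_error(list_frequencies(log, make_trial(), "m1", "day"),
               class = "nof1_error_unsupported_grain")
})

test_that("phase contrast means, difference and Welch test are exact", {
  trial <- make_trial()
  log <- make_log(trial, days = c(1, 2, 8, 9), values = c(5, 5, 3, 3))
  pc <- phase_contrast(log, trial, "m1")
  expect_identical(pc$difference, 2)
  expect_identical(pc$mean_A, 5)
  expect_identical(pc$mean_B, 3)
  expect_identical(c(pc$n_A, pc$n_B), c(2L, 2L))

  # identical samples in both phases: difference 0, t = 0
  log0 <- make_log(trial, days = c(1, 2, 8, 9), values = c(4, 6, 4, 6))
  pc0 <- phase_contrast(log0, trial, "m1", with_test = TRUE)
  expect_identical(pc0$difference, 0)
  expect_identical(pc0$statistic, 0)

  # Welch statistic equals the textbook formula on random samples
  withr::with_seed(62, {
    for (k in 1:20) {
      na <- sample(3:10, 1); nb <- sample(3:10, 1)
      a <- round(rnorm(na, 6, 2), 4)
      b <- round(rnorm(nb, 4, 1), 4)
      days <- c(sample(1:7, na, TRUE), sample(8:14, nb, TRUE))
      log <- make_log(trial, days[order(days)], c(a, b)[order(days)])
      pc <- phase_contrast(log, trial, "m1", with_test = TRUE)
      oracle <- welch_oracle(as.numeric(log$value[log$phase_label == "A"]),
                             as.numeric(log$value[log$phase_label == "B"]))
      expect_equal(pc$statistic, oracle$t, tolerance = 1e-10)
      expect_equal(pc$df, oracle$df, tolerance = 1e-10)
      expect_equal(pc$p_value, oracle$p, tolerance = 1e-10)
    }
  })

  # insufficient data per phase type
  log_a <- make_log(trial, days = 1, values = 5)
  expect_error(phase_contrast(log_a, trial, "m1"),
               class = "nof1_error_insufficient_data")
  log_1 <- make_log(trial, days = c(1, 8), values = c(5, 3))
  expect_error(phase_contrast(log_1, trial, "m1", with_test = TRUE),
               class = "nof1_error_insufficient_data")
  expect_identical(phase_contrast(log_1, trial, "m1")$difference, 2)
})

test_that("history report covers measures, stays consistent, renders as JSON", {
  trial <- make_trial(measures = list(
    measure_keyboard("sleep", unit = "hours", id = "m1"),
    measure_list("felt well", items = c("yes", "no"), id = "m2")
  ))

  empty <- history_report(trial, new_observation_log())
  expect_length(empty$measures, 2L)
  expect_true(all(vapply(empty$measures, function(s) isTRUE(s$no_data), logical(1))))

  log <- make_log(trial, days = c(1, 8), values = c(7, 5))
  rep1 <- history_report(trial, log, with_test = FALSE)
  sec <- rep1$measures[[1]]
  expect_identical(sec$by_phase$mean,
                   aggregate_observations(log, trial, "m1", "phase")$mean)
  expect_identical(sec$contrast$difference, 2)
  expect_true(isTRUE(rep1$measures[[2]]$no_data))

  parsed <- jsonlite::fromJSON(history_to_json(rep1))
  expect_identical(parsed$trial_id, "trial-1")
  expect_identical(parsed$measures$measure_id, c("m1", "m2"))

  td <- tidy(rep1)
  expect_identical(nrow(td), 2L)
  expect_identical(td$estimate[1], 2)
  expect_true(is.na(td$estimate[2]))
  expect_identical(glance(rep1)$n_with_data, 1L)
})
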