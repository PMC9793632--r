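test_that("record validates each input type with distinct error classes", {
  trial <- make_trial(measures = list(
    measure_keyboard("sleep", unit = "hours", id = "m1"),
    measure_list("felt well", items = c("yes", "no"), id = "m2"),
    measure_scale("pain", min = 0, max = 10, id = "m3")
  ))
  log <- new_observation_log()
  start <- "2022-01-01"

  # keyboard text parses to a number, stamped with day and phase
  log <- record(log, trial, "m1", "7.5", at = "2022-01-10T08:00:00", start_date = start)
  expect_identical(log$day_index[1], 10L)
  expect_identical(log$phase_label[1], "B")   # day 10 of ABAB, d = 7
  expect_identical(as.numeric(log$value[1]), 7.5)

  expect_error(
    record(log, trial, "m3", 11, at = "2022-01-10T09:00:00", start_date = start),
    class = "nof1_error_out_of_range"
  )
  expect_error(
    record(log, trial, "m2", "maybe", at = "2022-01-10T09:00:00", start_date = start),
    class = "nof1_error_invalid_item"
  )
  expect_error(
    record(log, trial, "m1", "seven", at = "2022-01-10T09:00:00", start_date = start),
    class = "nof1_error_not_a_number"
  )
  expect_error(
    record(log, trial, "m1", 7, at = "2022-02-10T09:00:00", start_date = start),
    class = "nof1_error_outside_trial"
  )
  expect_error(
    record(log, trial, "nope", 7, at = "2022-01-10T09:00:00", start_date = start),
    class = "nof1_error_unknown_measure"
  )

  # boundary values are accepted; multiple same-day entries are retained
  log <- record(log, trial, "m3", 10, at = "2022-01-10T10:00:00", start_date = start)
  log <- record(log, trial, "m3", 0, at = "2022-01-10T11:00:00", start_date = start)
  log <- record(log, trial, "m2", "yes", at = "2022-01-10T12:00:00", start_date = start)
  expect_identical(nrow(log), 4L)

  # append-only chronological order is enforced
  expect_error(
    record(log, trial, "m1", 7, at = "2022-01-09T08:00:00", start_date = start),
    class = "nof1_error_out_of_order"
  )
})

test_that("phase stamping agrees with the phase calendar across random specs", {
  withr::with_seed(51, {
    for (k in 1:15) {
      spec <- random_trial_spec(max_d = 6, max_p = 3)
      numeric_measures <- Filter(function(m) m$input_type != "list", spec$measures)
      if (length(numeric_measures) == 0) next
      m <- numeric_measures[[1]]
      safe_value <- if (m$input_type == "scale") {
        (m$scale_config$min + m$scale_config$max) / 2
      } else {
        1
      }
      start <- as.Date("2022-01-01")
      cal <- phase_calendar(spec$schedule)
      log <- new_observation_log()
      days <- sort(sample(seq_len(total_duration(spec$schedule)),
                          min(5, total_duration(spec$schedule))))
      for (d in days) {
        at <- paste0(format(start + d - 1), "T09:00:00")
        log <- record(log, spec, m$id, safe_value, at = at, start_date = start)
      }
      by_cal <- vapply(log$day_index, function(d) {
        cal$label[cal$start_day <= d & d <= cal$end_day]
      }, character(1))
      expect_identical(log$phase_label, by_cal)
    }
  })
})

test_that("CSV export/import is a lossless round-trip", {
  trial <- make_trial(measures = list(
    measure_keyboard("sleep", unit = "hours", id = "m1"),
    measure_list("note, with comma", items = c("a \"quoted\"", "plain"), id = "m2")
  ))
  start <- "2022-01-01"
  log <- new_observation_log() |>
    record(trial, "m1", 7.25, at = "2022-01-02T08:00:00", start_date = start) |>
    record(trial, "m2", "a \"quoted\"", at = "2022-01-02T20:00:00", start_date = start) |>
    record(trial, "m1", 6, at = "2022-01-03T08:00:00", start_date = start)

  expect_identical(import_csv(export_csv(log), trial), log)

  # empty log gives a header-only CSV that round-trips to an empty log
  empty_csv <- export_csv(new_observation_log())
  expect_identical(trimws(empty_csv),
                   "measure_id,timestamp,day_index,phase_label,value")
  expect_identical(import_csv(empty_csv, trial), new_observation_log())

  # file round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  export_csv(log, path)
  expect_identical(import_csv(path, trial), log)
})

test_that("import_csv rejects invalid rows with their line numbers", {
  trial <- make_trial(measures = list(measure_scale("pain", 0, 10, id = "m1")))
  good <- "measure_id,timestamp,day_index,phase_label,value"
  rows <- c(
    good,
    "m1,2022-01-02T08:00:00,2,A,5",        # fine (line 2)
    "m1,2022-01-10T08:00:00,10,B,11",      # out of range (line 3)
    "m1,2022-01-12T08:00:00,12,A,3"        # phase should be B (line 4)
  )
  err <- tryCatch(import_csv(rows, trial), condition = function(e) e)
  expect_s3_class(err, "nof1_error_csv_row")
  expect_match(conditionMessage(err), "line 3")
  expect_match(conditionMessage(err), "line 4")
  expect_no_match(conditionMessage(err), "line 2:")

  # every stored observation re-validates against its measure
  run <- simulate_participant(
    make_trial(measures = list(measure_scale("pain", 0, 10, id = "m1"))),
    simulation_config(seed = 3, noise_sd = 4)
  )
  expect_no_error(import_csv(export_csv(run$observations), make_trial(
    measures = list(measure_scale("pain", 0, 10, id = "m1"))
  )))
})
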