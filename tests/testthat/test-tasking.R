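test_that("recurrence_days enumerates daily and every-x-days policies", {
  expect_identical(recurrence_days(reminder_policy(), 28), 1:28)
  expect_identical(
    recurrence_days(reminder_policy(recurrence = "every_x_days", interval_days = 2), 7),
    c(1L, 3L, 5L, 7L)
  )
  expect_identical(
    recurrence_days(reminder_policy(recurrence = "every_x_days", interval_days = 3), 10),
    c(1L, 4L, 7L, 10L)
  )
})

test_that("tasks_for_day expands reminders and respects the active phase", {
  # withdrawal B-phase day: measure with 2 daily times -> 2 measurement tasks
  wd <- make_trial(measures = list(
    measure_keyboard("sleep", unit = "hours",
                     reminder = reminder_policy(times = c("08:00", "20:00")), id = "m1")
  ))
  tb <- tasks_for_day(wd, 10)  # day 10 is a B day under ABAB, d = 7
  expect_identical(nrow(tb), 2L)
  expect_true(all(tb$kind == "measurement"))
  expect_true(all(tb$phase_label == "B"))

  # alternating design: intervention active every day
  at <- make_trial("alternating_treatment")
  ta <- tasks_for_day(at, 10)
  expect_identical(sort(ta$kind), c("intervention", "measurement"))
  expect_identical(ta$component_id[ta$kind == "intervention"], "iv2")

  # A-phase day not covered by an every_x_days intervention reminder
  wd2 <- make_trial()
  wd2$interventions[[1]]$reminder <-
    reminder_policy(recurrence = "every_x_days", interval_days = 2)
  t2 <- tasks_for_day(wd2, 2)  # A day, but recurrence covers odd days only
  expect_true(all(t2$kind == "measurement"))

  expect_error(tasks_for_day(wd, 29), class = "nof1_error_day_out_of_range")

  # tasks come sorted by time of day
  multi <- make_trial(measures = list(
    measure_keyboard("a", reminder = reminder_policy(times = "21:00"), id = "m1"),
    measure_keyboard("b", reminder = reminder_policy(times = "06:00"), id = "m2")
  ))
  tm <- tasks_for_day(multi, 10)
  expect_identical(tm$component_id, c("m2", "m1"))
})

test_that("notification_schedule matches the derived task counts", {
  # default schedule, daily 1-time measure + daily 1-time intervention:
  # 28 measurement tasks + 14 intervention tasks (A days only)
  wd <- make_trial()
  log <- notification_schedule(wd)
  expect_identical(sum(log$kind == "measurement"), 28L)
  expect_identical(sum(log$kind == "intervention"), 14L)
  expect_true(all(log$phase_label[log$kind == "intervention"] == "A"))

  at <- make_trial("alternating_treatment")
  log2 <- notification_schedule(at)
  expect_identical(sum(log2$kind == "measurement"), 28L)
  expect_identical(sum(log2$kind == "intervention"), 28L)

  # calendar dates attach to day indices
  dated <- notification_schedule(wd, start_date = "2022-03-01")
  expect_identical(dated$date, as.Date("2022-03-01") + dated$day_index - 1L)
})

test_that("task counts equal a brute-force component-by-component oracle", {
  withr::with_seed(41, {
    for (k in 1:30) {
      spec <- random_trial_spec()
      dur <- total_duration(spec$schedule)
      labels <- phase_of_day(spec$schedule, seq_len(dur))

      # oracle: sum over components of |covered days ∩ active days| * |times|
      expected <- 0L
      for (m in spec$measures) {
        expected <- expected +
          length(recurrence_days(m$reminder, dur)) * length(m$reminder$times)
      }
      for (j in seq_along(spec$interventions)) {
        iv <- spec$interventions[[j]]
        active <- if (spec$design == "withdrawal") {
          which(labels == "A")
        } else {
          which(labels == if (j == 1) "A" else "B")
        }
        covered <- intersect(recurrence_days(iv$reminder, dur), active)
        expected <- expected + length(covered) * length(iv$reminder$times)
      }

      log <- notification_schedule(spec)
      expect_identical(nrow(log), expected)

      # no intervention task on a withdrawal no-intervention day
      if (spec$design == "withdrawal") {
        expect_true(all(log$phase_label[log$kind == "intervention"] == "A"))
      }

      # deterministic given spec and start date
      expect_identical(log, notification_schedule(spec))
    }
  })
})

test_that("status transitions and adherence follow the task lifecycle", {
  wd <- make_trial(schedule = schedule(1, 1, "alternating"))  # 2 days
  log <- notification_schedule(wd)  # day1: iv+m, day2: m -> 3 tasks
  expect_identical(nrow(log), 3L)

  log <- mark_completed(log, 1, "m1", at = "2022-01-01T08:05:00")
  expect_identical(log$status[log$component_id == "m1" & log$day_index == 1], "completed")
  expect_error(mark_completed(log, 1, "m1"), class = "nof1_error_task_state")
  expect_error(mark_completed(log, 1, "nope"), class = "nof1_error_unknown_task")

  log <- mark_completed(log, 1, "iv1")
  log <- mark_completed(log, 2, "m1")
  expect_identical(adherence_rate(log), 1.0)

  log2 <- finalize_tasks(notification_schedule(wd))
  expect_true(all(log2$status == "missed"))
  expect_identical(adherence_rate(log2), 0.0)

  # 3 of 4 completed once the trial is over
  wd4 <- make_trial(schedule = schedule(2, 1, "alternating"))  # 4 days
  wd4$interventions[[1]]$reminder <- reminder_policy(recurrence = "every_x_days",
                                                     interval_days = 4)
  log4 <- notification_schedule(wd4)  # 4 measurement + 1 intervention (day 1)
  log4 <- log4[log4$kind == "measurement", ]
  for (d in 1:3) log4 <- mark_completed(log4, d, "m1")
  expect_identical(adherence_rate(log4), 0.75)

  # tasks not yet due are excluded from the denominator
  expect_identical(adherence_rate(log4, as_of_day = 4), 1.0)
})
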