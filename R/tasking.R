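#' Days on which a reminder policy fires
#'
#' `daily` covers every trial day; `every_x_days` fires on day 1 and then
#' every `x` days (1, 1+x, 1+2x, ...), anchored at trial day 1 rather than at
#' phase boundaries.
#'
#' @param policy A [reminder_policy()].
#' @param total_days Trial length in days, `>= 1`.
#' @return Integer vector of covered day indices within `[1, total_days]`.
#' @examples
#' recurrence_days(reminder_policy(recurrence = "every_x_days", interval_days = 3), 10)
#' @export
recurrence_days <- function(policy, total_days) {
  if (!is_count(total_days, min = 1L)) {
    abort_nof1("bad_argument", "total_days must be an integer >= 1")
  }
  total_days <- as.integer(total_days)
  if (identical(policy$recurrence, "daily")) {
    seq_len(total_days)
  } else if (identical(policy$recurrence, "every_x_days")) {
    seq.int(1L, total_days, by = as.integer(policy$interval_days))
  } else {
    abort_nof1("bad_argument", "unknown recurrence in reminder policy")
  }
}

task_log_ptype <- function() {
  tibble::tibble(
    day_index = integer(),
    date = as.Date(character()),
    time = character(),
    kind = character(),
    component_id = character(),
    component_name = character(),
    phase_label = character(),
    status = character(),
    completed_at = character()
  )
}

#' Tasks due on one trial day
#'
#' Expands the trial's reminder policies into the concrete to-dos of a single
#' day: one measurement task per (measure, reminder time) whose recurrence
#' covers the day, and one intervention task per (active intervention,
#' reminder time) likewise covered. Intervention tasks are suppressed on
#' withdrawal B days — the participant should not be told to perform the
#' intervention during a no-intervention phase — while measures are collected
#' in all phases. Tasks are sorted by time of day, then kind, then component.
#'
#' @param spec A valid `nof1_trial`.
#' @param day 1-based day index within the trial.
#' @param start_date Optional trial start date; fills the `date` column.
#' @return A task tibble (see [notification_schedule()] for the columns), all
#'   rows `pending`.
#' @export
tasks_for_day <- function(spec, day, start_date = NULL) {
  stop_if_invalid(spec)
  dur <- total_duration(spec$schedule)
  if (!is_count(day, min = 1L) || day > dur) {
    abort_nof1("day_out_of_range", paste0("day must be in [1, ", dur, "]"))
  }
  day_tasks(spec, as.integer(day), start_date, dur)
}

# internal: no re-validation, used by notification_schedule over all days
day_tasks <- function(spec, day, start_date, dur) {
  label <- phase_of_day(spec$schedule, day)
  rows <- list()

  active <- if (spec$design == "withdrawal") {
    if (label == "A") spec$interventions[1] else list()
  } else {
    if (label == "A") spec$interventions[1] else spec$interventions[2]
  }
  for (iv in active) {
    if (day %in% recurrence_days(iv$reminder, dur)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        day_index = day, time = iv$reminder$times, kind = "intervention",
        component_id = iv$id, component_name = iv$name
      )
    }
  }
  for (m in spec$measures) {
    if (day %in% recurrence_days(m$reminder, dur)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        day_index = day, time = m$reminder$times, kind = "measurement",
        component_id = m$id, component_name = m$name
      )
    }
  }

  if (length(rows) == 0) {
    out <- task_log_ptype()
  } else {
    out <- dplyr::bind_rows(rows)
    out$date <- if (is.null(start_date)) as.Date(NA) else as.Date(start_date) + day - 1L
    out$phase_label <- label
    out$status <- "pending"
    out$completed_at <- NA_character_
    out <- out[order(hhmm_to_minutes(out$time), out$kind, out$component_id), ]
    out <- out[, names(task_log_ptype())]
  }
  out
}

#' Full task calendar for a trial
#'
#' Concatenates [tasks_for_day()] over every day of the trial, giving the
#' complete schedule of reminders/notifications the engine would fire. The
#' calendar is deterministic given the spec and start date.
#'
#' @inheritParams tasks_for_day
#' @return A tibble with columns `day_index`, `date`, `time`, `kind`
#'   (`"intervention"`/`"measurement"`), `component_id`, `component_name`,
#'   `phase_label`, `status` (all `"pending"`), `completed_at` (`NA`).
#' @examples
#' trial <- nof1_trial(
#'   goal = goal("Improve sleep"),
#'   interventions = list(intervention("Meditation")),
#'   measures = list(measure_keyboard("Sleep duration", unit = "hours"))
#' )
#' nrow(notification_schedule(trial))  # 28 measurement + 14 intervention tasks
#' @export
notification_schedule <- function(spec, start_date = NULL) {
  stop_if_invalid(spec)
  dur <- total_duration(spec$schedule)
  days <- purrr::map(seq_len(dur), function(d) day_tasks(spec, d, start_date, dur))
  dplyr::bind_rows(task_log_ptype(), days)
}

match_task <- function(log, day_index, component_id, time = NULL) {
  hit <- log$day_index == day_index & log$component_id == component_id
  if (!is.null(time)) hit <- hit & log$time == time
  which(hit)
}

#' Update task status
#'
#' A task is addressed by its `(day_index, component_id, time)` coordinates
#' (`time` may be omitted when unambiguous). Statuses only ever move from
#' `pending` to `completed` or `missed`; completing an already-resolved task
#' is an error.
#'
#' @param log A task tibble from [notification_schedule()].
#' @param day_index,component_id,time Task coordinates.
#' @param at Completion timestamp (`"YYYY-MM-DDTHH:MM:SS"`).
#' @return The updated task tibble.
#' @export
mark_completed <- function(log, day_index, component_id, time = NULL,
                           at = now_timestamp()) {
  set_task_status(log, day_index, component_id, time, "completed", at)
}

#' @rdname mark_completed
#' @export
mark_missed <- function(log, day_index, component_id, time = NULL) {
  set_task_status(log, day_index, component_id, time, "missed", NA_character_)
}

set_task_status <- function(log, day_index, component_id, time, status, at) {
  idx <- match_task(log, day_index, component_id, time)
  if (length(idx) == 0) {
    abort_nof1("unknown_task", paste0(
      "no task for component '", component_id, "' on day ", day_index,
      if (!is.null(time)) paste0(" at ", time) else ""
    ))
  }
  if (length(idx) > 1) {
    abort_nof1("ambiguous_task",
               "several tasks match; disambiguate with the time argument")
  }
  if (log$status[idx] != "pending") {
    abort_nof1("task_state", paste0(
      "task is already '", log$status[idx], "'; only pending tasks can change status"
    ))
  }
  log$status[idx] <- status
  log$completed_at[idx] <- at
  log
}

#' Mark past-due pending tasks as missed
#'
#' A task not completed by the end of its calendar day becomes missed.
#'
#' @param log A task tibble.
#' @param as_of_day Current trial day; all pending tasks on earlier days are
#'   marked missed. Defaults to past the end of the trial (everything due).
#' @return The updated task tibble.
#' @export
finalize_tasks <- function(log, as_of_day = Inf) {
  past_due <- log$status == "pending" & log$day_index < as_of_day
  log$status[past_due] <- "missed"
  log
}

#' Adherence rate of a task log
#'
#' The fraction of due tasks that were completed: completed over
#' (completed + missed + pending past-due).
#'
#' @param log A task tibble.
#' @param as_of_day Current trial day; tasks on day `as_of_day` or later that
#'   are still pending are not yet due. Defaults to past the end of the trial.
#' @return A fraction in `[0, 1]`, or `NA` when no task is due yet.
#' @export
adherence_rate <- function(log, as_of_day = Inf) {
  due <- log$status %in% c("completed", "missed") |
    (log$status == "pending" & log$day_index < as_of_day)
  if (!any(due)) return(NA_real_)
  sum(log$status[due] == "completed") / sum(due)
}
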