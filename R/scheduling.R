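#' Generate a balanced phase label sequence
#'
#' Phases come in pairs so that A and B always occur equally often. Under the
#' `alternating` order the AB pair is repeated `p` times (ABAB...). Under the
#' `counterbalanced` order the pair orientation alternates: odd pairs are AB,
#' even pairs BA, giving ABBA for `p = 2` and ABBAAB for `p = 3`. The
#' blockwise extension beyond two pairs preserves both the balance and the
#' ABBA motif of the classical counterbalanced sequence.
#'
#' @param n_phase_pairs Integer `p >= 1`.
#' @param order `"alternating"` or `"counterbalanced"`.
#' @return A character vector of `2 * p` labels `"A"`/`"B"` with exactly `p`
#'   of each.
#' @examples
#' generate_phase_sequence(2, "alternating")     # A B A B
#' generate_phase_sequence(2, "counterbalanced") # A B B A
#' @export
generate_phase_sequence <- function(n_phase_pairs, order = c("alternating", "counterbalanced")) {
  order <- match.arg(order)
  if (!is_count(n_phase_pairs, min = 1L)) {
    abort_nof1("bad_argument", "n_phase_pairs must be an integer >= 1")
  }
  p <- as.integer(n_phase_pairs)
  pairs <- lapply(seq_len(p), function(k) {
    if (order == "alternating" || k %% 2L == 1L) c("A", "B") else c("B", "A")
  })
  unlist(pairs, use.names = FALSE)
}

#' Total trial duration in days
#'
#' A schedule of `p` phase pairs with `d` days per phase lasts `2 * p * d`
#' days (each pair contributes two phases).
#'
#' @param schedule A [schedule()].
#' @return Integer number of days.
#' @export
total_duration <- function(schedule) {
  2L * as.integer(schedule$n_phase_pairs) * as.integer(schedule$phase_duration_days)
}

#' Realize a schedule as a labeled phase calendar
#'
#' Expands a schedule into its contiguous phase spans: 1-based inclusive day
#' ranges, one row per phase, optionally mapped onto calendar dates.
#'
#' @param schedule A [schedule()].
#' @param start_date Optional trial start (`Date` or `"YYYY-MM-DD"`); when
#'   given, `start_date`/`end_date` columns hold whole local calendar days.
#' @return A tibble with columns `phase` (ordinal), `label` (`"A"`/`"B"`),
#'   `start_day`, `end_day` (inclusive day indices) and, when `start_date`
#'   is supplied, `start_date` and `end_date`.
#' @examples
#' phase_calendar(default_schedule(), start_date = "2022-01-01")
#' @export
phase_calendar <- function(schedule, start_date = NULL) {
  v <- violation_collector()
  validate_schedule(schedule, "schedule", v)
  if (nrow(v$report()) > 0) {
    abort_nof1("invalid_schedule", paste(v$report()$message, collapse = "; "))
  }
  d <- as.integer(schedule$phase_duration_days)
  labels <- generate_phase_sequence(schedule$n_phase_pairs, schedule$order)
  n <- length(labels)
  cal <- tibble::tibble(
    phase = seq_len(n),
    label = labels,
    start_day = (seq_len(n) - 1L) * d + 1L,
    end_day = seq_len(n) * d
  )
  if (!is.null(start_date)) {
    start_date <- as.Date(start_date)
    cal$start_date <- start_date + cal$start_day - 1L
    cal$end_date <- start_date + cal$end_day - 1L
  }
  cal
}

#' Phase label for a trial day
#'
#' @param schedule A [schedule()].
#' @param day 1-based day index (vectorised), within `[1, total_duration]`.
#' @return Character vector of `"A"`/`"B"` labels.
#' @export
phase_of_day <- function(schedule, day) {
  dur <- total_duration(schedule)
  if (any(day < 1 | day > dur | day != as.integer(day))) {
    abort_nof1("day_out_of_range",
               paste0("day must be an integer in [1, ", dur, "]"))
  }
  labels <- generate_phase_sequence(schedule$n_phase_pairs, schedule$order)
  phase_idx <- (as.integer(day) - 1L) %/% as.integer(schedule$phase_duration_days) + 1L
  labels[phase_idx]
}

phase_ordinal_of_day <- function(schedule, day) {
  (as.integer(day) - 1L) %/% as.integer(schedule$phase_duration_days) + 1L
}

#' Which intervention is active on a given trial day
#'
#' Under the withdrawal design the single intervention is active on A days
#' and nothing is active on B (no-intervention) days. Under the
#' alternating-treatment design the first-entered intervention is active on A
#' days and the second on B days; some intervention is always active.
#'
#' @param spec A valid `nof1_trial`.
#' @param day 1-based day index within the trial.
#' @return The active intervention (a named list) or `NULL` on withdrawal
#'   B days.
#' @export
active_intervention_on_day <- function(spec, day) {
  stop_if_invalid(spec)
  label <- phase_of_day(spec$schedule, day)
  if (spec$design == "withdrawal") {
    if (label == "A") spec$interventions[[1]] else NULL
  } else {
    if (label == "A") spec$interventions[[1]] else spec$interventions[[2]]
  }
}
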