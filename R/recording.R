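#' Create an empty observation log
#'
#' Observations are kept in an append-only tibble, chronologically ordered by
#' timestamp, with one row per recorded measurement.
#'
#' @return A zero-row tibble with columns `measure_id`, `timestamp`,
#'   `day_index`, `phase_label`, `value`. Values are stored as text in the
#'   log (numbers are formatted losslessly and re-parsed on aggregation) so
#'   numeric and categorical measures share one tidy container and the CSV
#'   round-trip is exact.
#' @export
new_observation_log <- function() {
  tibble::tibble(
    measure_id = character(),
    timestamp = character(),
    day_index = integer(),
    phase_label = character(),
    value = character()
  )
}

#' Record a measurement
#'
#' Validates a raw entry against the measure's input type and appends it to
#' the log, stamped with the trial day index and phase label derived from the
#' timestamp. Validation failures carry distinct condition classes:
#' * keyboard/scale value that is not a finite number — `nof1_error_not_a_number`;
#' * list entry not among the configured items — `nof1_error_invalid_item`;
#' * scale value outside `[min, max]` — `nof1_error_out_of_range`;
#' * timestamp outside the trial window — `nof1_error_outside_trial`.
#'
#' Multiple observations of one measure on the same day are allowed (reminder
#' policies permit several times per day) and all retained.
#'
#' @param log An observation tibble from [new_observation_log()].
#' @param spec A valid `nof1_trial`.
#' @param measure_id Id of the measure being recorded.
#' @param value The raw entry: a number or numeric text for keyboard and
#'   scale measures, an item for list measures.
#' @param at Entry timestamp `"YYYY-MM-DDTHH:MM:SS"`.
#' @param start_date Trial start date, anchoring day 1.
#' @return The log with one appended row.
#' @examples
#' trial <- nof1_trial(
#'   goal = goal("Improve sleep"),
#'   interventions = list(intervention("Meditation")),
#'   measures = list(measure_keyboard("sleep", unit = "hours", id = "m-sleep"))
#' )
#' log <- new_observation_log() |>
#'   record(trial, "m-sleep", "7.5", at = "2022-01-10T08:00:00",
#'          start_date = "2022-01-01")
#' log
#' @export
record <- function(log, spec, measure_id, value, at = now_timestamp(),
                   start_date) {
  stop_if_invalid(spec)
  measure <- find_measure(spec, measure_id)
  if (!is_timestamp(at)) {
    abort_nof1("bad_timestamp", "at must be a 'YYYY-MM-DDTHH:MM:SS' timestamp")
  }

  day <- as.integer(timestamp_date(at) - as.Date(start_date)) + 1L
  dur <- total_duration(spec$schedule)
  if (day < 1L || day > dur) {
    abort_nof1("outside_trial", paste0(
      "timestamp ", at, " falls on trial day ", day,
      ", outside the trial window [1, ", dur, "]"
    ))
  }

  stored <- validate_value(measure, value)
  if (nrow(log) > 0 && parse_timestamp(at) < parse_timestamp(log$timestamp[nrow(log)])) {
    abort_nof1("out_of_order",
               "observations must be appended in chronological order")
  }

  dplyr::bind_rows(log, tibble::tibble(
    measure_id = measure_id,
    timestamp = at,
    day_index = day,
    phase_label = phase_of_day(spec$schedule, day),
    value = stored
  ))
}

# validate a raw entry against a measure's input-type config; returns the
# canonical text representation stored in the log
validate_value <- function(measure, value) {
  if (measure$input_type == "list") {
    value <- as.character(value)
    if (length(value) != 1 || !value %in% measure$list_config$items) {
      abort_nof1("invalid_item", paste0(
        "'", paste(value, collapse = ","), "' is not one of the configured items: ",
        paste(measure$list_config$items, collapse = ", ")
      ))
    }
    return(value)
  }
  num <- suppressWarnings(as.numeric(value))
  if (length(num) != 1 || !is.finite(num)) {
    abort_nof1("not_a_number", paste0(
      "'", paste(value, collapse = ","), "' cannot be read as a finite number"
    ))
  }
  if (measure$input_type == "scale") {
    sc <- measure$scale_config
    if (num < sc$min || num > sc$max) {
      abort_nof1("out_of_range", paste0(
        "scale value ", num, " outside [", sc$min, ", ", sc$max, "]"
      ))
    }
  }
  format_value(num)
}

format_value <- function(x) {
  # as.character() keeps up to 15 significant digits, enough to round-trip
  # values the engine itself produced
  as.character(x)
}

observation_values <- function(log) as.numeric(log$value)

#' Export / import an observation log as CSV
#'
#' The CSV has columns `measure_id, timestamp, day_index, phase_label, value`
#' with RFC 4180 quoting in UTF-8. Import re-validates every row against the
#' trial spec (known measure, value conforming to its input type, day index
#' within the trial, phase label consistent with the schedule) and reports
#' offending rows by line number.
#'
#' @param log An observation tibble.
#' @param path Optional file path; when `NULL`, `export_csv` returns the CSV
#'   text and `import_csv` treats `x` as CSV text.
#' @param x CSV text or a file path.
#' @param spec A valid `nof1_trial` used for re-validation.
#' @return `export_csv`: the CSV text (invisibly when written to `path`);
#'   `import_csv`: an observation tibble.
#' @export
export_csv <- function(log, path = NULL) {
  out <- log[, names(new_observation_log())]
  if (is.null(path)) {
    readr::format_csv(out)
  } else {
    readr::write_csv(out, path)
    invisible(readr::format_csv(out))
  }
}

#' @rdname export_csv
#' @export
import_csv <- function(x, spec) {
  stop_if_invalid(spec)
  src <- if (length(x) == 1 && !grepl("[\n,]", x) && file.exists(x)) x else I(paste(x, collapse = "\n"))
  parsed <- tryCatch(
    readr::read_csv(
      src,
      col_types = readr::cols(
        measure_id = readr::col_character(),
        timestamp = readr::col_character(),
        day_index = readr::col_integer(),
        phase_label = readr::col_character(),
        value = readr::col_character()
      ),
      progress = FALSE
    ),
    error = function(e) abort_nof1("csv_parse", paste0("cannot read CSV: ", conditionMessage(e)))
  )
  required <- names(new_observation_log())
  if (!all(required %in% names(parsed))) {
    abort_nof1("csv_parse", paste0(
      "CSV is missing column(s): ", paste(setdiff(required, names(parsed)), collapse = ", ")
    ))
  }
  probs <- readr::problems(parsed)
  if (nrow(probs) > 0) {
    abort_nof1("csv_row", paste0(
      "malformed CSV row(s) at line(s): ", paste(unique(probs$row + 1L), collapse = ", ")
    ))
  }

  dur <- total_duration(spec$schedule)
  bad <- character()
  for (i in seq_len(nrow(parsed))) {
    line <- i + 1L  # header is line 1
    row_ok <- tryCatch({
      m <- find_measure(spec, parsed$measure_id[i])
      validate_value(m, parsed$value[i])
      if (is.na(parsed$day_index[i]) || parsed$day_index[i] < 1 || parsed$day_index[i] > dur) {
        abort_nof1("outside_trial", "day index outside trial")
      }
      if (phase_of_day(spec$schedule, parsed$day_index[i]) != parsed$phase_label[i]) {
        abort_nof1("phase_mismatch", "phase label inconsistent with schedule")
      }
      TRUE
    }, nof1_error = function(e) conditionMessage(e))
    if (!isTRUE(row_ok)) bad <- c(bad, paste0("line ", line, ": ", row_ok))
  }
  if (length(bad) > 0) {
    abort_nof1("csv_row", paste0(
      "invalid observation row(s):\n", paste(bad, collapse = "\n")
    ), lines = bad)
  }
  tibble::tibble(
    measure_id = parsed$measure_id,
    timestamp = parsed$timestamp,
    day_index = parsed$day_index,
    phase_label = parsed$phase_label,
    value = parsed$value
  )
}
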